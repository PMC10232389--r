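test_that("a lone Levins species declines monotonically with patch loss", {
  fw <- basal_web(1)
  p <- param_set(cP = 0.45, eP = 0.2)
  sw <- run_sweep(fw, hierarchical_H(1), p, U_grid = c(0, 0.2, 0.5),
                  mode = "basal_only", cross_validate = 0)
  expect_equal(unname(sw$P[, 1]), 1 - c(0, 0.2, 0.5) - 0.2 / 0.45,
               tolerance = 1e-8)
  expect_true(all(diff(sw$P[, 1]) < 0))
})

test_that("the two-species tradeoff community has a non-monotone richness band", {
  fw <- basal_web(2)
  p <- param_set(cP = c(0.45, 0.8), eP = 0.2)
  sw <- run_sweep(fw, hierarchical_H(2), p, U_grid = seq(0, 0.85, by = 0.01),
                  mode = "basal_only", cross_validate = 0)
  at <- function(u) sw$metrics$n_basal[which.min(abs(sw$U - u))]
  expect_equal(at(0), 1L)     # fast colonizer excluded without loss
  expect_equal(at(0.3), 2L)   # coexistence band at intermediate loss
  expect_equal(at(0.85), 0L)  # loss beyond every balance point (max 1 - e/c)
  expect_true(any(diff(sw$metrics$n_basal) > 0))  # richness rises: non-monotone
})

test_that("turning points census enter/leave threshold crossings", {
  fw <- basal_web(2)
  p <- param_set(cP = c(0.45, 0.8), eP = 0.2)
  sw <- run_sweep(fw, hierarchical_H(2), p, U_grid = seq(0, 0.85, by = 0.01),
                  mode = "basal_only", cross_validate = 0)
  tp <- detect_turning_points(sw)
  expect_equal(sum(tp$events$direction == "enter"), 1L)  # B2 enters once
  expect_equal(sum(tp$events$direction == "leave"), 2L)  # both leave eventually
  # the lone-species extinction point lands at U = 1 - e/c
  fw1 <- basal_web(1)
  sw1 <- run_sweep(fw1, hierarchical_H(1), param_set(cP = 0.45, eP = 0.2),
                   U_grid = seq(0, 0.7, by = 0.01), mode = "basal_only",
                   cross_validate = 0)
  tp1 <- detect_turning_points(sw1)
  expect_equal(nrow(tp1$events), 1L)
  expect_equal(tp1$events$direction, "leave")
  expect_lte(tp1$events$U_lo, 1 - 0.2 / 0.45)
  expect_gte(tp1$events$U_hi, 1 - 0.2 / 0.45)
})

test_that("constant profiles yield no turning points and empty grids are vacuous", {
  fw <- basal_web(1)
  p <- param_set(cP = 0.8, eP = 0.2)
  sw <- run_sweep(fw, hierarchical_H(1), p, U_grid = c(0, 0.05, 0.1),
                  mode = "basal_only", cross_validate = 0)
  expect_equal(nrow(detect_turning_points(sw)$events), 0L)
  empty <- run_sweep(fw, hierarchical_H(1), p, U_grid = numeric())
  expect_length(empty$U, 0L)
  expect_equal(nrow(detect_turning_points(empty)$events), 0L)
})

test_that("local-maxima counting handles plateaus and boundaries", {
  expect_equal(count_local_maxima(c(1, 2, 1, 3, 1)), 2L)
  expect_equal(count_local_maxima(c(1, 2, 2, 1)), 1L)       # plateau counts once
  expect_equal(count_local_maxima(c(3, 2, 1)), 1L)          # boundary maximum
  expect_equal(count_local_maxima(c(3, 2, 1), boundary = FALSE), 0L)
  expect_equal(count_local_maxima(c(2, 2, 2)), 0L)
  expect_equal(count_local_maxima(c(1, 2, 1, 3, 1), boundary = FALSE), 2L)
})

test_that("analytic and ODE sweep solvers agree along the gradient", {
  fw <- basal_web(3)
  p <- param_set(cP = c(0.45, 0.625, 0.8), eP = 0.2)
  U <- c(0, 0.25, 0.5)
  sa <- run_sweep(fw, hierarchical_H(3), p, U_grid = U, mode = "basal_only",
                  solver = "analytic", cross_validate = 0)
  so <- run_sweep(fw, hierarchical_H(3), p, U_grid = U, mode = "basal_only",
                  solver = "ode", cross_validate = 0)
  expect_equal(sa$P, so$P, tolerance = 1e-4)
  expect_equal(sa$metrics$n_basal, so$metrics$n_basal)
})

test_that("basal-only mode zeroes predation and drops consumers", {
  fw <- generate_web(3, 5, 11, seed = 2)
  p <- assign_cc_tradeoff(fw, c(0.45, 0.8))  # mu = phi = 0.05 in full mode
  sw <- run_sweep(fw, hierarchical_H(3), p, U_grid = c(0, 0.3),
                  mode = "basal_only", cross_validate = 0)
  expect_equal(ncol(sw$A), 0L)
  expect_equal(sw$solver, "analytic")
  expect_equal(colnames(sw$P), fw$basal)
})

test_that("richer basal pools produce at least as many turning points on average", {
  counts <- function(n_P, seeds) {
    vapply(seeds, function(s) {
      fw <- basal_web(n_P)
      p <- assign_cc_tradeoff(fw, c(0.25, 1), spacing = "irregular", seed = s)
      sw <- run_sweep(fw, hierarchical_H(n_P), p,
                      U_grid = seq(0, 0.9, by = 0.01), mode = "basal_only",
                      cross_validate = 0)
      nrow(detect_turning_points(sw)$events)
    }, numeric(1))
  }
  seeds <- 1:10
  expect_gte(mean(counts(6, seeds)), mean(counts(3, seeds)))
})

test_that("full webs with consumers lose complexity non-monotonically", {
  # a generated web of the smallest island-web size class exhibits rises in
  # richness, mean chain length and omnivory somewhere along the gradient;
  # the property is existential over topologies, hence the bounded seed search
  found <- FALSE
  for (s in 1:4) {
    fw <- generate_web(3, 11, 23, seed = s)
    p <- assign_cc_tradeoff(fw, c(0.45, 0.8))
    sw <- run_sweep(fw, hierarchical_H(3), p, U_grid = seq(0, 0.6, by = 0.05),
                    mode = "full")
    m <- sw$metrics
    expect_true(all(m$ok))
    expect_lt(m$S[nrow(m)], m$S[1])  # the community is eventually poorer
    rises <- c(any(diff(m$S) > 0),
               any(diff(m$mean_fcl[!is.na(m$mean_fcl)]) > 0),
               any(diff(m$omnivory) > 0))
    if (all(rises)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("removing the tradeoff collapses richness to a monotone decline", {
  fw <- basal_web(4)
  p <- param_set(cP = rep(0.6, 4), eP = 0.2)
  sw <- run_sweep(fw, hierarchical_H(4), p, U_grid = seq(0, 0.9, by = 0.01),
                  mode = "basal_only", cross_validate = 0)
  expect_true(all(diff(sw$metrics$n_basal) <= 0))
})

test_that("sweep results export as one CSV row per patch-loss level", {
  fw <- basal_web(2)
  p <- param_set(cP = c(0.45, 0.8), eP = 0.2)
  sw <- run_sweep(fw, hierarchical_H(2), p, U_grid = c(0, 0.3, 0.6),
                  mode = "basal_only", cross_validate = 0)
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f, seed = 99, config_hash = "abcd")
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$U, c(0, 0.3, 0.6))
  expect_true(all(back$seed == 99))
  unlink(f)
})
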