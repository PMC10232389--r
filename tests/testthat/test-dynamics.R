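test_that("basal growth rate matches hand evaluation in the single-species limit", {
  fw <- basal_web(1)
  p <- param_set(cP = 0.45, eP = 0.2, U = 0)
  # c*P*(1 - P) - e*P = 0.45*0.5*0.5 - 0.2*0.5
  expect_equal(basal_rhs(0.5, numeric(), fw, hierarchical_H(1), p), 0.0125)
})

test_that("extinct basal species have zero growth and symmetric contests cancel", {
  fw <- basal_web(2)
  p <- param_set(cP = c(0.5, 0.5), eP = 0.2, U = 0.1)
  H <- weakened_H(2, 0)  # symmetric 0.5 contests
  r0 <- basal_rhs(c(0, 0.4), numeric(), fw, H, p)
  expect_equal(r0[1], 0)
  # identical species, symmetric H: displacement terms cancel exactly
  r <- basal_rhs(c(0.3, 0.3), numeric(), fw, H, p)
  expect_equal(r[1], r[2])
  levins <- 0.5 * 0.3 * (1 - 0.1 - 0.6) - 0.2 * 0.3
  expect_equal(r[1], levins)
})

test_that("consumer growth decays without prey and vanishes at the fixed point", {
  fw <- food_web(cbind("B1", "C1"), "B1", "C1")
  p <- param_set(cP = 0.45, eP = 0.2, cA = 0.625, eA = 0.05, U = 0, web = fw)
  expect_equal(consumer_rhs(0, 0.3, fw, p), -0.05 * 0.3)
  P_star <- 1 - 0.2 / 0.45
  A_star <- 1 - 0.05 / (0.625 * P_star)
  expect_equal(consumer_rhs(P_star, A_star, fw, p), 0)
  expect_equal(round(c(P_star, A_star), 4), c(0.5556, 0.856),
               tolerance = 1e-3)
  # no vacant patches: colonization shuts off and the rate is negative
  expect_lt(consumer_rhs(P_star, 1, fw, p), 0)
})

test_that("per-capita basal growth has the Lotka-Volterra form b + M P when mu = 0", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    fw <- basal_web(n)
    cP <- sort(stats::runif(n, 0.2, 1))
    p <- param_set(cP = cP, eP = 0.2, U = stats::runif(1, 0, 0.5))
    H <- if (rep %% 2) hierarchical_H(n) else weakened_H(n, stats::runif(1))
    P <- stats::runif(n, 0, (1 - p$U) / n)
    b <- cP * (1 - p$U) - p$eP
    Hm <- unclass(as.matrix(H))
    M <- cP * Hm - t(cP * Hm) - matrix(cP, n, n)
    expect_equal(basal_rhs(P, numeric(), fw, H, p) / P,
                 b + drop(M %*% P))
  }
})

test_that("the steady-state protocol reproduces the Levins closed form", {
  fw <- basal_web(1)
  for (U in c(0, 0.2, 0.5)) {
    p <- param_set(cP = 0.45, eP = 0.2, U = U)
    st <- run_to_steady_state(fw, hierarchical_H(1), p)
    expect_lt(abs(st$P - (1 - U - 0.2 / 0.45)), 1e-6)
  }
})

test_that("a basal-consumer pair settles on the bottom-up equilibrium", {
  fw <- food_web(cbind("B1", "C1"), "B1", "C1")
  p <- param_set(cP = 0.45, eP = 0.2, cA = 0.625, eA = 0.05, U = 0, web = fw)
  st <- run_to_steady_state(fw, hierarchical_H(1), p)
  P_star <- 1 - 0.2 / 0.45
  expect_equal(unname(st$P), P_star, tolerance = 1e-5)
  expect_equal(unname(st$A), 1 - 0.05 / (0.625 * P_star), tolerance = 1e-5)
  expect_false(any(st$extinct))
  expect_equal(unname(st$q), 1)
})

test_that("patch loss beyond the colonization-extinction balance exterminates all", {
  fw <- food_web(cbind("B1", "C1"), "B1", "C1")
  # U > 1 - e/c for the basal species: nothing can persist
  p <- param_set(cP = 0.45, eP = 0.2, cA = 0.625, eA = 0.05, U = 0.6, web = fw)
  st <- run_to_steady_state(fw, hierarchical_H(1), p)
  expect_true(all(st$extinct))
  expect_equal(unname(st$P), 0)
  expect_equal(unname(st$A), 0)
})

test_that("occupancies stay within feasible bounds along trajectories", {
  set.seed(11)
  for (s in 1:3) {
    fw <- generate_web(3, 6, 14, seed = s)
    p <- assign_cc_tradeoff(fw, c(0.25, 1), U = 0.1)
    st <- run_to_steady_state(fw, hierarchical_H(3), p)
    tol <- 1e-7
    expect_true(all(st$P >= 0 & st$P <= 1 - p$U + tol))
    expect_true(all(st$A >= 0 & st$A <= 1 - p$U + tol))
    expect_lte(sum(st$P), 1 - p$U + tol)
  }
})

test_that("the steady state is insensitive to the initialization", {
  fw <- generate_web(3, 5, 11, seed = 4)
  p <- assign_cc_tradeoff(fw, c(0.45, 0.8), U = 0.2)
  H <- hierarchical_H(3)
  st1 <- run_to_steady_state(fw, H, p)
  S <- n_species(fw)
  st2 <- run_to_steady_state(fw, H, p, init = rep(0.08, S))
  expect_equal(st1$P, st2$P, tolerance = 1e-5)
  expect_equal(st1$A, st2$A, tolerance = 1e-5)
})

test_that("time-averaged occupancies below threshold are flagged extinct", {
  fw <- basal_web(1)
  p <- param_set(cP = 0.45, eP = 0.2, U = 0.6)  # doomed: U > 1 - e/c
  st <- run_to_steady_state(fw, hierarchical_H(1), p)
  expect_true(st$extinct[["B1"]])
  expect_equal(st$P[["B1"]], 0)
})

test_that("dimension mismatches are reported", {
  fw <- basal_web(2)
  p <- param_set(cP = c(0.4, 0.6), eP = 0.2)
  expect_error(basal_rhs(c(0.1, 0.1, 0.1), numeric(), fw, hierarchical_H(2), p),
               "does not match")
  expect_error(run_to_steady_state(fw, hierarchical_H(2), p, init = c(0.1)),
               "one entry per species")
})

test_that("steady states export as tidy per-species CSV", {
  fw <- food_web(cbind("B1", "C1"), "B1", "C1")
  p <- param_set(cP = 0.45, eP = 0.2, cA = 0.625, eA = 0.05, U = 0, web = fw)
  st <- run_to_steady_state(fw, hierarchical_H(1), p)
  f <- tempfile(fileext = ".csv")
  df <- write_steady_state_csv(st, fw, f)
  back <- utils::read.csv(f)
  expect_equal(back$species_id, c("B1", "C1"))
  expect_equal(back$role, c("basal", "consumer"))
  expect_equal(back$occupancy, df$occupancy, tolerance = 1e-8)
  unlink(f)
})
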