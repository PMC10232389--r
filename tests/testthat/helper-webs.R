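# fixture builders and independent (brute-force) oracles

basal_web <- function(n) {
  food_web(matrix(character(), 0L, 2L),
           basal = sprintf("B%d", seq_len(n)), consumers = character())
}

chain_web <- function() {
  food_web(rbind(c("B1", "C1"), c("C1", "C2")),
           basal = "B1", consumers = c("C1", "C2"))
}

diamond_web <- function() {
  food_web(rbind(c("B1", "C1"), c("B1", "C2"), c("C1", "C3"), c("C2", "C3")),
           basal = "B1", consumers = c("C1", "C2", "C3"))
}

# all 0/1 tournaments on n nodes (list of matrices); feasible for n <= 5
all_tournaments <- function(n) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    H <- matrix(0, n, n)
    for (p in seq_len(m)) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      if (bits[p]) H[i, j] <- 1 else H[j, i] <- 1
    }
    H
  })
}

# brute-force cyclic-triad census: a 3-sub-tournament is cyclic iff every
# competitor beats exactly one other
cyclic_triads_brute <- function(H) {
  n <- nrow(H)
  cnt <- 0L
  for (i in seq_len(n - 2L)) for (j in seq(i + 1L, n - 1L)) for (k in seq(j + 1L, n)) {
    sub <- H[c(i, j, k), c(i, j, k)]
    if (all(rowSums(sub) == 1)) cnt <- cnt + 1L
  }
  cnt
}

# exhaustive top-to-basal path enumeration through igraph, as an oracle for
# the chain-length dynamic programming
fcl_brute <- function(web) {
  g <- as_igraph(web)
  tops <- setdiff(web$species, unique(web$edges[, 1L]))
  lens <- unlist(lapply(web$basal, function(b) {
    unlist(lapply(tops, function(t) {
      if (t == b) return(0L)
      ps <- igraph::all_simple_paths(g, from = b, to = t, mode = "out")
      vapply(ps, function(p) length(p) - 1L, integer(1L))
    }))
  }))
  c(mean_fcl = mean(lens), max_fcl = max(lens))
}

# per-species omnivory by brute-force path-length census
omnivory_brute <- function(web) {
  g <- as_igraph(web)
  omn <- vapply(web$species, function(sp) {
    prey <- web$edges[web$edges[, 2L] == sp, 1L]
    if (length(prey) < 2L) return(FALSE)
    lens <- unlist(lapply(web$basal, function(b) {
      if (b == sp) return(0L)
      ps <- igraph::all_simple_paths(g, from = b, to = sp, mode = "out")
      vapply(ps, function(p) length(p) - 1L, integer(1L))
    }))
    length(unique(lens)) >= 2L
  }, logical(1L))
  sum(omn) / n_species(web)
}

# random instance for analytic-vs-numeric comparisons, redrawn when the
# equilibrium sits within margin of an exclusion boundary: marginal cases
# approach/leave the boundary at a vanishing exponential rate and need
# burn-in far beyond the standard protocol to settle numerically
draw_regular_instance <- function(n_P_max = 6L, n_A_max = 10L,
                                  occ_margin = 0.02, rate_margin = 1e-3) {
  repeat {
    n_P <- sample.int(n_P_max, 1L)
    n_A <- sample.int(n_A_max, 1L)
    max_links <- n_P * n_A + (n_A * (n_A - 1L)) %/% 2L
    pool <- seq(n_A, min(max_links, 3L * n_A))
    L <- pool[sample.int(length(pool), 1L)]
    web <- generate_web(n_P, n_A, L, seed = sample.int(1e6, 1L))
    H <- hierarchical_H(n_P)
    lo <- stats::runif(1L, 0.2, 0.5)
    hi <- stats::runif(1L, lo + 0.2, 1)
    params <- assign_cc_tradeoff(web, c(lo, hi), mu = 0, phi = 0,
                                 U = stats::runif(1L, 0, 0.6))
    st <- analytic_steady_state(web, H, params)
    if (instance_is_regular(web, H, params, st, occ_margin, rate_margin))
      return(list(web = web, H = H, params = params, analytic = st))
  }
}

instance_is_regular <- function(web, H, params, st, occ_margin, rate_margin) {
  occ <- c(st$P, st$A)
  if (any(occ > 0 & occ < occ_margin)) return(FALSE)
  # excluded basal species must be repelled from the boundary at a real rate
  cP <- params$cP
  Hm <- unclass(as.matrix(H))
  b <- cP * (1 - params$U) - params$eP
  cPH <- cP * Hm
  M <- cPH - t(cPH) - matrix(cP, length(cP), length(cP))
  out <- which(st$P == 0)
  if (length(out)) {
    r_inv <- b[out] + drop(M[out, , drop = FALSE] %*% st$P)
    if (any(abs(r_inv) < rate_margin)) return(FALSE)
  }
  # same for consumers: near-zero net growth at the boundary is marginal
  if (length(st$A)) {
    s <- drop(crossprod(web$theta, st$P)) + drop(crossprod(web$delta, st$A))
    g <- params$cA * s * (1 - params$U) - params$eA
    marginal <- st$A == 0 & s > 0 & abs(g) < rate_margin
    if (any(marginal)) return(FALSE)
  }
  TRUE
}
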