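#' Analytic basal equilibrium (no top-down predation)
#'
#' With predation disregarded (`mu = 0`) the basal dynamics have
#' Lotka-Volterra form for the per-capita growth rate,
#' `r_i = b_i + sum_j M_ij P_j`, with effective growth rate
#' `b_i = cP_i (1 - U) - eP_i` and effective interaction
#' `M_ij = cP_i H_ij - cP_j H_ji - cP_i` (so `M_ii = -cP_i`).  The unique
#' candidate coexistence point is `P* = -M^{-1} b`.  Feasibility is
#' enforced by community assembly: species with non-positive equilibrium
#' occupancy are removed one at a time (most negative first) and the
#' reduced system re-solved; removed species whose invasion growth rate at
#' the candidate point is positive are re-admitted.  The result is the
#' feasible equilibrium on the surviving subset; non-surviving species are
#' reported at occupancy 0.
#'
#' @param web a `food_web`, or `NULL` for a basal-only system.
#' @param H a `competition_matrix` (n_P x n_P).
#' @param params a `param_set`; all entries of `params$mu` must be 0.
#' @return named basal occupancy vector of length `n_P` (zeros for
#'   excluded species), with the surviving index set in attribute
#'   `"alive"`.
#' @examples
#' pars <- param_set(cP = c(0.45, 0.8), eP = 0.2, U = 0.3)
#' basal_equilibrium_analytic(NULL, hierarchical_H(2), pars)
#' @export
basal_equilibrium_analytic <- function(web, H, params) {
  if (any(params$mu != 0))
    stop("analytic basal equilibrium requires mu = 0 (no top-down predation)")
  cP <- params$cP
  n_P <- length(cP)
  Hm <- unclass(as.matrix(H))
  if (!identical(dim(Hm), c(n_P, n_P))) stop("'H' must be n_P x n_P")
  b <- cP * (1 - params$U) - params$eP
  cPH <- cP * Hm                       # cP_i * H_ij
  M <- cPH - t(cPH) - matrix(cP, n_P, n_P)

  alive <- which(b > 0)                # species unable to grow when alone never assemble
  seen <- character()
  P <- rep(0, n_P)
  while (length(alive) > 0L) {
    key <- paste(alive, collapse = ",")
    if (key %in% seen) {               # assembly cycle: settle it numerically
      warning("community assembly did not converge; ",
              "falling back to numerical integration")
      return(basal_equilibrium_fallback(web, H, params))
    }
    seen <- c(seen, key)
    sol <- tryCatch(
      solve(M[alive, alive, drop = FALSE], -b[alive]),
      error = function(e) NULL)
    if (is.null(sol)) {
      warning("singular effective interaction matrix; ",
              "falling back to numerical integration")
      return(basal_equilibrium_fallback(web, H, params))
    }
    if (all(sol > 0)) {
      # candidate feasible point: re-admit any excluded species that invades
      out <- setdiff(seq_len(n_P), alive)
      r_inv <- b[out] + drop(M[out, alive, drop = FALSE] %*% sol)
      if (length(out) == 0L || all(r_inv <= 1e-12)) {
        P[alive] <- sol
        break
      }
      alive <- sort(c(alive, out[which.max(r_inv)]))
    } else {
      alive <- alive[-which.min(sol)]
    }
  }
  names(P) <- if (!is.null(web)) web$basal else sprintf("B%d", seq_len(n_P))
  attr(P, "alive") <- which(P > 0)
  P
}

basal_equilibrium_fallback <- function(web, H, params) {
  if (is.null(web)) web <- basal_only_web(length(params$cP))
  st <- run_to_steady_state(web, H, params)
  P <- st$P
  attr(P, "alive") <- which(P > 0)
  P
}

basal_only_web <- function(n_P) {
  food_web(matrix(character(), 0L, 2L),
           basal = sprintf("B%d", seq_len(n_P)), consumers = character())
}

#' Analytic consumer equilibrium by bottom-up substitution
#'
#' With no top-down predation on consumers (`phi = 0`), the consumer
#' equilibrium is
#' \deqn{A_i^* = 1 - U - e^A_i / (c^A_i (\sum_j \theta_{ji} P_j^*
#'   + \sum_k \delta_{ki} A_k^*)),}
#' which depends only on the equilibria of species *below* consumer `i`
#' in the acyclic predation graph.  Consumers are therefore solved in
#' topological (prey-before-predator) order; a consumer whose prey sum is
#' zero, or whose solution is non-positive, is set extinct (0) before its
#' own predators are evaluated -- the bottom-up control that propagates
#' basal turnover to higher trophic levels.
#'
#' @param web a `food_web`.
#' @param params a `param_set`; all entries of `params$phi` must be 0.
#' @param P_star named basal equilibrium occupancies (e.g. from
#'   [basal_equilibrium_analytic()]).
#' @return named consumer occupancy vector of length `n_A`.
#' @export
consumer_equilibrium_analytic <- function(web, params, P_star) {
  stopifnot(inherits(web, "food_web"))
  if (any(params$phi != 0))
    stop("analytic consumer equilibrium requires phi = 0")
  n_A <- length(web$consumers)
  A <- numeric(n_A)
  names(A) <- web$consumers
  if (n_A == 0L) return(A)
  if (length(P_star) != length(web$basal))
    stop("'P_star' must have one entry per basal species")
  delta <- web$delta
  order_idx <- consumer_topo_order(delta)
  U <- params$U
  for (i in order_idx) {
    s <- sum(web$theta[, i] * P_star) + sum(delta[, i] * A)
    if (s <= 0) next                   # no surviving prey: consumer extinct
    Ai <- 1 - U - params$eA[i] / (params$cA[i] * s)
    if (Ai > 0) A[i] <- Ai
  }
  A
}

consumer_topo_order <- function(delta) {
  n <- nrow(delta)
  if (n == 0L) return(integer())
  g <- igraph::graph_from_adjacency_matrix(delta, mode = "directed")
  if (!igraph::is_dag(g))
    stop("cycle detected in the consumer predation graph")
  as.integer(igraph::topo_sort(g, mode = "out"))
}

#' Full analytic steady state (no top-down predation)
#'
#' Convenience wrapper combining [basal_equilibrium_analytic()] and
#' [consumer_equilibrium_analytic()] into a `steady_state`.
#'
#' @inheritParams basal_equilibrium_analytic
#' @param threshold extinction threshold applied to the equilibrium
#'   occupancies.
#' @return a `steady_state`.
#' @export
analytic_steady_state <- function(web, H, params, threshold = 1e-6) {
  P <- basal_equilibrium_analytic(web, H, params)
  A <- consumer_equilibrium_analytic(web, params, P)
  attr(P, "alive") <- NULL
  steady_state(P = P, A = A, U = params$U, threshold = threshold)
}
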