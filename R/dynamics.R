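#' Patch-occupancy dynamics: basal right-hand side
#'
#' Rate of change of basal patch occupancies under the
#' colonization-extinction-competition-predation processes:
#' \deqn{dP_i/dt = c^P_i P_i (1 - U - \sum_j P_j) - e^P_i P_i
#'   + \sum_j (c^P_i P_i H_{ij} P_j - c^P_j P_j H_{ji} P_i)
#'   - P_i \sum_k \theta_{ik} \mu_{ik} A_k.}
#' Basal species exclude one another within a patch (the colonization term
#' sees patches free of *any* basal species) and displace one another with
#' probabilities `H`; consumers impose extra, top-down extinction.
#'
#' @param P basal occupancy vector (length `n_P`).
#' @param A consumer occupancy vector (length `n_A`).
#' @param web a `food_web`.
#' @param H a `competition_matrix` (n_P x n_P).
#' @param params a `param_set`.
#' @return numeric vector `dP/dt` of length `n_P`.
#' @export
basal_rhs <- function(P, A, web, H, params) {
  n_P <- length(params$cP)
  if (length(P) != n_P) stop("'P' does not match the number of basal species")
  if (length(A) != length(params$cA))
    stop("'A' does not match the number of consumers")
  H <- unclass(as.matrix(H))
  if (!identical(dim(H), c(n_P, n_P))) stop("'H' must be n_P x n_P")
  cP <- params$cP
  colonization <- cP * P * (1 - params$U - sum(P))
  extinction <- params$eP * P
  displacement <- cP * P * drop(H %*% P) - P * drop(crossprod(H, cP * P))
  predation <- if (length(A)) P * drop(params$mu %*% A) else 0
  colonization - extinction + displacement - predation
}

#' Patch-occupancy dynamics: consumer right-hand side
#'
#' Rate of change of consumer occupancies under
#' colonization-extinction-predation:
#' \deqn{dA_i/dt = c^A_i A_i (\sum_j \theta_{ji} P_j + \sum_k \delta_{ki} A_k)
#'   (1 - U - A_i) - e^A_i A_i - A_i \sum_k \varphi_{ik} \delta_{ik} A_k.}
#' Colonization is fuelled by encounters with prey (bottom-up control);
#' consumers co-occur freely, so the vacant-patch factor is `1 - U - A_i`.
#' Top predators have no predation term.
#'
#' @inheritParams basal_rhs
#' @return numeric vector `dA/dt` of length `n_A`.
#' @export
consumer_rhs <- function(P, A, web, params) {
  n_A <- length(params$cA)
  if (length(A) != n_A) stop("'A' does not match the number of consumers")
  if (length(P) != length(params$cP))
    stop("'P' does not match the number of basal species")
  if (n_A == 0L) return(numeric())
  prey <- drop(crossprod(web$theta, P)) + drop(crossprod(web$delta, A))
  colonization <- params$cA * A * prey * (1 - params$U - A)
  extinction <- params$eA * A
  predation <- A * drop(params$phi %*% A)
  unname(colonization - extinction - predation)
}

#' Integrate the occupancy dynamics to steady state
#'
#' Runs the coupled basal/consumer system for a burn-in period, then
#' averages each species' occupancy over a further window; the
#' time-averaged occupancy is the steady-state estimate.  A species whose
#' average falls below `threshold` is flagged extinct and reported at 0.
#' Species are never removed mid-integration: an occupancy at 0 stays at 0
#' under the dynamics, so thresholding applies only to the averaged
#' trajectory.
#'
#' @param web a `food_web`.
#' @param H a `competition_matrix` for the basal species.
#' @param params a `param_set`.
#' @param t_burnin burn-in duration (time units) before averaging.
#' @param t_avg duration of the averaging window.
#' @param threshold extinction threshold on the mean occupancy.
#' @param init initial occupancy vector of length `n_P + n_A`; the default
#'   `(1 - U) / (2 S)` for every species keeps the basal sum feasible.
#'   The steady state is insensitive to the initialization.
#' @param method integration method passed to [deSolve::ode()]
#'   (`"lsoda"` by default; `"ode45"` selects the Dormand-Prince pair).
#' @param rtol,atol relative/absolute integrator tolerances; occupancies
#'   near the extinction threshold must be resolved, hence the tight
#'   defaults.
#' @param n_avg_samples number of trajectory samples in the averaging
#'   window.
#' @return a `steady_state` with components `P`, `A` (named mean
#'   occupancies, zeroed below threshold), `extinct` (named logical over
#'   all species), `q` (basal relative abundances over survivors), `U`.
#' @examples
#' fw <- food_web(matrix(character(), 0, 2), basal = "B1", consumers = character())
#' pars <- param_set(cP = 0.45, eP = 0.2)
#' st <- run_to_steady_state(fw, hierarchical_H(1), pars)
#' st$P  # ~ 1 - e/c = 0.5556
#' @export
run_to_steady_state <- function(web, H, params, t_burnin = 15000,
                                t_avg = 5000, threshold = 1e-6, init = NULL,
                                method = "lsoda", rtol = 1e-8, atol = 1e-10,
                                n_avg_samples = 201L) {
  stopifnot(inherits(web, "food_web"), inherits(params, "param_set"))
  n_P <- length(web$basal)
  n_A <- length(web$consumers)
  S <- n_P + n_A
  if (length(params$cP) != n_P || length(params$cA) != n_A)
    stop("'params' dimensions do not match the web")
  U <- params$U
  y0 <- if (is.null(init)) rep((1 - U) / (2 * S), S) else as.numeric(init)
  if (length(y0) != S) stop("'init' must have one entry per species")
  if (sum(y0[seq_len(n_P)]) > 1 - U + 1e-12)
    stop("initial basal occupancies exceed the available patch fraction")

  Hm <- unclass(as.matrix(H))
  rhs <- function(t, y, p) {
    P <- y[seq_len(n_P)]
    A <- y[n_P + seq_len(n_A)]
    list(c(basal_rhs(P, A, web, Hm, params),
           consumer_rhs(P, A, web, params)))
  }
  times <- unique(c(0, seq(t_burnin, t_burnin + t_avg,
                           length.out = max(2L, n_avg_samples))))
  out <- deSolve::ode(y0, times, rhs, parms = NULL, method = method,
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop("integrator failed to reach the end of the averaging window; ",
         "diagnostics: istate = ", istate[1L])
  if (nrow(out) < 2L || anyNA(out))
    stop("integrator returned an incomplete trajectory")
  window <- out[out[, "time"] >= t_burnin, -1L, drop = FALSE]
  neg_tol <- max(1e-12, 100 * atol)
  if (any(window < -neg_tol))
    stop(sprintf("negative occupancies beyond tolerance (min = %.3g)",
                 min(window)))
  window[window < 0] <- 0
  occ <- colMeans(window)
  extinct <- occ < threshold
  occ[extinct] <- 0
  names(occ) <- web$species
  names(extinct) <- web$species
  steady_state(P = occ[seq_len(n_P)], A = occ[n_P + seq_len(n_A)],
               extinct = extinct, U = U, threshold = threshold)
}

#' Construct a steady-state record
#'
#' @param P named basal mean occupancies (extinct species at 0).
#' @param A named consumer mean occupancies.
#' @param extinct named logical over all species.
#' @param U patch loss the state was computed at.
#' @param threshold extinction threshold used.
#' @return a `steady_state` with basal relative abundances
#'   `q = P / sum(P)` over surviving basal species.
#' @export
steady_state <- function(P, A = numeric(), extinct = NULL, U = 0,
                         threshold = 1e-6) {
  if (is.null(extinct)) {
    extinct <- c(P, A) < threshold
    P[P < threshold] <- 0
    A[A < threshold] <- 0
  }
  tot <- sum(P)
  q <- if (tot > 0) P / tot else rep(NA_real_, length(P))
  structure(list(P = P, A = A, extinct = extinct, q = q, U = U,
                 threshold = threshold),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state at U = %.3f: %d of %d species surviving\n",
              x$U, sum(!x$extinct), length(x$extinct)))
  occ <- c(x$P, x$A)
  print(round(occ, 4))
  invisible(x)
}

#' Export a steady state as a tidy CSV
#'
#' One row per species with its role, mean occupancy and extinction flag.
#'
#' @param state a `steady_state`.
#' @param web the `food_web` the state belongs to.
#' @param path output file path.
#' @return the data frame written, invisibly.
#' @export
write_steady_state_csv <- function(state, web, path) {
  df <- data.frame(
    species_id = web$species,
    role = c(rep("basal", length(web$basal)),
             rep("consumer", length(web$consumers))),
    occupancy = unname(c(state$P, state$A)),
    extinct = unname(state$extinct))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
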