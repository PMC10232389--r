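#' Demographic and interaction rate sets
#'
#' Bundles all rates of the patch-occupancy dynamics: basal colonization
#' `cP` and extinction `eP` (per species), consumer colonization `cA` and
#' extinction `eA`, the top-down extinction rates `mu` (basal x consumer,
#' supported only on feeding links) and `phi` (consumer x consumer,
#' `phi[k, i]` = extra extinction of consumer `k` caused by its predator
#' `i`), and the patch-loss fraction `U` (proportion of patches
#' permanently destroyed).
#'
#' @param cP,eP numeric vectors of length `n_P` (scalars are recycled).
#' @param cA,eA numeric vectors of length `n_A`.
#' @param mu `n_P x n_A` matrix of top-down rates on basal species.
#' @param phi `n_A x n_A` matrix of top-down rates on consumers.
#' @param U patch loss in \[0, 1).
#' @param web optional `food_web`; when given, `mu`/`phi` are checked to be
#'   supported only on feeding links.
#' @return a `param_set`.
#' @export
param_set <- function(cP, eP, cA = numeric(), eA = numeric(),
                      mu = NULL, phi = NULL, U = 0, web = NULL) {
  n_P <- length(cP)
  if (!is.null(web)) {
    n_P <- length(web$basal)
    n_A <- length(web$consumers)
    cP <- rep_len(cP, n_P)
    cA <- rep_len(cA, n_A)
  }
  eP <- rep_len(eP, length(cP))
  eA <- rep_len(eA, length(cA))
  n_A <- length(cA)
  if (is.null(mu)) mu <- matrix(0, length(cP), n_A)
  if (is.null(phi)) phi <- matrix(0, n_A, n_A)
  mu <- as.matrix(mu); phi <- as.matrix(phi)
  if (any(c(cP, eP, cA, eA, mu, phi) < 0)) stop("all rates must be >= 0")
  if (length(U) != 1L || U < 0 || U >= 1) stop("'U' must be in [0, 1)")
  if (!identical(dim(mu), c(length(cP), n_A)))
    stop("'mu' must be n_P x n_A")
  if (!identical(dim(phi), c(n_A, n_A)))
    stop("'phi' must be n_A x n_A")
  if (!is.null(web)) {
    if (any(mu[web$theta == 0L] != 0))
      stop("'mu' must be supported only on basal-consumer feeding links")
    if (any(phi[web$delta == 0L] != 0))
      stop("'phi' must be supported only on consumer-consumer feeding links")
  }
  structure(list(cP = as.numeric(cP), eP = eP, cA = as.numeric(cA), eA = eA,
                 mu = mu, phi = phi, U = U),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("param_set: %d basal, %d consumers, U = %.3f\n",
              length(x$cP), length(x$cA), x$U))
  cat("  cP:", paste(signif(x$cP, 4), collapse = " "), "\n")
  cat("  eP:", paste(signif(unique(x$eP), 4), collapse = " "),
      " cA:", paste(signif(unique(x$cA), 4), collapse = " "),
      " eA:", paste(signif(unique(x$eA), 4), collapse = " "), "\n")
  cat(sprintf("  mu in [%g, %g], phi in [%g, %g]\n",
              min(x$mu, 0), max(x$mu, 0), min(x$phi, 0), max(x$phi, 0)))
  invisible(x)
}

#' Assign a competition-colonization tradeoff parameterization
#'
#' Gives basal species colonization rates that increase strictly with the
#' species index, so that under a strict competitive hierarchy (species 1
#' the best competitor) competitive rank and colonization ability are
#' negatively correlated -- the classic competition-colonization tradeoff.
#' `"even"` spacing places the rates at equal intervals spanning `c_range`
#' inclusive; `"irregular"` draws them uniformly from `c_range` and sorts
#' them.  All other rates take the standard defaults: `eP = 0.2`,
#' `cA = 0.625`, `eA = 0.05`, and top-down rates `mu = phi = 0.05` on
#' every feeding link.
#'
#' @param web a `food_web`.
#' @param c_range interval for basal colonization rates, within (0, 1\].
#' @param spacing `"even"` or `"irregular"`.
#' @param seed integer seed (used by `"irregular"` spacing).
#' @param eP,cA,eA scalar (or per-species) rate overrides.
#' @param mu,phi scalar top-down rates applied to every feeding link.
#' @param U patch loss in \[0, 1).
#' @return a `param_set` with `cP` strictly increasing.
#' @examples
#' fw <- generate_web(3, 4, 9, seed = 1)
#' assign_cc_tradeoff(fw, c(0.45, 0.8))$cP  # 0.450 0.625 0.800
#' @export
assign_cc_tradeoff <- function(web, c_range = c(0.45, 0.8),
                               spacing = c("even", "irregular"), seed = NULL,
                               eP = 0.2, cA = 0.625, eA = 0.05,
                               mu = 0.05, phi = 0.05, U = 0) {
  stopifnot(inherits(web, "food_web"))
  spacing <- match.arg(spacing)
  n_P <- length(web$basal)
  if (n_P < 1L) stop("web has an empty basal set")
  if (length(c_range) != 2L || c_range[1L] > c_range[2L] ||
      c_range[1L] <= 0 || c_range[2L] > 1)
    stop("'c_range' must be an interval within (0, 1]")
  if (n_P > 1L && c_range[1L] == c_range[2L])
    stop("degenerate 'c_range' cannot order more than one species")
  if (!is.null(seed)) set.seed(seed)
  cP <- if (n_P == 1L) {
    c_range[2L]
  } else if (spacing == "even") {
    seq(c_range[1L], c_range[2L], length.out = n_P)
  } else {
    repeat {
      x <- sort(stats::runif(n_P, c_range[1L], c_range[2L]))
      if (!anyDuplicated(x)) break
    }
    x
  }
  n_A <- length(web$consumers)
  param_set(cP = cP, eP = eP,
            cA = rep_len(cA, n_A), eA = rep_len(eA, n_A),
            mu = mu * (web$theta == 1L), phi = phi * (web$delta == 1L),
            U = U, web = web)
}
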