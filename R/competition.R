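#' Competitive displacement matrices among basal species
#'
#' Basal species compete for patches by displacement: a colonizer of
#' species `i` arriving at a patch held by species `j` takes it over with
#' probability `H[i, j]`.  Three structures are supported: a strict
#' hierarchy (`H[i, j] = 1` for `i < j`, 0 otherwise), a weakened
#' hierarchy interpolating between strict dominance and symmetric coin-flip
#' contests, and intransitive 0/1 tournaments with cyclic (rock-paper-
#' scissors-like) dominance quantified by relative intransitivity.
#'
#' @param H square numeric matrix of displacement probabilities in
#'   \[0, 1\] with zero diagonal.
#' @param structure one of `"hierarchical"`, `"weakened"`, `"intransitive"`.
#' @return a `competition_matrix` (a matrix with a `structure` attribute
#'   and, for tournaments, an `RI` attribute).
#' @export
competition_matrix <- function(H, structure = c("hierarchical", "weakened",
                                                "intransitive")) {
  structure <- match.arg(structure)
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("'H' must be square")
  if (any(H < 0 | H > 1)) stop("displacement probabilities must be in [0, 1]")
  if (any(diag(H) != 0)) stop("no self-displacement: diagonal of H must be 0")
  out <- structure(H, class = c("competition_matrix", "matrix"))
  attr(out, "structure") <- structure
  if (structure != "weakened" && is_tournament(H) && nrow(H) >= 3L)
    attr(out, "RI") <- relative_intransitivity(H)
  out
}

#' @export
as.matrix.competition_matrix <- function(x, ...) {
  out <- unclass(x)
  attr(out, "structure") <- NULL
  attr(out, "RI") <- NULL
  out
}

#' @export
print.competition_matrix <- function(x, ...) {
  cat(sprintf("competition_matrix (%s), %d basal species\n",
              attr(x, "structure"), nrow(x)))
  if (!is.null(attr(x, "RI")))
    cat(sprintf("  relative intransitivity RI = %.4g\n", attr(x, "RI")))
  print(unclass(structure(x, structure = NULL, RI = NULL)))
  invisible(x)
}

is_tournament <- function(H) {
  n <- nrow(H)
  if (n < 2L) return(TRUE)
  if (!all(H %in% c(0, 1))) return(FALSE)
  off <- H + t(H)
  diag(off) <- 1
  all(off == 1)
}

#' Strict hierarchical competition
#'
#' `H[i, j] = 1` whenever species `i` outranks species `j`, 0 otherwise.
#' With the default ranks the species index order is the competitive order
#' (species 1 the best competitor), which combined with colonization rates
#' increasing in the index sets up the classic competition-colonization
#' tradeoff.  Supplying a permutation of ranks decouples competitive rank
#' from colonization rank (a "local tradeoff" scenario).
#'
#' @param n_P number of basal species (>= 1).
#' @param ranks optional permutation of `1:n_P` giving each species'
#'   competitive rank (1 = best competitor).
#' @return a `competition_matrix` tagged `"hierarchical"`.
#' @examples
#' hierarchical_H(3)
#' @export
hierarchical_H <- function(n_P, ranks = seq_len(n_P)) {
  n_P <- as.integer(n_P)
  if (n_P < 1L) stop("need at least one basal species")
  if (!setequal(ranks, seq_len(n_P)))
    stop("'ranks' must be a permutation of 1:n_P")
  H <- outer(ranks, ranks, function(a, b) as.numeric(a < b))
  competition_matrix(H, "hierarchical")
}

#' Weakened hierarchical competition
#'
#' One-parameter interpolation between a strict hierarchy and fully
#' symmetric contests: `H[i, j] = (1 + w) / 2` for `i < j` and
#' `(1 - w) / 2` for `i > j`.  `w = 1` recovers the strict hierarchy,
#' `w = 0` gives 50/50 displacement in both directions.
#'
#' @param n_P number of basal species.
#' @param w hierarchy strength in \[0, 1\].
#' @return a `competition_matrix` tagged `"weakened"`.
#' @export
weakened_H <- function(n_P, w) {
  n_P <- as.integer(n_P)
  if (n_P < 1L) stop("need at least one basal species")
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("'w' must be a single value in [0, 1]")
  H <- matrix(0, n_P, n_P)
  H[upper.tri(H)] <- (1 + w) / 2
  H[lower.tri(H)] <- (1 - w) / 2
  competition_matrix(H, "weakened")
}

#' Relative intransitivity of a competitive tournament
#'
#' For a 0/1 tournament (exactly one of `H[i, j]`, `H[j, i]` is 1 for each
#' pair), the number of cyclic triads is computed from the out-degree
#' (score) sequence, `choose(n, 3) - sum(choose(d, 2))`, and scaled by the
#' maximum attainable for `n` competitors (`(n^3 - n) / 24` for odd `n`,
#' `(n^3 - 4n) / 24` for even `n`).  RI = 0 for a transitive hierarchy and
#' RI = 1 for maximally cyclic dominance (rock-paper-scissors at `n = 3`).
#'
#' @param H a 0/1 tournament matrix (or `competition_matrix`).
#' @return RI in \[0, 1\].
#' @examples
#' relative_intransitivity(hierarchical_H(4))  # 0
#' @export
relative_intransitivity <- function(H) {
  H <- unclass(as.matrix(H))
  n <- nrow(H)
  if (n < 3L) stop("relative intransitivity needs at least 3 competitors")
  if (!is_tournament(H))
    stop("'H' is not a 0/1 tournament (each pair needs exactly one winner)")
  cyc <- cyclic_triads(H)
  cyc / max_cyclic_triads(n)
}

cyclic_triads <- function(H) {
  n <- nrow(H)
  d <- rowSums(H)                       # score sequence
  choose(n, 3) - sum(choose(d, 2))
}

max_cyclic_triads <- function(n) {
  if (n %% 2L == 1L) (n^3 - n) / 24 else (n^3 - 4 * n) / 24
}

#' Intransitive tournament with a target relative intransitivity
#'
#' Perturbs the strict hierarchical matrix by randomized single-pair
#' dominance flips, hill-climbing until the achieved RI is as close as
#' possible to `target_RI` (attainable RIs form a discrete grid, so the
#' closest grid value is returned; the achieved value is stored in the
#' `RI` attribute).  Only the dominance matrix is perturbed; the ranking
#' of species by colonization rate, which lives in the parameter set, is
#' untouched.
#'
#' @param n_P number of basal species (>= 3 for RI > 0).
#' @param target_RI desired relative intransitivity in \[0, 1\].
#' @param seed integer seed; the search is deterministic for a fixed seed.
#' @param max_iter maximum proposal count per restart.
#' @param restarts number of random restarts kept if the target is not met.
#' @return a `competition_matrix` tagged `"intransitive"` (tagged
#'   `"hierarchical"` when `target_RI = 0`).
#' @examples
#' H <- intransitive_H(3, 1, seed = 1)  # rock-paper-scissors
#' attr(H, "RI")
#' @export
intransitive_H <- function(n_P, target_RI, seed = NULL, max_iter = 2000L,
                           restarts = 5L) {
  n_P <- as.integer(n_P)
  if (length(target_RI) != 1L || target_RI < 0 || target_RI > 1)
    stop("'target_RI' must be a single value in [0, 1]")
  if (target_RI == 0) return(hierarchical_H(n_P))
  if (n_P < 3L) stop("RI > 0 requires at least 3 basal species")
  if (!is.null(seed)) set.seed(seed)

  score <- function(H) abs(relative_intransitivity(H) - target_RI)
  pairs <- which(upper.tri(diag(n_P)), arr.ind = TRUE)
  best <- NULL
  for (r in seq_len(restarts)) {
    H <- unclass(as.matrix(hierarchical_H(n_P)))
    cur <- score(H)
    stale <- 0L
    for (it in seq_len(max_iter)) {
      if (cur == 0) break
      p <- pairs[sample.int(nrow(pairs), 1L), ]
      Hn <- H
      Hn[p[1L], p[2L]] <- H[p[2L], p[1L]]
      Hn[p[2L], p[1L]] <- H[p[1L], p[2L]]
      new <- score(Hn)
      if (new < cur) {
        H <- Hn
        cur <- new
        stale <- 0L
      } else stale <- stale + 1L
      if (stale > 50L * nrow(pairs)) break
    }
    if (is.null(best) || cur < best$score) best <- list(H = H, score = cur)
    if (best$score == 0) break
  }
  out <- competition_matrix(best$H, "intransitive")
  if (best$score > 0)
    warning(sprintf(
      "target RI %.3f not attainable for n_P = %d; achieved RI = %.3f",
      target_RI, n_P, attr(out, "RI")))
  out
}
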