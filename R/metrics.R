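#' Realized food web at steady state
#'
#' Induced subgraph on the non-extinct species.  Because consumer
#' persistence is bottom-up controlled, a surviving consumer left with no
#' surviving prey is removed as well, and removal cascades up the web.
#'
#' @param web a `food_web`.
#' @param state a `steady_state` conforming to `web`.
#' @return a `food_web` on the surviving species (possibly empty: zero
#'   basal species is represented as a web with an empty edge set and the
#'   surviving sets only).
#' @export
realized_web <- function(web, state) {
  stopifnot(inherits(web, "food_web"), inherits(state, "steady_state"))
  if (length(state$extinct) != n_species(web))
    stop("'state' does not conform to 'web'")
  keep <- web$species[!state$extinct]
  repeat {
    edges <- web$edges[web$edges[, 1L] %in% keep &
                         web$edges[, 2L] %in% keep, , drop = FALSE]
    cons <- intersect(web$consumers, keep)
    fed <- cons %in% edges[, 2L]
    if (all(fed)) break
    keep <- setdiff(keep, cons[!fed])
  }
  sub_food_web(web, keep)
}

sub_food_web <- function(web, keep) {
  basal <- intersect(web$basal, keep)
  consumers <- intersect(web$consumers, keep)
  edges <- web$edges[web$edges[, 1L] %in% keep &
                       web$edges[, 2L] %in% keep, , drop = FALSE]
  if (length(basal) == 0L) {
    # an empty (or basal-free, hence fully collapsed) community
    return(structure(list(species = character(), basal = character(),
                          consumers = character(),
                          edges = matrix(character(), 0L, 2L,
                                         dimnames = list(NULL, c("prey", "predator"))),
                          theta = matrix(0L, 0L, 0L),
                          delta = matrix(0L, 0L, 0L)),
                     class = "food_web"))
  }
  food_web(edges, basal = basal, consumers = consumers)
}

#' Connectance of a food web
#'
#' `C = 2 L / (S (S - 1))`: the number of realized links relative to the
#' number of species pairs.
#'
#' @param S species count (>= 2 for a defined value).
#' @param L link count.
#' @return connectance, or `NA` when `S < 2`.
#' @examples
#' connectance(14, 23)  # 0.2527...
#' @export
connectance <- function(S, L) {
  if (S < 2) return(NA_real_)
  2 * L / (S * (S - 1))
}

top_species <- function(web) {
  setdiff(web$species, unique(web$edges[, 1L]))
}

prey_of <- function(web) {
  split(web$edges[, 1L], factor(web$edges[, 2L], levels = web$species))
}

#' Enumerate all food chains
#'
#' A food chain is a directed path linking a top species (one that is not
#' preyed upon) down to a basal species.  All such paths are enumerated
#' over the acyclic predation graph; an unconsumed basal species
#' contributes a single chain of zero links.
#'
#' @param web a `food_web` (must be acyclic).
#' @param convention `"links"` (default) counts feeding links per chain,
#'   `"nodes"` counts species.
#' @return a list with `chains` (list of species-id vectors, top first)
#'   and `lengths` (numeric vector per the convention).
#' @export
food_chains <- function(web, convention = c("links", "nodes")) {
  convention <- match.arg(convention)
  if (n_species(web) == 0L)
    return(list(chains = list(), lengths = numeric()))
  preys <- prey_of(web)
  basal <- web$basal
  descend <- function(sp) {
    if (sp %in% basal) return(list(sp))
    unlist(lapply(preys[[sp]], function(pr) {
      lapply(descend(pr), function(tail) c(sp, tail))
    }), recursive = FALSE)
  }
  chains <- unlist(lapply(top_species(web), descend), recursive = FALSE)
  lens <- lengths(chains) - (convention == "links")
  list(chains = chains, lengths = as.numeric(lens))
}

# memoized DP over the DAG: per species, the number of paths down to basal,
# their total and maximum link counts
chain_dp <- function(web) {
  preys <- prey_of(web)
  n <- n_species(web)
  N <- Tot <- Mx <- stats::setNames(rep(NA_real_, n), web$species)
  N[web$basal] <- 1; Tot[web$basal] <- 0; Mx[web$basal] <- 0
  rec <- function(sp) {
    if (!is.na(N[[sp]])) return()
    for (pr in preys[[sp]]) rec(pr)
    pr <- preys[[sp]]
    N[[sp]] <<- sum(N[pr])
    Tot[[sp]] <<- sum(Tot[pr] + N[pr])
    Mx[[sp]] <<- max(Mx[pr]) + 1
  }
  for (sp in web$species) rec(sp)
  list(N = N, Tot = Tot, Mx = Mx)
}

#' Mean and maximum food chain length
#'
#' Computed by memoized dynamic programming over the DAG (equivalent to
#' averaging over the exhaustive chain enumeration of [food_chains()]).
#' The mean averages over *all* top-to-basal chains.
#'
#' @inheritParams food_chains
#' @return `c(mean_fcl, max_fcl)`; `NA`s for an empty web.
#' @export
fcl_stats <- function(web, convention = c("links", "nodes")) {
  convention <- match.arg(convention)
  if (n_species(web) == 0L)
    return(c(mean_fcl = NA_real_, max_fcl = NA_real_))
  dp <- chain_dp(web)
  tops <- top_species(web)
  add <- if (convention == "nodes") 1 else 0
  c(mean_fcl = sum(dp$Tot[tops]) / sum(dp$N[tops]) + add,
    max_fcl = max(dp$Mx[tops]) + add)
}

#' Degree of omnivory
#'
#' A species is an omnivore when it consumes two or more species *and*
#' is reached from the basal level by food chains of different lengths
#' (it feeds at multiple trophic levels).  Returns the fraction of
#' species that are omnivores; 0 for an empty web.
#'
#' @param web a `food_web` (acyclic).
#' @return fraction in \[0, 1\].
#' @export
omnivory_fraction <- function(web) {
  S <- n_species(web)
  if (S == 0L) return(0)
  preys <- prey_of(web)
  depth_sets <- stats::setNames(vector("list", S), web$species)
  for (b in web$basal) depth_sets[[b]] <- 0
  rec <- function(sp) {
    if (!is.null(depth_sets[[sp]])) return(depth_sets[[sp]])
    ds <- sort(unique(unlist(lapply(preys[[sp]], rec)) + 1))
    depth_sets[[sp]] <<- ds
    ds
  }
  omn <- vapply(web$species, function(sp) {
    length(preys[[sp]]) >= 2L && length(rec(sp)) >= 2L
  }, logical(1L))
  sum(omn) / S
}

#' Inverse Simpson diversity of the basal community
#'
#' Effective number of equally abundant basal species,
#' `1 / sum(q_i^2)` with relative abundances `q_i = P_i / sum(P_j)` taken
#' over the species with positive occupancy.
#'
#' @param P basal occupancy vector.
#' @return effective species count in \[1, n\], or `NA` if no species has
#'   positive occupancy.
#' @examples
#' inverse_simpson(c(0.3, 0.3))  # 2
#' @export
inverse_simpson <- function(P) {
  P <- P[P > 0]
  if (length(P) == 0L) return(NA_real_)
  q <- P / sum(P)
  1 / sum(q^2)
}

#' Structural and diversity metrics of a (realized) food web
#'
#' Computes the complexity metrics used along the patch-loss gradient:
#' species richness, basal richness, links, connectance, mean/max food
#' chain length, omnivory, and (when a state is supplied) the inverse
#' Simpson diversity of the surviving basal species.
#'
#' @param web a `food_web`.
#' @param state optional `steady_state`; when given, metrics are computed
#'   on [realized_web()] and diversity on the surviving basal occupancies.
#' @param convention chain-length convention, see [food_chains()].
#' @return one-row `data.frame` with columns `S`, `n_basal`, `L`,
#'   `connectance`, `mean_fcl`, `max_fcl`, `omnivory`, `inv_simpson`.
#' @export
web_metrics <- function(web, state = NULL, convention = c("links", "nodes")) {
  convention <- match.arg(convention)
  inv <- NA_real_
  if (!is.null(state)) {
    inv <- inverse_simpson(state$P)
    web <- realized_web(web, state)
  }
  S <- n_species(web)
  L <- n_links(web)
  fcl <- if (S > 0L) fcl_stats(web, convention)
         else c(mean_fcl = NA_real_, max_fcl = NA_real_)
  data.frame(S = S, n_basal = length(web$basal), L = L,
             connectance = connectance(S, L),
             mean_fcl = unname(fcl[1L]), max_fcl = unname(fcl[2L]),
             omnivory = omnivory_fraction(web), inv_simpson = inv)
}
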