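#' Food-web topology objects
#'
#' A `food_web` is a directed acyclic predation graph on a community
#' partitioned into basal species (first trophic level, no prey) and
#' consumers.  Edges point from prey to predator.  The object carries the
#' two binary interaction matrices used by the occupancy dynamics:
#' `theta` (`n_P x n_A`; `theta[i, k] = 1` iff consumer `k` feeds on basal
#' species `i`) and `delta` (`n_A x n_A`; `delta[k, i] = 1` iff consumer
#' `i` feeds on consumer `k`).
#'
#' @param edges two-column character matrix or data frame of directed
#'   prey -> predator pairs (zero-row input is allowed).
#' @param basal character vector of basal species identifiers.
#' @param consumers character vector of consumer identifiers.
#' @return An object of class `food_web` with components `species`,
#'   `basal`, `consumers`, `edges`, `theta`, `delta`.
#' @examples
#' fw <- food_web(cbind("B1", "C1"), basal = "B1", consumers = "C1")
#' fw
#' @export
food_web <- function(edges, basal, consumers) {
  basal <- as.character(basal)
  consumers <- as.character(consumers)
  if (anyDuplicated(c(basal, consumers)))
    stop("species identifiers must be unique across basal and consumer sets")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), 0L, 2L)
  if (ncol(edges) != 2L) stop("'edges' must have two columns (prey, predator)")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("prey", "predator")
  species <- c(basal, consumers)
  n_P <- length(basal)
  n_A <- length(consumers)
  theta <- matrix(0L, n_P, n_A, dimnames = list(basal, consumers))
  delta <- matrix(0L, n_A, n_A, dimnames = list(consumers, consumers))
  if (nrow(edges) > 0L) {
    if (!all(edges %in% species)) stop("edge endpoints must be known species")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-edges (cannibalism) are not allowed")
    if (any(edges[, 2L] %in% basal))
      stop("basal species cannot have prey")
    bi <- edges[, 1L] %in% basal
    theta[edges[bi, , drop = FALSE]] <- 1L
    delta[edges[!bi, , drop = FALSE]] <- 1L
  }
  fw <- structure(
    list(species = species, basal = basal, consumers = consumers,
         edges = edges, theta = theta, delta = delta),
    class = "food_web")
  validate_food_web(fw)
  fw
}

#' Validate a food web's structural invariants
#'
#' Checks that the predation graph is acyclic, has no self-edges, that
#' basal species have no prey, and that every consumer is supported by at
#' least one feeding path rooted at a basal species.
#'
#' @param web a `food_web`.
#' @return `web`, invisibly; errors on violation.
#' @export
validate_food_web <- function(web) {
  stopifnot(inherits(web, "food_web"))
  if (length(web$basal) < 1L) stop("a food web needs at least one basal species")
  if (nrow(web$edges) > 0L) {
    g <- as_igraph(web)
    if (!igraph::is_dag(g)) stop("predation graph must be acyclic")
  }
  if (length(web$consumers) > 0L) {
    # bottom-up support: prey counts; consumers are reachable from basal iff
    # every consumer keeps >= 1 prey after iteratively deleting unsupported ones
    supported <- c(rep(TRUE, length(web$basal)),
                   rep(FALSE, length(web$consumers)))
    names(supported) <- web$species
    repeat {
      new <- supported
      for (cons in web$consumers[!supported[web$consumers]]) {
        prey <- web$edges[web$edges[, 2L] == cons, 1L]
        if (length(prey) > 0L && any(supported[prey])) new[cons] <- TRUE
      }
      if (identical(new, supported)) break
      supported <- new
    }
    if (!all(supported))
      stop("consumer(s) without a basal-rooted feeding path: ",
           paste(names(supported)[!supported], collapse = ", "))
  }
  invisible(web)
}

#' Number of species and links
#' @param web a `food_web`.
#' @return integer count.
#' @export
n_species <- function(web) length(web$species)

#' @rdname n_species
#' @export
n_links <- function(web) nrow(web$edges)

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf(
    "food_web: %d species (%d basal + %d consumers), %d links\n",
    n_species(x), length(x$basal), length(x$consumers), n_links(x)))
  cat("  basal:    ", paste(x$basal, collapse = " "), "\n")
  if (length(x$consumers))
    cat("  consumers:", paste(x$consumers, collapse = " "), "\n")
  invisible(x)
}

#' Generate a random layered food-web topology
#'
#' Generates an acyclic predation graph with `n_basal` basal species,
#' `n_consumers` consumers and exactly `links` feeding links, emulating
#' the structural character of small island food webs (no loops, no
#' cannibalism, every consumer supported by a basal-rooted chain).
#' Consumers are placed in a random trophic order; each consumer is wired
#' to at least one prey drawn from the basal set and the consumers below
#' it, and the remaining links are added uniformly at random among valid
#' lower-position targets, so chains of unequal length (and hence
#' omnivory) arise naturally.
#'
#' @param n_basal number of basal species (>= 1).
#' @param n_consumers number of consumers (>= 0).
#' @param links total number of feeding links; must satisfy
#'   `links >= n_consumers` (every consumer needs prey) and
#'   `links <= n_basal * n_consumers + choose(n_consumers, 2)`.
#' @param seed integer seed; generation is reproducible for a fixed seed.
#' @return a `food_web`.
#' @examples
#' fw <- generate_web(3, 11, 23, seed = 7)
#' n_links(fw)
#' @export
generate_web <- function(n_basal, n_consumers, links, seed = NULL) {
  n_basal <- as.integer(n_basal)
  n_consumers <- as.integer(n_consumers)
  links <- as.integer(links)
  if (n_basal < 1L) stop("need at least one basal species")
  if (n_consumers < 0L || links < 0L) stop("negative counts are not allowed")
  max_links <- n_basal * n_consumers + (n_consumers * (n_consumers - 1L)) %/% 2L
  if (links < n_consumers)
    stop(sprintf("infeasible: %d links cannot give each of %d consumers prey",
                 links, n_consumers))
  if (links > max_links)
    stop(sprintf("infeasible: at most %d links possible for %d basal + %d consumers",
                 max_links, n_basal, n_consumers))
  if (n_consumers == 0L && links > 0L)
    stop("a web without consumers cannot have links")
  if (!is.null(seed)) set.seed(seed)

  basal <- sprintf("B%d", seq_len(n_basal))
  consumers <- if (n_consumers > 0L) sprintf("C%d", seq_len(n_consumers)) else character()
  # random trophic order of consumers; consumer at position p may feed on any
  # basal species and any consumer at positions < p
  pos <- sample(seq_len(n_consumers))
  edges <- matrix(character(), 0L, 2L)
  if (n_consumers > 0L) {
    by_pos <- consumers[order(pos)]
    mandatory <- vapply(seq_len(n_consumers), function(p) {
      cand <- c(basal, by_pos[seq_len(p - 1L)])
      cand[sample.int(length(cand), 1L)]
    }, character(1L))
    edges <- cbind(mandatory, by_pos)
    # remaining links among all valid (lower position -> higher position) pairs
    all_pairs <- do.call(rbind, lapply(seq_len(n_consumers), function(p) {
      cand <- c(basal, by_pos[seq_len(p - 1L)])
      cbind(cand, by_pos[p])
    }))
    key <- paste(all_pairs[, 1L], all_pairs[, 2L])
    free <- all_pairs[!(key %in% paste(edges[, 1L], edges[, 2L])), , drop = FALSE]
    extra <- links - n_consumers
    if (extra > 0L)
      edges <- rbind(edges, free[sample.int(nrow(free), extra), , drop = FALSE])
  }
  dimnames(edges) <- NULL
  food_web(edges, basal = basal, consumers = consumers)
}

#' Convert a food web to an igraph graph
#'
#' Vertices carry a `role` attribute (`"basal"` or `"consumer"`); edges
#' point from prey to predator.
#'
#' @param web a `food_web`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(web) {
  stopifnot(inherits(web, "food_web"))
  verts <- data.frame(
    name = web$species,
    role = c(rep("basal", length(web$basal)),
             rep("consumer", length(web$consumers))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    as.data.frame(web$edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts)
}

#' Read and write food webs as annotated edge lists
#'
#' The plain-text format is a tab-separated edge list (`prey<TAB>predator`)
#' preceded by a header block of comment lines naming the basal species and
#' any isolated consumers.  `write_web_graphml()`/`read_web_graphml()`
#' exchange the same topology as GraphML via igraph.
#'
#' @param web a `food_web`.
#' @param path file path.
#' @return `read_web_tsv()` and `read_web_graphml()` return a `food_web`;
#'   the writers return `path` invisibly.
#' @export
write_web_tsv <- function(web, path) {
  stopifnot(inherits(web, "food_web"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# basal:", paste(web$basal, collapse = " ")),
               paste("# consumers:", paste(web$consumers, collapse = " ")),
               "# prey\tpredator"), con)
  if (nrow(web$edges) > 0L)
    writeLines(paste(web$edges[, 1L], web$edges[, 2L], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_web_tsv
#' @export
read_web_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  basal_line <- grep("^# basal:", hdr, value = TRUE)
  cons_line <- grep("^# consumers:", hdr, value = TRUE)
  if (length(basal_line) != 1L)
    stop("missing '# basal:' header line in ", path)
  split1 <- function(s, tag) {
    s <- trimws(sub(tag, "", s, fixed = TRUE))
    if (nzchar(s)) strsplit(s, "[[:space:]]+")[[1L]] else character()
  }
  basal <- split1(basal_line, "# basal:")
  consumers <- if (length(cons_line) == 1L) split1(cons_line, "# consumers:") else character()
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  edges <- if (length(body)) {
    do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  } else matrix(character(), 0L, 2L)
  if (length(cons_line) != 1L)
    consumers <- setdiff(unique(c(edges)), basal)
  food_web(edges, basal = basal, consumers = consumers)
}

#' @rdname write_web_tsv
#' @export
write_web_graphml <- function(web, path) {
  igraph::write_graph(as_igraph(web), path, format = "graphml")
  invisible(path)
}

#' @rdname write_web_tsv
#' @export
read_web_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  role <- igraph::vertex_attr(g, "role")
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(role)) stop("GraphML file lacks the 'role' vertex attribute")
  el <- igraph::as_edgelist(g, names = TRUE)
  food_web(el, basal = nm[role == "basal"], consumers = nm[role == "consumer"])
}
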