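#' Build the thresholded similarity graph of a cluster
#'
#' Vertices are the cluster's elements; an edge joins two elements whose
#' pairwise sequence identity reaches the threshold (non-strict `>=`).
#' Edge weights store the identity.
#'
#' @param elements Element table rows for the cluster members (must carry
#'   sequences).
#' @param threshold Identity threshold in `(0, 1]`; 0.8 is a good default
#'   for tRNA-scale conservation.
#' @param id_cache Optional environment used to memoize identities across
#'   clusters (keyed by the sequence pair).
#' @return An `orthology_graph`: list with `vertices` (element ids), `adj`
#'   (logical adjacency matrix), `weights` (numeric matrix of identities),
#'   `threshold`.
#' @export
build_similarity_graph <- function(elements, threshold = 0.8,
                                   id_cache = NULL) {
  if (any(is.na(elements$sequence) | !nzchar(elements$sequence))) {
    missing <- elements$element_id[is.na(elements$sequence) |
                                     !nzchar(elements$sequence)]
    stop_nocall("cluster members without sequence: ",
                paste(missing, collapse = ", "))
  }
  n <- nrow(elements)
  ids <- elements$element_id
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(w) <- 1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        w[i, j] <- w[j, i] <- cached_identity(elements$sequence[i],
                                              elements$sequence[j], id_cache)
      }
    }
  }
  adj <- w >= threshold
  diag(adj) <- FALSE
  structure(list(vertices = ids, adj = adj, weights = w,
                 threshold = threshold),
            class = "orthology_graph")
}

cached_identity <- function(s1, s2, cache) {
  if (is.null(cache)) return(pairwise_identity(s1, s2))
  key <- if (s1 <= s2) paste0(s1, "\r", s2) else paste0(s2, "\r", s1)
  val <- cache[[key]]
  if (is.null(val)) {
    val <- pairwise_identity(s1, s2)
    cache[[key]] <- val
  }
  val
}

#' Test whether a graph is a cograph (P4-free)
#'
#' @param adj Logical adjacency matrix.
#' @return `TRUE` if the graph has no induced path on four vertices.
#' @export
is_cograph <- function(adj) {
  cpp_is_cograph(as_adj_matrix(adj))
}

as_adj_matrix <- function(adj) {
  if (inherits(adj, "orthology_graph")) adj <- adj$adj
  storage.mode(adj) <- "logical"
  adj
}

#' Edit a graph to a cograph with a minimum number of edge changes
#'
#' Valid orthology relations are cographs: no four vertices may induce a
#' path P4.  For graphs with at most `exact_limit` vertices an exact
#' branch-and-bound search (branching over the six vertex pairs of an
#' induced P4, iterative deepening on the edit budget) returns a true
#' minimum edit set; larger graphs fall back to a greedy heuristic that
#' repeatedly applies the single edge flip that destroys the most induced
#' P4s.  Ties prefer edge insertion over deletion, then the
#' lexicographically smallest vertex pair.
#'
#' @param graph An `orthology_graph` or logical adjacency matrix.
#' @param exact_limit Largest vertex count for which the exact search runs.
#' @return List with `adj` (edited adjacency), `edits` (data frame
#'   `from`, `to`, `action`), `count`, `exact` (logical), and for
#'   `orthology_graph` input the updated graph in `graph` (inserted edges
#'   receive the threshold as weight).
#' @export
cograph_edit <- function(graph, exact_limit = 10) {
  adj <- as_adj_matrix(graph)
  n <- nrow(adj)
  ids <- rownames(adj) %||% as.character(seq_len(n))
  dimnames(adj) <- list(ids, ids)
  if (n <= 3L || (n <= 63L && cpp_is_cograph(adj))) {
    res <- list(adj = adj, edits = empty_edits(), count = 0L, exact = TRUE)
  } else if (n <= exact_limit) {
    ex <- cpp_cograph_edit_exact(adj, max_k = n * (n - 1L) / 2L)
    ed <- ex$edits
    out <- adj
    for (r in seq_len(nrow(ed))) {
      out[ed[r, 1L], ed[r, 2L]] <- out[ed[r, 2L], ed[r, 1L]] <- ed[r, 3L] > 0L
    }
    res <- list(adj = out, edits = edits_df(ed, ids), count = ex$count,
                exact = TRUE)
  } else {
    # a P4 never spans connected components, so edit each component alone
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    out <- adj
    all_edits <- empty_edits()
    exact <- TRUE
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      m <- length(idx)
      if (m <= 3L) next
      sub <- adj[idx, idx, drop = FALSE]
      if (m <= 63L && cpp_is_cograph(sub)) next
      if (m <= exact_limit) {
        ex <- cpp_cograph_edit_exact(sub, max_k = m * (m - 1L) / 2L)
        ed <- ex$edits
      } else if (m <= 63L) {
        gr <- cpp_cograph_edit_greedy(sub, max_edits = m * (m - 1L))
        ed <- gr$edits
        exact <- FALSE
      } else {
        warning("similarity-graph component with ", m, " vertices exceeds ",
                "the cograph-editing limit (63); left unedited",
                call. = FALSE)
        exact <- FALSE
        next
      }
      for (r in seq_len(nrow(ed))) {
        a <- idx[ed[r, 1L]]; b <- idx[ed[r, 2L]]
        out[a, b] <- out[b, a] <- ed[r, 3L] > 0L
      }
      all_edits <- rbind(all_edits, edits_df(ed, ids[idx]))
    }
    res <- list(adj = out, edits = all_edits, count = nrow(all_edits),
                exact = exact)
  }
  if (inherits(graph, "orthology_graph")) {
    g <- graph
    g$adj <- res$adj
    ins <- res$edits[res$edits$action == "insert", , drop = FALSE]
    for (r in seq_len(nrow(ins))) {
      # inserted edges carry the threshold as a conservative weight
      g$weights[ins$from[r], ins$to[r]] <- g$threshold
      g$weights[ins$to[r], ins$from[r]] <- g$threshold
    }
    g$edits <- res$edits
    res$graph <- g
  }
  res
}

empty_edits <- function() {
  data.frame(from = character(), to = character(), action = character(),
             stringsAsFactors = FALSE)
}

edits_df <- function(ed, ids) {
  if (nrow(ed) == 0L) return(empty_edits())
  data.frame(from = ids[ed[, 1L]], to = ids[ed[, 2L]],
             action = ifelse(ed[, 3L] > 0L, "insert", "delete"),
             stringsAsFactors = FALSE)
}

#' Exhaustive minimum cograph-edit count (reference implementation)
#'
#' Enumerates all edge-flip subsets in order of increasing size until one
#' yields a P4-free graph.  Exponential; intended for validating
#' [cograph_edit()] on graphs with at most 8 vertices.
#'
#' @param adj Logical adjacency matrix (n <= 8).
#' @return The minimum number of edge edits.
#' @export
cograph_edit_exhaustive <- function(adj) {
  cpp_cograph_edit_exhaustive(as_adj_matrix(adj))
}
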