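#' Refine a cluster's ortholog groups from the edited graph and alignments
#'
#' Connected components of the edited similarity graph may still lump
#' elements whose genomic order contradicts orthology.  The components are
#' therefore intersected with the matches retained by the pairwise
#' duplication-aware alignments: two elements of different species stay in
#' one group only if some alignment matched them (directly or through a
#' run), while same-species elements stay together when the edited graph
#' links them.  Components whose cross-species matches were all removed as
#' crossings fall apart into per-species groups.
#'
#' Elements linked by a retained cross-species match (directly or through a
#' duplication run) share a group.  Elements that retained no match at all
#' are grouped per species within their edited-graph component: a component
#' confined to one species (in-paralogs) stays together, and a component
#' whose cross-species matches were all removed as crossings falls apart
#' into per-species groups.  Same-species similarity edges never bridge two
#' alignment-separated groups: the genomic order evidence wins over raw
#' similarity, which cannot discriminate under concerted evolution.
#'
#' @param elements Element rows of one cluster.
#' @param edited_adj Logical adjacency matrix of the edited graph (dimnames
#'   = element ids).
#' @param alignments List of `dup_alignment` objects covering the species
#'   pairs of the cluster.
#' @return List of character vectors: the ortholog groups (element ids).
#' @export
refine_ortholog_groups <- function(elements, edited_adj, alignments) {
  ids <- elements$element_id
  n <- length(ids)
  if (n == 1L) return(list(ids))
  keep <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (al in alignments) {
    for (mt in al$matches) {
      for (a in mt$s) for (b in mt$t) {
        keep[a, b] <- keep[b, a] <- TRUE
      }
    }
  }
  matched <- rowSums(keep) > 0
  sp <- setNames(elements$species, ids)
  ecomp <- igraph::components(igraph::graph_from_adjacency_matrix(
    edited_adj[ids, ids], mode = "undirected"))$membership
  um <- which(!matched)
  if (length(um) > 1L) {
    for (x in seq_len(length(um) - 1L)) {
      for (y in seq.int(x + 1L, length(um))) {
        a <- um[x]; b <- um[y]
        if (sp[a] == sp[b] && ecomp[a] == ecomp[b] && edited_adj[a, b]) {
          keep[a, b] <- keep[b, a] <- TRUE
        }
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(ids, comp[ids]))
}

#' Full orthology analysis of one cluster
#'
#' Builds the thresholded similarity graph over the cluster members, edits
#' it to a cograph, aligns the per-species element orders for every species
#' pair (allowing tandem-duplication runs), and refines the ortholog groups.
#'
#' @param cluster One cluster record (see [initial_partition()]).
#' @param elements Full element table.
#' @param threshold Identity threshold for orthology edges.
#' @param exact_limit Vertex limit for exact cograph editing.
#' @param run_open Duplication-run opening cost.
#' @param id_cache Optional memoization environment for identities.
#' @return List with `groups` (list of member-id vectors), `graph`
#'   (edited `orthology_graph`), `edits`, `alignments` (named by
#'   `"spA|spB"`), and `dup` (data frame `group`, `species`, `count` of
#'   tandem duplications, aggregated as the maximum over partner species).
#' @export
cluster_orthology <- function(cluster, elements, threshold = 0.8,
                              exact_limit = 10, run_open = 0.05,
                              id_cache = NULL) {
  el <- elements[match(cluster$members, elements$element_id), , drop = FALSE]
  ids <- el$element_id
  if (length(ids) == 1L) {
    return(list(groups = list(ids), graph = NULL, edits = empty_edits(),
                alignments = list(), dup = empty_dup()))
  }
  graph <- build_similarity_graph(el, threshold, id_cache)
  edited <- cograph_edit(graph, exact_limit)
  g <- edited$graph
  species <- unique(el$species)
  orders <- lapply(species, function(s) {
    r <- el[el$species == s, , drop = FALSE]
    r$element_id[order(r$chrom, r$start)]
  })
  names(orders) <- species
  alignments <- list()
  if (length(species) > 1L) {
    prs <- combn(sort(species), 2L)
    for (k in seq_len(ncol(prs))) {
      s1 <- prs[1L, k]; s2 <- prs[2L, k]
      allowed <- allowed_pairs(g, orders[[s1]], orders[[s2]])
      alignments[[paste(s1, s2, sep = "|")]] <-
        duplication_alignment(orders[[s1]], orders[[s2]], allowed, run_open)
    }
  }
  groups <- refine_ortholog_groups(el, g$adj, alignments)
  dup <- duplication_counts(groups, el, alignments, species)
  list(groups = groups, graph = g, edits = edited$edits,
       alignments = alignments, dup = dup)
}

allowed_pairs <- function(graph, order_s, order_t) {
  adj <- graph$adj
  prs <- which(adj[order_s, order_t, drop = FALSE], arr.ind = TRUE)
  if (length(prs) == 0L) {
    return(data.frame(a = character(), b = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(a = order_s[prs[, 1L]], b = order_t[prs[, 2L]],
             weight = graph$weights[cbind(order_s[prs[, 1L]],
                                          order_t[prs[, 2L]])],
             stringsAsFactors = FALSE)
}

empty_dup <- function() {
  data.frame(group = integer(), species = character(), count = integer(),
             stringsAsFactors = FALSE)
}

# Tandem duplications per (group, species).  A run of length k in species X
# contributes k-1 duplications to X; counts are aggregated over partner
# species by taking the maximum, so one event seen against several partners
# is not double-counted.  Groups confined to a single species fall back to
# copy-number minus one.
duplication_counts <- function(groups, el, alignments, species) {
  grp_of <- setNames(rep(seq_along(groups), lengths(groups)),
                     unlist(groups))
  sp <- setNames(el$species, el$element_id)
  acc <- list() # key: group|species|partner -> dup count
  for (nm in names(alignments)) {
    al <- alignments[[nm]]
    pair <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    for (mt in al$matches) {
      if (length(mt$s) > 1L) {
        run <- mt$s; partner <- sp[mt$t[1L]]
      } else if (length(mt$t) > 1L) {
        run <- mt$t; partner <- sp[mt$s[1L]]
      } else next
      key <- paste(grp_of[run[1L]], sp[run[1L]], partner, sep = "\r")
      acc[[key]] <- (acc[[key]] %||% 0L) + length(run) - 1L
    }
  }
  out <- empty_dup()
  if (length(acc)) {
    parts <- do.call(rbind, strsplit(names(acc), "\r", fixed = TRUE))
    df <- data.frame(group = as.integer(parts[, 1L]), species = parts[, 2L],
                     partner = parts[, 3L],
                     count = unlist(acc, use.names = FALSE),
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(count ~ group + species, df, max)
    out <- agg[, c("group", "species", "count")]
  }
  # single-species groups: tandem copies imply copy-number - 1 duplications
  for (gi in seq_along(groups)) {
    gsp <- unique(sp[groups[[gi]]])
    if (length(gsp) == 1L && length(groups[[gi]]) > 1L &&
        !any(out$group == gi & out$species == gsp)) {
      out <- rbind(out, data.frame(group = gi, species = gsp,
                                   count = length(groups[[gi]]) - 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
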