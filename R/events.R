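#' Read a rooted species tree from newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces unique leaf labels.
#' Polytomies are allowed.
#'
#' @param file Path to a newick file, or the newick string itself
#'   (`text = TRUE`).
#' @param text Interpret `file` as the newick string.
#' @return An [ape::phylo] tree.
#' @export
read_species_tree <- function(file, text = FALSE) {
  tree <- if (text) ape::read.tree(text = file) else ape::read.tree(file)
  if (is.null(tree)) stop_nocall("could not parse newick tree")
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1L]
    stop_nocall("duplicate leaf label in species tree: ", dup)
  }
  tree
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# children of an internal node
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

# label for the edge above a node: leaf name, internal node label, or node#
node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node == 0L) return("root")
  if (node <= ntip) return(tree$tip.label[node])
  lb <- tree$node.label
  if (!is.null(lb) && nzchar(lb[node - ntip] %|NA|% "")) {
    return(lb[node - ntip])
  }
  paste0("node", node)
}

#' Place a group's insertion on the species tree
#'
#' By parsimony an ortholog group first appears on the edge ancestral to the
#' least common ancestor of the species carrying it; a group spanning the
#' root is an insertion before the root (reported as the virtual edge
#' `"root"`).
#'
#' @param sigma Character vector: species carrying the group.
#' @param tree Species tree.
#' @return List with `node` (the LCA; 0 when the LCA is the root, denoting
#'   the virtual ancestral edge) and `label` (edge label).
#' @export
place_insertion <- function(sigma, tree) {
  sigma <- unique(sigma)
  missing <- setdiff(sigma, tree$tip.label)
  if (length(missing)) {
    stop_nocall("species not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(sigma) == 0L) stop_nocall("empty species set")
  lca <- if (length(sigma) == 1L) {
    match(sigma, tree$tip.label)
  } else {
    ape::getMRCA(tree, sigma)
  }
  node <- if (lca == root_node(tree)) 0L else lca
  list(node = node, lca = lca, label = node_label(tree, node))
}

#' Place a group's deletions on the species tree
#'
#' Deletions are inferred on the edges ancestral to the *maximal* subtrees
#' below the group's LCA that contain none of the group's species.  On a
#' fully resolved tree no deletion edge can lead to a child of the LCA
#' (each child subtree contains a sigma species by definition of the LCA);
#' under polytomies such edges occur when forced.
#'
#' @param sigma Species carrying the group.
#' @param tree Species tree.
#' @param exclude_leaves Leaves treated as unavailable (e.g. reclassified as
#'   missing data); subtrees are maximal among sigma-free subtrees whose
#'   leaves are all deletable.
#' @return Data frame `node`, `label`, `n_leaves`: one row per deletion
#'   edge (edge above `node`).
#' @export
place_deletions <- function(sigma, tree, exclude_leaves = character(0)) {
  ins <- place_insertion(sigma, tree)
  lca <- ins$lca
  ntip <- ape::Ntip(tree)
  res <- list()
  # depth-first from the LCA: report a node when its whole leaf set is
  # deletable (sigma-free and not excluded), otherwise recurse
  walk <- function(node) {
    lv <- tip_labels_below(tree, node)
    if (!any(lv %in% sigma) && !any(lv %in% exclude_leaves)) {
      res[[length(res) + 1L]] <<- data.frame(
        node = node, label = node_label(tree, node), n_leaves = length(lv),
        stringsAsFactors = FALSE)
      return(invisible())
    }
    if (node > ntip) for (ch in node_children(tree, node)) walk(ch)
    invisible()
  }
  for (ch in node_children(tree, lca)) walk(ch)
  if (length(res) == 0L) {
    return(data.frame(node = integer(), label = character(),
                      n_leaves = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

descendants_of <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, nd)
    if (nd > ntip) stack <- c(stack, node_children(tree, nd))
  }
  out
}

tip_labels_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  dd <- descendants_of(tree, node)
  tree$tip.label[dd[dd <= ntip]]
}

#' Reclassify deletions as missing data
#'
#' A species scored as a deletion is reclassified as missing data when the
#' group's flanking anchor blocks have no alignment row for that species at
#' all: without alignment coverage an absent element is indistinguishable
#' from an unaligned region.
#'
#' @param sigma Species carrying the group.
#' @param tree Species tree.
#' @param flanking List with `upstream` and `downstream` block id sets of
#'   the group's cluster.
#' @param blocks Anchor blocks (for species coverage lookup).
#' @return Character vector of leaves (below the LCA, outside sigma) to be
#'   treated as missing data.
#' @export
classify_missing_data <- function(sigma, tree, flanking, blocks) {
  ins <- place_insertion(sigma, tree)
  lv <- tip_labels_below(tree, ins$lca)
  candidates <- setdiff(lv, sigma)
  if (length(candidates) == 0L) return(character(0))
  fb <- c(flanking$upstream, flanking$downstream)
  covered <- unique(blocks$species[blocks$block_id %in% fb])
  setdiff(candidates, covered)
}

#' Detect remolding and divergent same-type pairs within clusters
#'
#' Remolding changes an element's functional type (e.g. a tRNA anticodon
#' switch) while the sequence stays recognizably similar.  Within each
#' cluster, a pair with distinct types and identity at or above the
#' threshold is reported as a remolding event; a pair with the same type
#' but identity below the threshold is reported as divergent.  Singleton
#' clusters contribute nothing.  Elements without a type label are skipped
#' with a warning.
#'
#' @param clusters `syn_clusters` object.
#' @param elements Element table.
#' @param threshold Identity threshold.
#' @param include_pseudogenes Include pseudogene elements in the scan?
#' @param id_cache Optional identity memoization environment.
#' @return Data frame `cluster_id`, `element_a`, `element_b`, `type_a`,
#'   `type_b`, `identity`, `kind` (`"remolding"` or
#'   `"divergent-same-type"`).
#' @export
detect_remolding <- function(clusters, elements, threshold = 0.8,
                             include_pseudogenes = FALSE, id_cache = NULL) {
  out <- list()
  warned <- FALSE
  for (cl in clusters) {
    if (length(cl$members) < 2L) next
    el <- elements[match(cl$members, elements$element_id), , drop = FALSE]
    if (!include_pseudogenes) el <- el[!el$pseudo, , drop = FALSE]
    no_type <- is.na(el$type) | !nzchar(el$type)
    if (any(no_type)) {
      if (!warned) {
        warning("elements without type labels skipped; remolding cannot ",
                "be assessed for them", call. = FALSE)
        warned <- TRUE
      }
      el <- el[!no_type, , drop = FALSE]
    }
    if (nrow(el) < 2L) next
    for (i in seq_len(nrow(el) - 1L)) {
      for (j in seq.int(i + 1L, nrow(el))) {
        idy <- cached_identity(el$sequence[i], el$sequence[j], id_cache)
        same <- el$type[i] == el$type[j]
        kind <- if (!same && idy >= threshold) {
          "remolding"
        } else if (same && idy < threshold) {
          "divergent-same-type"
        } else {
          next
        }
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = cl$cluster_id,
          element_a = el$element_id[i], element_b = el$element_id[j],
          type_a = el$type[i], type_b = el$type[j],
          identity = idy, kind = kind, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cluster_id = character(), element_a = character(),
                      element_b = character(), type_a = character(),
                      type_b = character(), identity = numeric(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tally evolutionary events over all ortholog groups
#'
#' Aggregates, per tree edge, the insertions (one per group, at the edge
#' above the group's LCA) and deletions (maximal empty subtrees), and per
#' leaf the tandem duplications, singleton groups, missing-data calls and
#' pseudogene counts.
#'
#' @param groups List of group records: each a list with `members`,
#'   `species` (sigma), `dup` (named per-species duplication counts) and
#'   `flanking` (block id sets, may be `NULL`).
#' @param tree Species tree.
#' @param elements Element table (pseudogene and per-type counts).
#' @param blocks Anchor blocks for missing-data classification; `NULL`
#'   disables reclassification.
#' @return An `event_tally`: list of data frames `insertions` (edge label,
#'   count), `deletions`, `leaves` (per-species duplications, singletons,
#'   missing, pseudogenes, elements), plus `per_group` placements.
#' @export
tally_events <- function(groups, tree, elements, blocks = NULL) {
  ins_acc <- list(); del_acc <- list()
  leaves <- tree$tip.label
  dup <- setNames(numeric(length(leaves)), leaves)
  single <- setNames(numeric(length(leaves)), leaves)
  miss <- setNames(numeric(length(leaves)), leaves)
  per_group <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    sigma <- unique(g$species)
    ins <- place_insertion(sigma, tree)
    missing_lv <- character(0)
    if (!is.null(blocks) && !is.null(g$flanking)) {
      missing_lv <- classify_missing_data(sigma, tree, g$flanking, blocks)
    }
    dels <- place_deletions(sigma, tree, exclude_leaves = missing_lv)
    ins_acc[[gi]] <- ins$label
    del_acc[[gi]] <- dels$label
    for (s in missing_lv) miss[s] <- miss[s] + 1
    if (length(g$members) == 1L) {
      single[sigma] <- single[sigma] + 1
    }
    if (!is.null(g$dup) && length(g$dup)) {
      for (s in names(g$dup)) dup[s] <- dup[s] + g$dup[[s]]
    }
    per_group[[gi]] <- list(group = gi, members = g$members, sigma = sigma,
                            insertion = ins$label, deletions = dels$label,
                            missing = missing_lv)
  }
  edge_table <- function(labels) {
    labels <- unlist(labels)
    if (length(labels) == 0L) {
      return(data.frame(edge = character(), count = integer(),
                        stringsAsFactors = FALSE))
    }
    tab <- as.data.frame(table(labels), stringsAsFactors = FALSE)
    names(tab) <- c("edge", "count")
    tab
  }
  ins_tab <- edge_table(ins_acc)
  del_tab <- edge_table(del_acc)
  pseudo <- tapply(elements$pseudo, elements$species, sum)
  n_el <- table(elements$species)
  leaf_tab <- data.frame(
    species = leaves,
    duplications = as.numeric(dup),
    singletons = as.numeric(single),
    missing = as.numeric(miss),
    pseudogenes = as.numeric(pseudo[leaves] %|NA|% 0),
    elements = as.numeric(n_el[leaves] %|NA|% 0),
    stringsAsFactors = FALSE)
  structure(list(insertions = ins_tab, deletions = del_tab,
                 leaves = leaf_tab, per_group = per_group, tree = tree),
            class = "event_tally")
}

#' @export
print.event_tally <- function(x, ...) {
  cat("event_tally over", length(x$per_group), "ortholog groups\n")
  cat("insertions by edge:\n")
  print(x$insertions, row.names = FALSE)
  cat("deletions by edge:\n")
  print(x$deletions, row.names = FALSE)
  cat("per-leaf counts:\n")
  print(x$leaves, row.names = FALSE)
  invisible(x)
}
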