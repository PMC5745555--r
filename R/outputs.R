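#' Write the species tree with event annotations in newick format
#'
#' Each node label is augmented with a comment block
#' `[&ins=..,del=..,dup=..,sin=..,mis=..]` (zero fields omitted; leaf-only
#' fields only at leaves).  Insertions before the root are attached to the
#' root's comment as `root_ins`.
#'
#' @param tally An `event_tally`.
#' @param file Path or connection.
#' @export
write_event_tree <- function(tally, file) {
  tree <- tally$tree
  ntip <- ape::Ntip(tree)
  ins <- setNames(tally$insertions$count, tally$insertions$edge)
  del <- setNames(tally$deletions$count, tally$deletions$edge)
  lt <- tally$leaves
  fmt_node <- function(node) {
    lab <- node_label(tree, node)
    parts <- character(0)
    if (!is.na(ins[lab] %|NA|% NA)) parts <- c(parts, paste0("ins=", ins[lab]))
    if (!is.na(del[lab] %|NA|% NA)) parts <- c(parts, paste0("del=", del[lab]))
    if (node <= ntip) {
      r <- lt[lt$species == lab, ]
      if (nrow(r) == 1L) {
        if (r$duplications > 0) parts <- c(parts, paste0("dup=", r$duplications))
        if (r$singletons > 0) parts <- c(parts, paste0("sin=", r$singletons))
        if (r$missing > 0) parts <- c(parts, paste0("mis=", r$missing))
        if (r$pseudogenes > 0) parts <- c(parts, paste0("psi=", r$pseudogenes))
      }
    }
    if (node == root_node(tree) && !is.na(ins["root"] %|NA|% NA)) {
      parts <- c(parts, paste0("root_ins=", ins["root"]))
    }
    comment <- if (length(parts)) paste0("[&", paste(parts, collapse = ","),
                                         "]") else ""
    paste0(if (node <= ntip) lab else "", comment)
  }
  rec <- function(node) {
    if (node <= ntip) return(fmt_node(node))
    kids <- vapply(node_children(tree, node), rec, "")
    paste0("(", paste(kids, collapse = ","), ")", fmt_node(node))
  }
  writeLines(paste0(rec(root_node(tree)), ";"), file)
  invisible(file)
}

#' Write iTOL annotation datasets for an event tally
#'
#' Emits plain-text iTOL dataset files into `dir`: a multi-value bar chart
#' of per-leaf events (duplications, singletons, missing data, pseudogenes),
#' a simple bar chart of per-leaf element counts, and a binary dataset
#' marking leaves that carry pseudogenes.
#'
#' @param tally An `event_tally`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_itol_datasets <- function(tally, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lt <- tally$leaves
  f1 <- file.path(dir, "itol_events_multibar.txt")
  writeLines(c(
    "DATASET_MULTIBAR",
    "SEPARATOR TAB",
    "DATASET_LABEL\tevents",
    "COLOR\t#377eb8",
    "FIELD_COLORS\t#377eb8\t#4daf4a\t#999999\t#e41a1c",
    "FIELD_LABELS\tduplications\tsingletons\tmissing\tpseudogenes",
    "DATA",
    sprintf("%s\t%g\t%g\t%g\t%g", lt$species, lt$duplications,
            lt$singletons, lt$missing, lt$pseudogenes)), f1)
  f2 <- file.path(dir, "itol_elements_simplebar.txt")
  writeLines(c(
    "DATASET_SIMPLEBAR",
    "SEPARATOR TAB",
    "DATASET_LABEL\telement counts",
    "COLOR\t#ff7f00",
    "DATA",
    sprintf("%s\t%g", lt$species, lt$elements)), f2)
  f3 <- file.path(dir, "itol_pseudogenes_binary.txt")
  writeLines(c(
    "DATASET_BINARY",
    "SEPARATOR TAB",
    "DATASET_LABEL\tpseudogenes present",
    "COLOR\t#984ea3",
    "FIELD_SHAPES\t1",
    "FIELD_LABELS\tpseudogenes",
    "DATA",
    sprintf("%s\t%d", lt$species, as.integer(lt$pseudogenes > 0))), f3)
  invisible(c(f1, f2, f3))
}

#' Write the event list as TSV, sorted by event then location
#'
#' @param tally An `event_tally`.
#' @param file Path or connection.
#' @export
write_events_table <- function(tally, file) {
  rows <- rbind(
    data.frame(event = "insertion", location = tally$insertions$edge,
               count = tally$insertions$count, stringsAsFactors = FALSE),
    data.frame(event = "deletion", location = tally$deletions$edge,
               count = tally$deletions$count, stringsAsFactors = FALSE),
    data.frame(event = "duplication", location = tally$leaves$species,
               count = tally$leaves$duplications, stringsAsFactors = FALSE),
    data.frame(event = "singleton", location = tally$leaves$species,
               count = tally$leaves$singletons, stringsAsFactors = FALSE),
    data.frame(event = "missing", location = tally$leaves$species,
               count = tally$leaves$missing, stringsAsFactors = FALSE),
    data.frame(event = "pseudogene", location = tally$leaves$species,
               count = tally$leaves$pseudogenes, stringsAsFactors = FALSE))
  rows <- rows[order(rows$event, rows$location), ]
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write element counts by species and type
#'
#' @param elements Element table.
#' @param file Path or connection.
#' @export
write_counts_table <- function(elements, file) {
  tab <- as.data.frame(table(species = elements$species,
                             type = elements$type),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab <- tab[tab$count > 0L, ]
  tab <- tab[order(tab$species, tab$type), ]
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write remolding events as TSV
#'
#' @param remolding Data frame from [detect_remolding()].
#' @param file Path or connection.
#' @export
write_remolding_table <- function(remolding, file) {
  write.table(remolding, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
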