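#' Pipeline configuration
#'
#' Collects the user-tunable parameters of the pipeline.  The similarity
#' threshold is by far the most consequential: it decides which elements can
#' be orthologs at all.  80% identity is a good default for tRNA-scale
#' conservation; adjust for the sequence conservation and phylogenetic range
#' of the family at hand.
#'
#' @param similarity_threshold Identity threshold in (0, 1] for orthology
#'   edges (and remolding calls).
#' @param min_maf_score MAF blocks scoring below this are discarded.
#' @param max_anchor_distance Maximum joinable gap (bases) between clusters.
#' @param max_extent Maximum merged-cluster span (bases).
#' @param join_mode `"relaxed"` (default), `"strict"`, or `"none"`.
#' @param exact_limit Vertex limit for exact cograph editing.
#' @param run_open Duplication-run opening cost in the order alignment.
#' @param include_pseudogenes_in_remolding Scan pseudogenes for remolding?
#' @param verbose Write intermediate per-cluster files and log stage counts.
#' @param seed Optional integer seed (the pipeline itself is deterministic;
#'   the seed is recorded and applied for reproducibility of any downstream
#'   randomness).
#' @return A `run_config` list.
#' @export
run_config <- function(similarity_threshold = 0.8, min_maf_score = 0,
                       max_anchor_distance = 5000, max_extent = 50000,
                       join_mode = c("relaxed", "strict", "none"),
                       exact_limit = 10, run_open = 0.05,
                       include_pseudogenes_in_remolding = FALSE,
                       verbose = FALSE, seed = NULL) {
  join_mode <- match.arg(join_mode)
  if (!is.numeric(similarity_threshold) || similarity_threshold <= 0 ||
      similarity_threshold > 1) {
    stop_nocall("similarity_threshold must be in (0, 1]")
  }
  structure(list(
    similarity_threshold = similarity_threshold,
    min_maf_score = min_maf_score,
    max_anchor_distance = max_anchor_distance,
    max_extent = max_extent,
    join_mode = join_mode,
    exact_limit = exact_limit,
    run_open = run_open,
    include_pseudogenes_in_remolding = include_pseudogenes_in_remolding,
    verbose = verbose,
    seed = seed
  ), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param file Path to a YAML file.
#' @return A `run_config`.
#' @export
load_config <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_nocall("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Run the full synteny-orthology pipeline
#'
#' Executes every stage in memory: anchor filtering, tight-anchor mapping,
#' initial clustering, cluster joining, per-cluster orthology (similarity
#' graph, cograph editing, duplication-aware alignment, group refinement),
#' remolding detection and, when a species tree is supplied, event tallying.
#' With `output_dir` the standard result files are written; `verbose` mode
#' additionally writes per-cluster intermediates.
#'
#' @param maf Anchor blocks data frame or path to a MAF file.
#' @param elements Element table data frame or path to an element TSV.
#' @param tree Species tree (`phylo`), newick path, or `NULL` to stop after
#'   orthology inference (the tree is required only for event counting).
#' @param genomes Named list of genome FASTA paths /
#'   [Biostrings::DNAStringSet]; needed when element sequences must be
#'   extracted.
#' @param config A [run_config()].
#' @param output_dir Directory for result files, or `NULL` for in-memory
#'   operation only.
#' @return A `synorth_result`: list with `blocks` (retained anchors),
#'   `anchor_map`, `clusters`, `groups` (group records with members,
#'   species, duplication counts, flanking anchors), `remolding`, `tally`
#'   (or `NULL`), `config`, `log` (per-stage counts).
#' @export
run_pipeline <- function(maf, elements, tree = NULL, genomes = NULL,
                         config = run_config(), output_dir = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  say <- function(...) if (isTRUE(config$verbose)) message("[syntorth] ", ...)
  if (is.character(maf)) maf <- read_maf(maf)
  if (missing(elements) || is.null(maf) || is.null(elements)) {
    stop_nocall("required inputs: genome alignment (MAF) and elements; ",
                "a species tree is required only for event counting")
  }
  if (is.character(elements)) {
    elements <- read_element_table(elements, genomes = genomes)
  }
  if (any(is.na(elements$sequence))) {
    if (is.null(genomes)) {
      stop_nocall("elements lack sequences and no genomes were provided")
    }
    idx <- is.na(elements$sequence)
    elements$sequence[idx] <- extract_sequences(
      elements[idx, , drop = FALSE], genomes)
  }
  if (is.character(tree)) tree <- read_species_tree(tree)

  n_blocks_in <- length(unique(maf$block_id))
  blocks <- filter_anchors(maf, elements, config$min_maf_score)
  n_blocks <- length(unique(blocks$block_id))
  say("anchors: ", n_blocks, " kept of ", n_blocks_in)
  amap <- build_anchor_map(blocks, elements)
  clusters0 <- initial_partition(amap, elements)
  say("initial clusters: ", length(clusters0))
  clusters <- switch(config$join_mode,
    none = clusters0,
    strict = join_clusters_strict(clusters0, elements, blocks,
                                  config$max_anchor_distance,
                                  config$max_extent),
    relaxed = join_clusters_relaxed(clusters0, elements, blocks,
                                    config$max_anchor_distance,
                                    config$max_extent))
  say("clusters after ", config$join_mode, " joining: ", length(clusters))

  id_cache <- new.env(parent = emptyenv())
  groups <- list()
  ortho <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    res <- cluster_orthology(cl, elements,
                             threshold = config$similarity_threshold,
                             exact_limit = config$exact_limit,
                             run_open = config$run_open,
                             id_cache = id_cache)
    ortho[[k]] <- res
    for (gi in seq_along(res$groups)) {
      members <- res$groups[[gi]]
      el <- elements[match(members, elements$element_id), , drop = FALSE]
      dup_rows <- res$dup[res$dup$group == gi, , drop = FALSE]
      groups[[length(groups) + 1L]] <- list(
        group_id = sprintf("%s.g%d", cl$cluster_id, gi),
        cluster_id = cl$cluster_id,
        members = members,
        species = unique(el$species),
        dup = setNames(dup_rows$count, dup_rows$species),
        flanking = list(upstream = cl$upstream, downstream = cl$downstream)
      )
    }
  }
  say("ortholog groups: ", length(groups), " (",
      sum(vapply(groups, function(g) length(g$members) == 1L, TRUE)),
      " singletons)")
  remolding <- detect_remolding(
    clusters, elements, threshold = config$similarity_threshold,
    include_pseudogenes = config$include_pseudogenes_in_remolding,
    id_cache = id_cache)
  tally <- NULL
  if (!is.null(tree)) {
    tally <- tally_events(groups, tree, elements, blocks)
  }
  result <- structure(list(
    blocks = blocks, anchor_map = amap, clusters = clusters,
    groups = groups, remolding = remolding, tally = tally,
    elements = elements, config = config,
    log = list(blocks_in = n_blocks_in, blocks_kept = n_blocks,
               clusters_initial = length(clusters0),
               clusters_joined = length(clusters),
               groups = length(groups),
               cograph_edits = sum(vapply(ortho, function(o)
                 nrow(o$edits), 0L)))
  ), class = "synorth_result")
  if (!is.null(output_dir)) {
    write_result_files(result, ortho, output_dir)
  }
  result
}

#' @export
print.synorth_result <- function(x, ...) {
  cat("synorth_result:\n")
  cat("  anchors kept:   ", x$log$blocks_kept, "/", x$log$blocks_in, "\n")
  cat("  clusters:       ", x$log$clusters_initial, "->",
      x$log$clusters_joined, "after", x$config$join_mode, "joining\n")
  cat("  ortholog groups:", x$log$groups, "\n")
  cat("  cograph edits:  ", x$log$cograph_edits, "\n")
  if (!is.null(x$tally)) {
    cat("  events tallied over", length(x$tally$per_group), "groups\n")
  }
  invisible(x)
}

write_result_files <- function(result, ortho, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_cluster_table(result$clusters, result$elements,
                      file.path(output_dir, "clusters.tsv"))
  write_anchor_map(result$anchor_map, file.path(output_dir, "anchor_map.tsv"))
  write_counts_table(result$elements,
                     file.path(output_dir, "element_counts.tsv"))
  write_remolding_table(result$remolding,
                        file.path(output_dir, "remolding.tsv"))
  groups_df <- data.frame(
    group_id = rep(vapply(result$groups, `[[`, "", "group_id"),
                   lengths(lapply(result$groups, `[[`, "members"))),
    element_id = unlist(lapply(result$groups, `[[`, "members")),
    stringsAsFactors = FALSE)
  write.table(groups_df, file.path(output_dir, "ortholog_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$tally)) {
    write_events_table(result$tally, file.path(output_dir, "events.tsv"))
    write_event_tree(result$tally, file.path(output_dir, "events.nwk"))
    write_itol_datasets(result$tally, output_dir)
  }
  if (isTRUE(result$config$verbose)) {
    write_verbose_files(result, ortho, file.path(output_dir, "intermediate"))
  }
  invisible(output_dir)
}

# Per-cluster intermediates: edge-weighted graphs, alignments, and the
# cograph deviation report.
write_verbose_files <- function(result, ortho, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dev_lines <- character(0)
  for (k in seq_along(result$clusters)) {
    cl <- result$clusters[[k]]
    o <- ortho[[k]]
    if (is.null(o$graph)) next
    w <- o$graph$weights
    ids <- o$graph$vertices
    prs <- which(upper.tri(w), arr.ind = TRUE)
    edge_df <- data.frame(a = ids[prs[, 1L]], b = ids[prs[, 2L]],
                          identity = w[prs],
                          edge = o$graph$adj[prs],
                          stringsAsFactors = FALSE)
    write.table(edge_df,
                file.path(dir, paste0(cl$cluster_id, "_graph.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(o$alignments)) {
      lines <- character(0)
      for (nm in names(o$alignments)) {
        al <- o$alignments[[nm]]
        lines <- c(lines, paste0("# ", nm, " score=", format(al$score)))
        for (mt in al$matches) {
          lines <- c(lines, paste0(paste(mt$s, collapse = ","), " ~ ",
                                   paste(mt$t, collapse = ",")))
        }
        if (length(al$unmatched_s)) {
          lines <- c(lines, paste0("unmatched_s: ",
                                   paste(al$unmatched_s, collapse = ",")))
        }
        if (length(al$unmatched_t)) {
          lines <- c(lines, paste0("unmatched_t: ",
                                   paste(al$unmatched_t, collapse = ",")))
        }
      }
      writeLines(lines,
                 file.path(dir, paste0(cl$cluster_id, "_alignments.txt")))
    }
    if (nrow(o$edits)) {
      dev_lines <- c(dev_lines, paste0(
        cl$cluster_id, "\t", nrow(o$edits), "\t",
        paste(o$edits$action, o$edits$from, o$edits$to, collapse = "; ")))
    }
  }
  writeLines(c("cluster_id\tedits\tdetail", dev_lines),
             file.path(dir, "cograph_deviations.tsv"))
  invisible(dir)
}
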