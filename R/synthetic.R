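#' Generate a concerted-evolution benchmark with known ground truth
#'
#' Simulates species whose genomes are linked by colinear alignment anchors,
#' with multicopy elements of a few distinct types placed in the gaps
#' between anchors.  Within an ortholog group all copies carry the identical
#' sequence (the signature of concerted evolution), while distinct types are
#' kept below 60% pairwise identity so that an 80% orthology threshold
#' separates them cleanly.  A fraction of groups receives a tandem-duplicate
#' copy in one of its species, and alignment noise is modelled by deleting
#' anchor rows at random.
#'
#' Layout: anchor i occupies 100 bases starting at `500 + 1100*i` on a
#' single chromosome, identically in every species; each element occupies 75
#' bases inside one inter-anchor gap (at most one group per gap, so the
#' anchor-pair partition identifies the true groups when no anchors are
#' lost); a tandem copy sits 10 bases behind its sibling.  About 10% of
#' copies are placed on the minus strand (the genome then carries the
#' reverse complement, and strand-aware extraction must recover the
#' template).
#'
#' @param n_species Number of species (leaves of a fixed balanced tree).
#' @param n_anchors Anchor blocks per genome.
#' @param n_elements Number of ortholog groups to place.
#' @param n_types Number of distinct sequence types.
#' @param dup_fraction Fraction of groups receiving a tandem duplicate in
#'   one random species of their range.
#' @param anchor_loss Probability that an anchor (row) is deleted.
#' @param placement `"homologous-subset"` (each group occupies a uniform
#'   random nonempty species subset at homologous positions; the default),
#'   `"homologous-all"` (all species), or `"random"` (one species each).
#' @param seed Integer seed; identical seeds give identical benchmarks, and
#'   placements are drawn before noise so runs differing only in
#'   `anchor_loss` share their ground truth.
#' @param loss_mode `"per-species"` deletes individual species rows from
#'   blocks (the default; leaves partial alignment coverage, exercising
#'   missing-data classification); `"per-block"` deletes whole blocks.
#' @param write_dir Optionally write the pipeline's input files (MAF,
#'   genome FASTA per species, element TSV without sequences, newick tree,
#'   truth JSON) into this directory.
#' @return List with `blocks` (post-loss anchor blocks), `elements` (with
#'   sequences), `tree`, `truth` (a `benchmark_truth`: `groups`,
#'   `group_records`, `tally`, `deleted_anchors`, `templates`, `seed`) and,
#'   when written, `files`.
#' @export
generate_benchmark <- function(n_species = 6, n_anchors = 10000,
                               n_elements = 100, n_types = 3,
                               dup_fraction = 0.1, anchor_loss = 0,
                               placement = c("homologous-subset",
                                             "homologous-all", "random"),
                               seed = 1, loss_mode = c("per-species",
                                                       "per-block"),
                               write_dir = NULL) {
  placement <- match.arg(placement)
  loss_mode <- match.arg(loss_mode)
  if (dup_fraction < 0 || dup_fraction > 1 || anchor_loss < 0 ||
      anchor_loss > 1) {
    stop_nocall("dup_fraction and anchor_loss must be fractions in [0, 1]")
  }
  if (n_elements > n_anchors - 1L) {
    stop_nocall("need n_anchors > n_elements (one group per inter-anchor gap)")
  }
  set.seed(seed)
  species <- sprintf("sp%d", seq_len(n_species))
  tree <- benchmark_tree(species)
  anchor_len <- 100L; gap_len <- 1000L; el_len <- 75L
  pitch <- anchor_len + gap_len
  a_start <- 500 + pitch * (seq_len(n_anchors) - 1)

  # 1) type templates, mutually dissimilar
  templates <- make_templates(n_types, el_len)
  # 2) one gap per group (gap g lies between anchors g and g+1)
  gaps <- sort(sample.int(n_anchors - 1L, n_elements))
  # 3) types, 4) species subsets, 5) strands, 6) tandem duplications
  type_of <- sample.int(n_types, n_elements, replace = TRUE)
  sigma <- lapply(seq_len(n_elements), function(i) {
    switch(placement,
      "homologous-all" = species,
      "random" = sample(species, 1L),
      "homologous-subset" = sort(sample(species,
                                        sample.int(n_species, 1L))))
  })
  has_dup <- runif(n_elements) < dup_fraction
  dup_species <- vapply(seq_len(n_elements), function(i)
    if (has_dup[i]) sample(sigma[[i]], 1L) else NA_character_, "")

  rows <- list()
  for (i in seq_len(n_elements)) {
    gpos <- a_start[gaps[i]] + anchor_len + 400 # inside gap i
    for (sp in sigma[[i]]) {
      copies <- if (!is.na(dup_species[i]) && dup_species[i] == sp) 2L else 1L
      for (cp in seq_len(copies)) {
        start <- gpos + (cp - 1L) * (el_len + 10L)
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = sprintf("g%03d_%s_c%d", i, sp, cp),
          species = sp, chrom = "chr1",
          start = start, end = start + el_len,
          strand = if (runif(1) < 0.1) "-" else "+",
          type = sprintf("type%d", type_of[i]), pseudo = FALSE,
          score = NA_real_, sequence = templates[type_of[i]],
          group = i, stringsAsFactors = FALSE)
      }
    }
  }
  elements <- do.call(rbind, rows)
  group_of <- elements$group
  elements$group <- NULL

  # anchor blocks, identical coordinates in every species
  blocks <- data.frame(
    block_id = rep(sprintf("blk%06d", seq_len(n_anchors)), each = n_species),
    score = 100,
    species = rep(species, times = n_anchors),
    chrom = "chr1",
    start = rep(a_start, each = n_species),
    end = rep(a_start + anchor_len, each = n_species),
    strand = "+", stringsAsFactors = FALSE)
  class(blocks) <- c("anchor_blocks", "data.frame")

  # 7) alignment noise, drawn last so truth is paired across noise levels
  deleted <- character(0)
  if (anchor_loss > 0) {
    if (loss_mode == "per-species") {
      hit <- runif(nrow(blocks)) < anchor_loss
      deleted <- paste0(blocks$block_id[hit], ":", blocks$species[hit])
      blocks <- blocks[!hit, , drop = FALSE]
    } else {
      ids <- unique(blocks$block_id)
      hit_ids <- ids[runif(length(ids)) < anchor_loss]
      deleted <- hit_ids
      blocks <- blocks[!(blocks$block_id %in% hit_ids), , drop = FALSE]
    }
    class(blocks) <- c("anchor_blocks", "data.frame")
  }

  truth <- benchmark_truth(elements, group_of, tree, seed)
  out <- list(blocks = blocks, elements = elements, tree = tree,
              truth = truth)
  if (!is.null(write_dir)) {
    out$files <- write_benchmark_files(out, write_dir, a_start, anchor_len,
                                       pitch, n_anchors)
  }
  out
}

benchmark_tree <- function(species) {
  n <- length(species)
  if (n == 6L) {
    txt <- sprintf("(((%s,%s),(%s,%s)),(%s,%s));", species[1], species[2],
                   species[3], species[4], species[5], species[6])
    read_species_tree(txt, text = TRUE)
  } else {
    tr <- ape::stree(n, type = "balanced")
    if (is.null(tr) || ape::Ntip(tr) != n) tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- species
    tr
  }
}

make_templates <- function(n_types, len, max_identity = 0.6,
                           max_tries = 200L) {
  bases <- c("A", "C", "G", "T")
  templates <- character(0)
  tries <- 0L
  while (length(templates) < n_types) {
    cand <- paste(sample(bases, len, replace = TRUE), collapse = "")
    ok <- all(vapply(templates, function(t)
      pairwise_identity(cand, t) < max_identity, TRUE))
    if (ok) templates <- c(templates, cand)
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_nocall("could not draw ", n_types, " mutually dissimilar ",
                  "templates; lower n_types or raise max_identity")
    }
  }
  templates
}

# Ground truth: group memberships and the parsimony event tally they imply.
benchmark_truth <- function(elements, group_of, tree, seed) {
  groups <- split(elements$element_id, group_of)
  recs <- lapply(groups, function(members) {
    el <- elements[match(members, elements$element_id), , drop = FALSE]
    copies <- table(el$species)
    dups <- copies[copies > 1L] - 1L
    list(members = members, species = unique(el$species),
         dup = if (length(dups)) setNames(as.numeric(dups), names(dups))
               else numeric(0),
         flanking = NULL)
  })
  tally <- tally_events(recs, tree, elements, blocks = NULL)
  structure(list(groups = unname(groups), group_records = unname(recs),
                 tally = tally, seed = seed),
            class = "benchmark_truth")
}

write_benchmark_files <- function(bench, dir, a_start, anchor_len, pitch,
                                  n_anchors) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- sort(unique(bench$blocks$species))
  glen <- 500 + pitch * n_anchors + 500
  genomes <- list()
  for (sp in species) {
    g <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    rows <- which(bench$elements$species == sp)
    for (r in rows) {
      s <- bench$elements$sequence[r]
      if (bench$elements$strand[r] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      g[(bench$elements$start[r] + 1L):bench$elements$end[r]] <-
        strsplit(s, "")[[1L]]
    }
    genomes[[sp]] <- paste(g, collapse = "")
  }
  fasta_files <- setNames(file.path(dir, paste0(species, ".fa")), species)
  for (sp in species) {
    dna <- Biostrings::DNAStringSet(setNames(genomes[[sp]], "chr1"))
    Biostrings::writeXStringSet(dna, fasta_files[[sp]])
  }
  blocks <- bench$blocks
  blocks$text <- substring(unlist(genomes[blocks$species], use.names = FALSE),
                           blocks$start + 1L, blocks$end)
  maf_file <- file.path(dir, "anchors.maf")
  write_maf(blocks, maf_file,
            src_sizes = setNames(rep(glen, length(species)),
                                 paste0(species, ".chr1")))
  el <- bench$elements
  el$sequence <- NULL # force extraction from the genomes
  el_file <- file.path(dir, "elements.tsv")
  write_element_table(el, el_file)
  tree_file <- file.path(dir, "tree.nwk")
  ape::write.tree(bench$tree, tree_file)
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    seed = bench$truth$seed,
    groups = bench$truth$groups,
    insertions = bench$truth$tally$insertions,
    deletions = bench$truth$tally$deletions,
    leaves = bench$truth$tally$leaves
  ), truth_file, auto_unbox = TRUE, digits = NA)
  list(maf = maf_file, genomes = fasta_files, elements = el_file,
       tree = tree_file, truth = truth_file)
}

#' Score a pipeline run against benchmark ground truth
#'
#' Compares the inferred ortholog groups with the generating groups (exact
#' partition equality) and reports signed event-count differences
#' (inferred minus truth) per category: insertions at leaves and at
#' interior nodes (including before the root), deletions at leaves and
#' interior nodes, singletons, missing-data calls and tandem duplications.
#'
#' @param result A `synorth_result` from [run_pipeline()] on benchmark
#'   input.
#' @param truth The `benchmark_truth` of the same benchmark.
#' @return List with `exact_groups` (logical), `deltas` (named numeric),
#'   `inferred` and `truth` category counts.
#' @export
evaluate_benchmark <- function(result, truth) {
  pred_ids <- sort(unlist(lapply(result$groups, `[[`, "members")))
  true_ids <- sort(unlist(truth$groups))
  if (!identical(pred_ids, true_ids)) {
    stop_nocall("element ids of the pipeline result and the truth differ")
  }
  canon <- function(gs) {
    s <- lapply(gs, function(g) paste(sort(g), collapse = ","))
    sort(unlist(s))
  }
  exact <- identical(canon(lapply(result$groups, `[[`, "members")),
                     canon(truth$groups))
  inferred <- tally_categories(result$tally)
  truthc <- tally_categories(truth$tally)
  deltas <- inferred - truthc
  list(exact_groups = exact, deltas = deltas, inferred = inferred,
       truth = truthc)
}

# Collapse an event tally into the comparison categories.
tally_categories <- function(tally) {
  leaves <- tally$tree$tip.label
  ins_leaf <- sum(tally$insertions$count[tally$insertions$edge %in% leaves])
  ins_int <- sum(tally$insertions$count) - ins_leaf
  del_leaf <- sum(tally$deletions$count[tally$deletions$edge %in% leaves])
  del_int <- sum(tally$deletions$count) - del_leaf
  c(ins_leaf = ins_leaf, ins_internal = ins_int,
    del_leaf = del_leaf, del_internal = del_int,
    singletons = sum(tally$leaves$singletons),
    missing = sum(tally$leaves$missing),
    duplications = sum(tally$leaves$duplications))
}
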