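#' Filter alignment blocks down to usable synteny anchors
#'
#' A block can only serve as a synteny anchor if it marks a *unique* genomic
#' region.  Blocks are therefore removed when they (a) overlap an element of
#' interest in any species, (b) overlap another block in any species (both
#' members of an overlapping pair are dropped — neither is unique), or
#' (c) score below `min_score`.  Overlap means at least one shared base on
#' the same species and chromosome; abutting half-open intervals do not
#' overlap.  Blocks overlapping an element in one species are discarded in
#' all species.
#'
#' @param blocks `anchor_blocks` data frame from [read_maf()].
#' @param elements Element table (see [read_element_table()]).
#' @param min_score Minimum MAF block score; blocks with `NA` score are kept
#'   at the default `min_score = 0`.
#' @return The retained `anchor_blocks` rows.  The result is idempotent
#'   under re-filtering and contains no overlapping pair.
#' @export
filter_anchors <- function(blocks, elements, min_score = 0) {
  validate_blocks(blocks)
  if (nrow(blocks) == 0L) return(blocks)
  key <- paste0(blocks$species, "\r", blocks$chrom)
  gr_blocks <- GenomicRanges::GRanges(
    seqnames = key,
    ranges = IRanges::IRanges(start = blocks$start + 1, end = blocks$end))
  drop <- rep(FALSE, nrow(blocks))
  if (!is.null(elements) && nrow(elements) > 0L) {
    ekey <- paste0(elements$species, "\r", elements$chrom)
    gr_el <- GenomicRanges::GRanges(
      seqnames = ekey,
      ranges = IRanges::IRanges(start = elements$start + 1,
                                end = elements$end))
    suppressWarnings({
      hits <- GenomicRanges::findOverlaps(gr_blocks, gr_el)
    })
    bad_blocks <- unique(blocks$block_id[S4Vectors::queryHits(hits)])
    drop <- drop | blocks$block_id %in% bad_blocks
  }
  suppressWarnings({
    self <- GenomicRanges::findOverlaps(gr_blocks, drop.self = TRUE,
                                        drop.redundant = TRUE)
  })
  if (length(self) > 0L) {
    ov_rows <- unique(c(S4Vectors::queryHits(self), S4Vectors::subjectHits(self)))
    drop <- drop | blocks$block_id %in% unique(blocks$block_id[ov_rows])
  }
  score_ok <- is.na(blocks$score) | blocks$score >= min_score
  low <- unique(blocks$block_id[!score_ok])
  drop <- drop | blocks$block_id %in% low
  out <- blocks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("anchor_blocks", "data.frame")
  out
}

#' Build the tight-anchor map for a set of elements
#'
#' For each element the *tight anchors* are the closest retained blocks in
#' the element's own genome: upstream, the block with the largest end
#' coordinate not exceeding the element start; downstream, the block with the
#' smallest start coordinate not below the element end (same species and
#' chromosome).  Either side is `NA` where no such block exists (chromosome
#' end or unaligned region); elements on a chromosome with no blocks at all
#' get `(NA, NA)` and are flagged.
#'
#' @param blocks Filtered `anchor_blocks` (see [filter_anchors()]).
#' @param elements Element table.
#' @return Data frame `anchor_map`: `element_id`, `upstream`, `downstream`
#'   (block ids or `NA`), `flagged` (no block on the element's chromosome).
#' @export
build_anchor_map <- function(blocks, elements) {
  if (anyDuplicated(elements$element_id)) {
    stop_nocall("duplicate element_id in element table")
  }
  up <- rep(NA_character_, nrow(elements))
  down <- rep(NA_character_, nrow(elements))
  bkey <- paste0(blocks$species, "\r", blocks$chrom)
  ekey <- paste0(elements$species, "\r", elements$chrom)
  for (k in unique(ekey)) {
    ei <- which(ekey == k)
    bi <- which(bkey == k)
    if (length(bi) == 0L) next
    b <- blocks[bi, , drop = FALSE]
    ord <- order(b$start)
    b <- b[ord, , drop = FALSE]
    # blocks are non-overlapping, so start order equals end order
    iu <- findInterval(elements$start[ei], b$end)
    up[ei] <- ifelse(iu >= 1L, b$block_id[pmax(iu, 1L)], NA_character_)
    id <- findInterval(elements$end[ei] - 1L, b$start) + 1L
    down[ei] <- ifelse(id <= nrow(b), b$block_id[pmin(id, nrow(b))],
                       NA_character_)
  }
  flagged <- is.na(up) & is.na(down) & !(ekey %in% bkey)
  data.frame(element_id = elements$element_id, upstream = up,
             downstream = down, flagged = flagged, stringsAsFactors = FALSE)
}

#' Write or read an anchor map as TSV
#'
#' @param anchor_map Data frame from [build_anchor_map()].
#' @param file Path or connection.
#' @return The file path (write) or the anchor map (read).
#' @export
write_anchor_map <- function(anchor_map, file) {
  write.table(anchor_map, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_anchor_map
#' @export
read_anchor_map <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA")
}
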