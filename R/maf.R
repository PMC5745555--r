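#' Read a MAF (MultiZ) multiple alignment into anchor blocks
#'
#' Parses the MultiZ dialect of the multiple alignment format: each alignment
#' starts with an `a score=...` line followed by one `s` line per species,
#' `s src start size strand srcSize text`, where `src` is
#' `species.chromosome`.  Rows on the minus strand are normalized to
#' forward-strand coordinates using the source-size field, so all coordinates
#' in the result are 0-based, half-open, forward-strand intervals.
#'
#' @param file Path to a MAF file, a connection, or a character vector of
#'   lines (when `text = TRUE`).
#' @param keep_text Keep the per-row alignment text in a `text` column?
#'   Defaults to `FALSE`; the text is not needed for anchor analysis.
#' @param text Interpret `file` as the lines themselves instead of a path.
#' @return A data frame of class `anchor_blocks` with one row per species row
#'   of each block: columns `block_id`, `score`, `species`, `chrom`, `start`,
#'   `end`, `strand` (and `text`).  Block order follows the file.
#' @examples
#' maf <- c("##maf version=1", "a score=100",
#'          "s spA.chr1 10 50 + 1000 NNN", "s spB.chr2 5 50 + 900 NNN")
#' read_maf(maf, text = TRUE)
#' @export
read_maf <- function(file, keep_text = FALSE, text = FALSE) {
  lines <- if (text) file else readLines(file)
  first <- substr(lines, 1L, 2L)
  a_idx <- which(first == "a " | lines == "a")
  s_idx <- which(first == "s ")
  if (length(s_idx) == 0L) {
    return(empty_anchor_blocks(keep_text))
  }
  block_of <- findInterval(s_idx, a_idx)
  if (any(block_of == 0L)) {
    stop_nocall("malformed MAF: 's' line ", s_idx[block_of == 0L][1L],
                " appears before any 'a' line")
  }
  fields <- strsplit(trimws(lines[s_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- s_idx[nf != 7L][1L]
    stop_nocall("malformed MAF 's' line ", bad, ": expected 7 fields")
  }
  mat <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  src <- mat[, 2L]
  dot <- regexpr(".", src, fixed = TRUE)
  if (any(dot < 0L)) {
    stop_nocall("malformed MAF 's' line ", s_idx[dot < 0L][1L],
                ": source name lacks 'species.chromosome' form")
  }
  species <- substr(src, 1L, dot - 1L)
  chrom <- substr(src, dot + 1L, nchar(src))
  start <- suppressWarnings(as.numeric(mat[, 3L]))
  size <- suppressWarnings(as.numeric(mat[, 4L]))
  strand <- mat[, 5L]
  src_size <- suppressWarnings(as.numeric(mat[, 6L]))
  bad <- which(is.na(start) | is.na(size) | is.na(src_size) |
                 !(strand %in% c("+", "-")) | size <= 0)
  if (length(bad)) {
    stop_nocall("malformed MAF 's' line ", s_idx[bad[1L]],
                ": bad coordinates or strand")
  }
  # minus-strand starts are relative to the reverse strand
  fwd_start <- ifelse(strand == "-", src_size - start - size, start)
  fwd_end <- fwd_start + size
  score_txt <- sub("^a\\s*", "", lines[a_idx])
  score <- rep(NA_real_, length(a_idx))
  has <- grepl("score=", score_txt, fixed = TRUE)
  score[has] <- suppressWarnings(
    as.numeric(sub(".*score=([-0-9.eE+]+).*", "\\1", score_txt[has])))
  used <- sort(unique(block_of))
  block_id <- sprintf("blk%06d", match(block_of, used))
  blocks <- data.frame(
    block_id = block_id,
    score = score[block_of],
    species = species, chrom = chrom,
    start = fwd_start, end = fwd_end, strand = strand,
    stringsAsFactors = FALSE
  )
  if (keep_text) blocks$text <- mat[, 7L]
  dup <- duplicated(blocks[, c("block_id", "species")])
  if (any(dup)) {
    stop_nocall("malformed MAF: species '", blocks$species[dup][1L],
                "' occurs twice in block ", blocks$block_id[dup][1L])
  }
  class(blocks) <- c("anchor_blocks", "data.frame")
  blocks
}

empty_anchor_blocks <- function(keep_text = FALSE) {
  blocks <- data.frame(block_id = character(), score = numeric(),
                       species = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       strand = character(), stringsAsFactors = FALSE)
  if (keep_text) blocks$text <- character()
  class(blocks) <- c("anchor_blocks", "data.frame")
  blocks
}

#' Write anchor blocks as a MAF file
#'
#' Inverse of [read_maf()].  If no `text` column is present, each row is
#' written as a run of `N`s of the row's length (sufficient for synteny
#' anchors, whose alignment text is never inspected downstream).
#'
#' @param blocks An `anchor_blocks` data frame.
#' @param file Output path or connection.
#' @param src_sizes Named numeric vector `species.chrom` -> chromosome
#'   length.  Defaults to the largest end coordinate seen per chromosome.
#' @return `file`, invisibly.
#' @export
write_maf <- function(blocks, file, src_sizes = NULL) {
  validate_blocks(blocks)
  src <- paste0(blocks$species, ".", blocks$chrom)
  if (is.null(src_sizes)) {
    src_sizes <- tapply(blocks$end, src, max)
  }
  size <- blocks$end - blocks$start
  # forward intervals back to strand-relative starts
  rel_start <- ifelse(blocks$strand == "-",
                      src_sizes[src] - blocks$end, blocks$start)
  txt <- if ("text" %in% names(blocks)) blocks$text else
    strrep("N", size)
  s_lines <- sprintf("s %s %d %d %s %d %s", src, as.integer(rel_start),
                     as.integer(size), blocks$strand,
                     as.integer(src_sizes[src]), txt)
  ord <- order(match(blocks$block_id, unique(blocks$block_id)))
  per_block <- split(s_lines[ord], blocks$block_id[ord])
  per_block <- per_block[unique(blocks$block_id)]
  first_of <- !duplicated(blocks$block_id)
  score <- blocks$score[first_of]
  a_lines <- ifelse(is.na(score), "a", sprintf("a score=%g", score))
  out <- c("##maf version=1", "",
           unlist(mapply(function(a, s) c(a, s, ""), a_lines, per_block,
                         SIMPLIFY = FALSE), use.names = FALSE))
  writeLines(out, file)
  invisible(file)
}

validate_blocks <- function(blocks) {
  need <- c("block_id", "score", "species", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) {
    stop_nocall("anchor blocks lack column(s): ", paste(miss, collapse = ", "))
  }
  if (any(blocks$start >= blocks$end)) {
    stop_nocall("anchor blocks contain empty or negative intervals")
  }
  invisible(blocks)
}
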