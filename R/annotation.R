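#' Read an element table
#'
#' Loads the loci of interest from a tab-separated table with header columns
#' `species`, `chrom`, `start`, `end`, `strand`, `type`, `pseudo`, `score`
#' and optionally `sequence`.  Coordinates are 0-based, half-open.  When the
#' `sequence` column is absent (or empty for a row), the sequence is sliced
#' from the supplied genomes and reverse-complemented for minus-strand rows,
#' so stored sequences always read 5'->3' along the element.
#'
#' @param file Path, connection, or lines (`text = TRUE`).
#' @param genomes Named list (by species) of FASTA paths or
#'   [Biostrings::DNAStringSet] objects; required when sequences must be
#'   extracted.
#' @param text Interpret `file` as the lines themselves.
#' @return Element data frame: `element_id`, `species`, `chrom`, `start`,
#'   `end`, `strand`, `type`, `pseudo` (logical), `score`, `sequence`.
#'   Element ids are `species:chrom:start-end` unless the table carries an
#'   `element_id` column.
#' @export
read_element_table <- function(file, genomes = NULL, text = FALSE) {
  tab <- if (text) {
    read.table(textConnection(file), sep = "\t", header = TRUE,
               stringsAsFactors = FALSE, comment.char = "")
  } else {
    read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               comment.char = "")
  }
  need <- c("species", "chrom", "start", "end", "strand", "type", "pseudo",
            "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_nocall("element table is missing mandatory column(s): ",
                paste(miss, collapse = ", "))
  }
  el <- data.frame(
    element_id = if ("element_id" %in% names(tab)) as.character(tab$element_id)
                 else paste0(tab$species, ":", tab$chrom, ":", tab$start,
                             "-", tab$end),
    species = as.character(tab$species), chrom = as.character(tab$chrom),
    start = as.numeric(tab$start), end = as.numeric(tab$end),
    strand = as.character(tab$strand), type = as.character(tab$type),
    pseudo = parse_flag(tab$pseudo),
    score = suppressWarnings(as.numeric(tab$score)),
    sequence = if ("sequence" %in% names(tab)) as.character(tab$sequence)
               else NA_character_,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(el[, c("species", "chrom", "start", "end")])
  if (any(dup)) {
    stop_nocall("duplicate locus in element table: ",
                el$species[dup][1L], ":", el$chrom[dup][1L], ":",
                el$start[dup][1L], "-", el$end[dup][1L])
  }
  el$sequence[!nzchar(el$sequence %|NA|% "")] <- NA_character_
  needs_seq <- is.na(el$sequence)
  if (any(needs_seq)) {
    if (is.null(genomes)) {
      stop_nocall("element table lacks sequences for ", sum(needs_seq),
                  " row(s) and no genomes were provided")
    }
    el$sequence[needs_seq] <- extract_sequences(el[needs_seq, , drop = FALSE],
                                                genomes)
  }
  validate_elements(el)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "y", "pseudo")
}

validate_elements <- function(el) {
  if (anyDuplicated(el$element_id)) {
    stop_nocall("element ids are not unique")
  }
  if (any(el$start < 0 | el$start >= el$end)) {
    stop_nocall("element coordinates must satisfy 0 <= start < end")
  }
  seqs <- el$sequence[!is.na(el$sequence)]
  if (length(seqs)) {
    chars <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1L]])
    bad <- setdiff(chars, c("A", "C", "G", "T", "U", "N"))
    if (length(bad)) {
      stop_nocall("element sequences contain invalid character(s): ",
                  paste(bad, collapse = ""))
    }
  }
  el
}

# Slice element sequences out of genome FASTA, honouring strand.
extract_sequences <- function(el, genomes) {
  out <- character(nrow(el))
  for (sp in unique(el$species)) {
    g <- genomes[[sp]]
    if (is.null(g)) stop_nocall("no genome provided for species '", sp, "'")
    if (is.character(g)) g <- Biostrings::readDNAStringSet(g)
    names(g) <- sub("\\s.*", "", names(g))
    rows <- which(el$species == sp)
    for (i in rows) {
      chr <- g[[el$chrom[i]]]
      if (is.null(chr)) {
        stop_nocall("chromosome '", el$chrom[i], "' absent from genome of '",
                    sp, "'")
      }
      if (el$end[i] > length(chr)) {
        stop_nocall("element ", el$element_id[i],
                    " extends beyond its chromosome")
      }
      s <- Biostrings::subseq(chr, start = el$start[i] + 1L, end = el$end[i])
      if (el$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      out[i] <- as.character(s)
    }
  }
  out
}

#' Write an element table as TSV
#'
#' Round-trips with [read_element_table()].
#' @param elements Element data frame.
#' @param file Path or connection.
#' @export
write_element_table <- function(elements, file) {
  write.table(elements, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read tRNAscan-SE tabular output as elements
#'
#' Parses the standard tRNAscan-SE output table.  The type label combines
#' amino acid and anticodon (`"Ala-AGC"`), the pseudogene flag is set when
#' the note column marks the hit as a pseudogene, and coordinates are
#' converted from 1-based inclusive (begin > end on the minus strand) to
#' 0-based half-open forward-strand intervals.
#'
#' @param file Path, connection, or lines (`text = TRUE`).
#' @param species Species identifier to assign to all rows (tRNAscan output
#'   names only the sequence/chromosome).
#' @param genomes Optional genomes for sequence extraction (see
#'   [read_element_table()]); without them `sequence` stays `NA`.
#' @param text Interpret `file` as lines.
#' @return Element data frame; unparseable rows are skipped with a warning
#'   reporting their count.
#' @export
read_trnascan <- function(file, species, genomes = NULL, text = FALSE) {
  lines <- if (text) file else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  drop <- grepl("^(Sequence|Name|-----)", lines) |
    grepl("^\\s*(Name|Sequence)\\b", lines)
  lines <- lines[!drop]
  skipped <- 0L
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 9L || is.na(suppressWarnings(as.numeric(f[3L]))) ||
        is.na(suppressWarnings(as.numeric(f[4L])))) {
      skipped <- skipped + 1L
      next
    }
    begin <- as.numeric(f[3L]); end <- as.numeric(f[4L])
    minus <- begin > end
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, chrom = f[1L],
      start = if (minus) end - 1 else begin - 1,
      end = if (minus) begin else end,
      strand = if (minus) "-" else "+",
      type = paste0(f[5L], "-", f[6L]),
      pseudo = any(grepl("pseudo", f, ignore.case = TRUE)),
      score = as.numeric(f[9L]),
      stringsAsFactors = FALSE
    )
  }
  if (skipped > 0L) {
    warning(skipped, " unparseable tRNAscan-SE row(s) skipped", call. = FALSE)
  }
  finalize_parsed_elements(rows, genomes)
}

#' Read Infernal cmsearch --tblout output as elements
#'
#' The type label is the query model name; a hit is flagged as a pseudogene
#' when its bit score falls below `pseudo_score_threshold`.  Hits on the same
#' strandless locus that overlap by at least 50% of the shorter hit are
#' collapsed, keeping the higher-scoring one.
#'
#' @param file Path, connection, or lines (`text = TRUE`).
#' @param species Species identifier for all rows.
#' @param pseudo_score_threshold Bit-score threshold below which a hit is
#'   marked as a pseudogene.
#' @param genomes Optional genomes for sequence extraction.
#' @param text Interpret `file` as lines.
#' @return Element data frame.
#' @export
read_infernal_tblout <- function(file, species, pseudo_score_threshold = 0,
                                 genomes = NULL, text = FALSE) {
  lines <- if (text) file else readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 16L) stop_nocall("malformed cmsearch tblout row: ", ln)
    from <- as.numeric(f[8L]); to <- as.numeric(f[9L])
    minus <- f[10L] == "-"
    score <- as.numeric(f[15L])
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, chrom = f[1L],
      start = min(from, to) - 1, end = max(from, to),
      strand = if (minus) "-" else "+",
      type = f[3L], pseudo = score < pseudo_score_threshold, score = score,
      stringsAsFactors = FALSE
    )
  }
  el <- do.call(rbind, rows)
  if (!is.null(el) && nrow(el) > 1L) el <- resolve_overlapping_hits(el)
  finalize_parsed_elements(if (is.null(el)) list() else list(el), genomes)
}

# Keep the best-scoring hit per >=50%-reciprocal-overlap group.
resolve_overlapping_hits <- function(el) {
  keep <- rep(TRUE, nrow(el))
  ord <- order(-el$score)
  for (a in ord) {
    if (!keep[a]) next
    for (b in seq_len(nrow(el))) {
      if (b == a || !keep[b]) next
      if (el$species[a] != el$species[b] || el$chrom[a] != el$chrom[b]) next
      ov <- min(el$end[a], el$end[b]) - max(el$start[a], el$start[b])
      shorter <- min(el$end[a] - el$start[a], el$end[b] - el$start[b])
      if (ov >= 0.5 * shorter && el$score[b] <= el$score[a]) {
        keep[b] <- FALSE
      }
    }
  }
  el[keep, , drop = FALSE]
}

finalize_parsed_elements <- function(rows, genomes) {
  if (length(rows) == 0L) {
    return(validate_elements(data.frame(
      element_id = character(), species = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      type = character(), pseudo = logical(), score = numeric(),
      sequence = character(), stringsAsFactors = FALSE)))
  }
  el <- do.call(rbind, rows)
  el$element_id <- paste0(el$species, ":", el$chrom, ":", el$start, "-",
                          el$end)
  el$sequence <- NA_character_
  if (!is.null(genomes)) el$sequence <- extract_sequences(el, genomes)
  el <- el[, c("element_id", "species", "chrom", "start", "end", "strand",
               "type", "pseudo", "score", "sequence")]
  rownames(el) <- NULL
  validate_elements(el)
}
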