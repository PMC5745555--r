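element_tsv <- function(rows, header = TRUE) {
  hd <- "species\tchrom\tstart\tend\tstrand\ttype\tpseudo\tscore\tsequence"
  c(if (header) hd, rows)
}

test_that("element tables parse with pseudogene flags and sequences", {
  lines <- element_tsv(c(
    "spA\tchr1\t10\t18\t+\tAla-AGC\ttrue\t55\tACGTACGT",
    "spA\tchr1\t40\t48\t-\tGly-GCC\tfalse\t60\tTTTTCCCC"))
  el <- read_element_table(lines, text = TRUE)
  expect_equal(el$pseudo, c(TRUE, FALSE))
  expect_equal(el$sequence, c("ACGTACGT", "TTTTCCCC"))
  expect_equal(el$start, c(10, 40))
})

test_that("a missing mandatory column is reported by name", {
  lines <- c("species\tchrom\tstart\tend\tstrand\ttype\tscore",
             "spA\tchr1\t1\t5\t+\tx\t3")
  expect_error(read_element_table(lines, text = TRUE), "pseudo")
})

test_that("duplicate loci are rejected", {
  lines <- element_tsv(c(
    "spA\tchr1\t10\t18\t+\tx\tfalse\t1\tACGT",
    "spA\tchr1\t10\t18\t-\ty\tfalse\t2\tACGT"))
  expect_error(read_element_table(lines, text = TRUE), "duplicate locus")
})

test_that("sequences are extracted from genomes, reverse-complemented on minus", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTTTTGGGG"))
  lines <- c("species\tchrom\tstart\tend\tstrand\ttype\tpseudo\tscore",
             "spA\tchr1\t3\t7\t-\tx\tfalse\t1",
             "spA\tchr1\t0\t4\t+\tx\tfalse\t1")
  el <- read_element_table(lines, text = TRUE, genomes = list(spA = genome))
  expect_equal(el$sequence[2], "AAAA")
  # genomic slice [3,7) = ACGT; minus strand stores its reverse complement
  expect_equal(el$sequence[1], "ACGT")
  expect_equal(
    el$sequence[1],
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGT"))))
})

test_that("coordinates outside the genome are an error", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  lines <- c("species\tchrom\tstart\tend\tstrand\ttype\tpseudo\tscore",
             "spA\tchr1\t4\t20\t+\tx\tfalse\t1")
  expect_error(read_element_table(lines, text = TRUE,
                                  genomes = list(spA = genome)),
               "beyond")
})

test_that("element tables round-trip through write/read", {
  el <- make_elements(
    list("e1", "spA", "chr1", 10, 50, "+", "typeA", FALSE, "ACGTACGT"),
    list("e2", "spB", "chr2", 99, 140, "-", "typeB", TRUE, "GGGGCCCC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_element_table(el, f)
  el2 <- read_element_table(f)
  expect_equal(el2, el)
})

test_that("tRNAscan-SE output converts coordinates and types", {
  lines <- c(
    "Sequence\t\ttRNA\tBounds\t\ttRNA\tAnti\tIntron Bounds\tInf",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    "--------\t------\t-----\t----\t----\t-----\t-----\t---\t-----\t----",
    "chr1 \t1\t100\t172\tAla\tAGC\t0\t0\t66.1",
    "chr1 \t2\t300\t228\tGly\tGCC\t0\t0\t30.2\tpseudo")
  el <- read_trnascan(lines, species = "hg", text = TRUE)
  expect_equal(nrow(el), 2L)
  expect_equal(el$start, c(99, 227))
  expect_equal(el$end, c(172, 300))
  expect_equal(el$strand, c("+", "-"))
  expect_equal(el$type, c("Ala-AGC", "Gly-GCC"))
  expect_equal(el$pseudo, c(FALSE, TRUE))
})

test_that("unparseable tRNAscan rows are skipped with a warning", {
  lines <- c("chr1 \t1\t100\t172\tAla\tAGC\t0\t0\t66.1",
             "garbage row")
  expect_warning(el <- read_trnascan(lines, species = "hg", text = TRUE),
                 "skipped")
  expect_equal(nrow(el), 1L)
})

test_that("Infernal hits are typed by model and flagged by score threshold", {
  lines <- c(
    "#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description",
    "chr1 - YRNA RF00090 cm 1 100 5000 5090 + no 1 0.5 0.1 80.0 1e-20 ! -",
    "chr1 - YRNA RF00090 cm 1 100 7090 7000 - no 1 0.5 0.1 30.0 1e-4 ! -")
  el <- read_infernal_tblout(lines, species = "hg",
                             pseudo_score_threshold = 40, text = TRUE)
  expect_equal(el$type, c("YRNA", "YRNA"))
  expect_equal(el$pseudo, c(FALSE, TRUE))
  expect_equal(el$start, c(4999, 6999))
  expect_equal(el$end, c(5090, 7090))
  expect_equal(el$strand, c("+", "-"))
})

test_that("overlapping Infernal hits keep the best score", {
  lines <- c(
    "chr1 - YRNA RF00090 cm 1 100 5000 5090 + no 1 0.5 0.1 80.0 1e-20 ! -",
    "chr1 - YRNA RF00090 cm 1 100 5040 5130 + no 1 0.5 0.1 30.0 1e-3 ! -")
  el <- read_infernal_tblout(lines, species = "hg", text = TRUE)
  expect_equal(nrow(el), 1L)
  expect_equal(el$score, 80)
})
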