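# Small programmatic fixtures shared across test files.

make_blocks <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(block_id = r[[1]], score = as.numeric(r[[2]]),
               species = r[[3]], chrom = r[[4]],
               start = as.numeric(r[[5]]), end = as.numeric(r[[6]]),
               strand = if (length(r) >= 7) r[[7]] else "+",
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("anchor_blocks", "data.frame")
  df
}

make_elements <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(element_id = r[[1]], species = r[[2]], chrom = r[[3]],
               start = as.numeric(r[[4]]), end = as.numeric(r[[5]]),
               strand = if (length(r) >= 6) r[[6]] else "+",
               type = if (length(r) >= 7) r[[7]] else "typeA",
               pseudo = if (length(r) >= 8) r[[8]] else FALSE,
               score = NA_real_,
               sequence = if (length(r) >= 9) r[[9]] else
                 strrep("ACGT", 10),
               stringsAsFactors = FALSE)
  }))
  df
}

# a deterministic random DNA string
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# adjacency matrix for a path on the given vertex names (induced P4 when
# called with four names)
path_adjacency <- function(ids) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    adj[i, i + 1L] <- adj[i + 1L, i] <- TRUE
  }
  adj
}
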