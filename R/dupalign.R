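#' Duplication-aware order-preserving alignment of two element orders
#'
#' Aligns the genomic orders of a cluster's elements in two species with a
#' Needleman-Wunsch variant in which an element of one order may be matched
#' to a *run* of one or more consecutive elements of the other order.  Only
#' pairs listed in `allowed` (edges of the edited orthology graph) may be
#' matched; matches never cross, which is the intrinsic property of
#' alignments that removes conflicting orthology edges.  A run of length k
#' records k-1 tandem duplications in the run's species.
#'
#' Scoring: each matched pair contributes its edge weight (sequence
#' identity); unmatched elements (gaps) cost 0; opening a duplication run
#' (extending a match to a second consecutive element) costs `run_open`,
#' further extensions cost nothing.  The small opening cost keeps runs from
#' forming when a 1:1 matching scores equally well.
#'
#' @param order_s,order_t Character vectors: element ids in genomic order.
#' @param allowed Data frame with columns `a`, `b`, `weight`: matchable
#'   pairs (unordered) and their weights.
#' @param run_open Cost of opening a duplication run.
#' @return A `dup_alignment`: list with `matches` (list of
#'   `list(s =, t =)` id vectors, one side always length 1),
#'   `unmatched_s`, `unmatched_t`, `dup_s`, `dup_t` (duplication counts
#'   attributed to each side), `score`.
#' @export
duplication_alignment <- function(order_s, order_t, allowed,
                                  run_open = 0.05) {
  n <- length(order_s); m <- length(order_t)
  if (nrow(allowed) > 0L) {
    known <- c(order_s, order_t)
    bad <- !(allowed$a %in% known) | !(allowed$b %in% known)
    if (any(bad)) {
      stop_nocall("allowed pair references element(s) absent from the ",
                  "orders: ", allowed$a[bad][1L], "-", allowed$b[bad][1L])
    }
  }
  w <- matrix(-Inf, n, m, dimnames = list(order_s, order_t))
  for (r in seq_len(nrow(allowed))) {
    a <- allowed$a[r]; b <- allowed$b[r]
    if (a %in% order_s && b %in% order_t) w[a, b] <- allowed$weight[r]
    if (b %in% order_s && a %in% order_t) w[b, a] <- allowed$weight[r]
  }
  NEG <- -Inf
  D <- matrix(0, n + 1L, m + 1L)
  M0 <- matrix(NEG, n + 1L, m + 1L) # S_i matched 1:1 to T_j
  MT <- matrix(NEG, n + 1L, m + 1L) # S_i matched to a run ending at T_j
  MS <- matrix(NEG, n + 1L, m + 1L) # T_j matched to a run ending at S_i
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      wij <- w[i, j]
      if (is.finite(wij)) {
        M0[i + 1L, j + 1L] <- D[i, j] + wij
        MT[i + 1L, j + 1L] <- max(M0[i + 1L, j] - run_open,
                                  MT[i + 1L, j]) + wij
        MS[i + 1L, j + 1L] <- max(M0[i, j + 1L] - run_open,
                                  MS[i, j + 1L]) + wij
      }
      D[i + 1L, j + 1L] <- max(D[i, j + 1L], D[i + 1L, j],
                               M0[i + 1L, j + 1L], MT[i + 1L, j + 1L],
                               MS[i + 1L, j + 1L])
    }
  }
  # traceback; ties prefer 1:1 matches, then runs in T, runs in S, then gaps
  matches <- list()
  i <- n; j <- m
  state <- "D"
  run_s <- integer(0); run_t <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == "D") {
      v <- D[i + 1L, j + 1L]
      if (i > 0L && j > 0L && v == M0[i + 1L, j + 1L]) {
        state <- "M0"
      } else if (i > 0L && j > 0L && v == MT[i + 1L, j + 1L]) {
        state <- "MT"; run_s <- i; run_t <- integer(0)
      } else if (i > 0L && j > 0L && v == MS[i + 1L, j + 1L]) {
        state <- "MS"; run_t <- j; run_s <- integer(0)
      } else if (j > 0L && v == D[i + 1L, j]) {
        j <- j - 1L
      } else {
        i <- i - 1L
      }
    } else if (state == "M0") {
      matches[[length(matches) + 1L]] <- list(s = i, t = j)
      i <- i - 1L; j <- j - 1L
      state <- "D"
    } else if (state == "MT") {
      run_t <- c(j, run_t)
      prev_start <- M0[i + 1L, j] - run_open + w[i, j]
      if (MT[i + 1L, j + 1L] == prev_start) {
        run_t <- c(j - 1L, run_t)
        matches[[length(matches) + 1L]] <- list(s = run_s, t = run_t)
        i <- i - 1L; j <- j - 2L
        state <- "D"
      } else {
        j <- j - 1L
      }
    } else { # MS
      run_s <- c(i, run_s)
      prev_start <- M0[i, j + 1L] - run_open + w[i, j]
      if (MS[i + 1L, j + 1L] == prev_start) {
        run_s <- c(i - 1L, run_s)
        matches[[length(matches) + 1L]] <- list(s = run_s, t = run_t)
        i <- i - 2L; j <- j - 1L
        state <- "D"
      } else {
        i <- i - 1L
      }
    }
  }
  matches <- rev(matches)
  ms <- lapply(matches, function(x) list(s = order_s[x$s], t = order_t[x$t]))
  used_s <- unlist(lapply(matches, `[[`, "s"))
  used_t <- unlist(lapply(matches, `[[`, "t"))
  dup_s <- sum(vapply(matches, function(x) length(x$s) - 1L, 0L))
  dup_t <- sum(vapply(matches, function(x) length(x$t) - 1L, 0L))
  structure(list(
    matches = ms,
    unmatched_s = order_s[setdiff(seq_len(n), used_s)],
    unmatched_t = order_t[setdiff(seq_len(m), used_t)],
    dup_s = dup_s, dup_t = dup_t,
    score = D[n + 1L, m + 1L]
  ), class = "dup_alignment")
}
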