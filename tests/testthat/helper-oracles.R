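# Independent reference implementations used to validate the package's
# dynamic-programming and search code on small instances.  These are
# deliberately brute-force: they enumerate the full solution space.

# --- global alignment identity -------------------------------------------
# Enumerate every global alignment of a and b; score match +1, mismatch -1,
# gap -1.  Return the identity (matches / alignment length) of the best
# alignment under the lexicographic objective (score, matches, -length).
oracle_identity <- function(a, b) {
  a <- strsplit(tolower(a), "")[[1L]]
  b <- strsplit(tolower(b), "")[[1L]]
  best <- c(score = -Inf, matches = -Inf, len = Inf)
  rec <- function(i, j, score, matches, len) {
    if (i > length(a) && j > length(b)) {
      better <- score > best["score"] ||
        (score == best["score"] && (matches > best["matches"] ||
          (matches == best["matches"] && len < best["len"])))
      if (better) best <<- c(score = score, matches = matches, len = len)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      eq <- a[i] == b[j]
      rec(i + 1L, j + 1L, score + if (eq) 1 else -1,
          matches + as.integer(eq), len + 1L)
    }
    if (i <= length(a)) rec(i + 1L, j, score - 1, matches, len + 1L)
    if (j <= length(b)) rec(i, j + 1L, score - 1, matches, len + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  unname(best["matches"] / best["len"])
}

# --- duplication-aware non-crossing matching ------------------------------
# Enumerate all non-crossing run-matchings of two ordered element lists:
# an element of one list may match a run of >= 1 consecutive elements of
# the other (every pair in the run must be allowed); matched pairs score
# their weight, opening a run (length >= 2) costs run_open once.  Returns
# the maximum total score.
oracle_dup_align <- function(order_s, order_t, allowed, run_open = 0.05) {
  w <- matrix(-Inf, length(order_s), length(order_t),
              dimnames = list(order_s, order_t))
  for (r in seq_len(nrow(allowed))) {
    a <- allowed$a[r]; b <- allowed$b[r]
    if (a %in% order_s && b %in% order_t) w[a, b] <- allowed$weight[r]
    if (b %in% order_s && a %in% order_t) w[b, a] <- allowed$weight[r]
  }
  n <- length(order_s); m <- length(order_t)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i > n || j > m) return(0)
    key <- paste0(i, "_", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- max(f(i + 1L, j), f(i, j + 1L)) # leave s_i or t_j unmatched
    # s_i matched to the run t_j .. t_{j+k-1}
    sc <- 0
    for (k in seq_len(m - j + 1L)) {
      if (!is.finite(w[i, j + k - 1L])) break
      sc <- sc + w[i, j + k - 1L]
      cost <- if (k >= 2L) run_open else 0
      best <- max(best, sc - cost + f(i + 1L, j + k))
    }
    # t_j matched to the run s_i .. s_{i+k-1}
    sc <- 0
    for (k in seq_len(n - i + 1L)) {
      if (!is.finite(w[i + k - 1L, j])) break
      sc <- sc + w[i + k - 1L, j]
      cost <- if (k >= 2L) run_open else 0
      best <- max(best, sc - cost + f(i + k, j + 1L))
    }
    memo[[key]] <- best
    best
  }
  f(1L, 1L)
}

# --- random graphs ---------------------------------------------------------
random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      adj[i, j] <- adj[j, i] <- runif(1) < p
    }
  }
  adj
}

# direct P4-free check by enumerating all ordered quadruples
oracle_is_p4_free <- function(adj) {
  n <- nrow(adj)
  if (n < 4L) return(TRUE)
  for (q in combn(n, 4L, simplify = FALSE)) {
    for (perm in list(q, q[c(1, 2, 4, 3)], q[c(1, 3, 2, 4)],
                      q[c(1, 3, 4, 2)], q[c(1, 4, 2, 3)],
                      q[c(1, 4, 3, 2)], q[c(2, 1, 3, 4)],
                      q[c(2, 3, 1, 4)], q[c(2, 4, 1, 3)],
                      q[c(3, 1, 2, 4)], q[c(3, 2, 1, 4)],
                      q[c(2, 1, 4, 3)])) {
      a <- perm[1]; b <- perm[2]; cc <- perm[3]; d <- perm[4]
      if (adj[a, b] && adj[b, cc] && adj[cc, d] &&
          !adj[a, cc] && !adj[a, d] && !adj[b, d]) {
        return(FALSE)
      }
    }
  }
  TRUE
}
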