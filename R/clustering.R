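#' Partition elements into initial candidate co-ortholog clusters
#'
#' Two elements fall into the same initial cluster exactly when they share
#' the identical (upstream, downstream) anchor-block pair.  Elements with no
#' anchors at all (`(NA, NA)`) become flagged singleton clusters.  Every
#' element belongs to exactly one cluster.
#'
#' @param anchor_map Data frame from [build_anchor_map()].
#' @param elements Element table.
#' @return An object of class `syn_clusters`: a list of clusters, each a
#'   list with `cluster_id`, `members` (element ids), `upstream` and
#'   `downstream` (anchor block id sets), `flagged`.
#' @export
initial_partition <- function(anchor_map, elements) {
  if (!all(elements$element_id %in% anchor_map$element_id)) {
    stop_nocall("anchor map does not cover all elements")
  }
  m <- anchor_map[match(elements$element_id, anchor_map$element_id), ]
  ord <- order(elements$species, elements$chrom, elements$start)
  key <- paste(m$upstream %|NA|% "*", m$downstream %|NA|% "*", sep = "\r")
  orphan <- is.na(m$upstream) & is.na(m$downstream)
  key[orphan] <- paste0("orphan\r", elements$element_id[orphan])
  key_levels <- unique(key[ord])
  idx <- split(seq_len(nrow(elements)), factor(key, levels = key_levels))
  clusters <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    clusters[[k]] <- list(
      cluster_id = sprintf("CL%05d", k),
      members = elements$element_id[i],
      upstream = unique(m$upstream[i][!is.na(m$upstream[i])]),
      downstream = unique(m$downstream[i][!is.na(m$downstream[i])]),
      flagged = all(orphan[i])
    )
  }
  structure(clusters, class = "syn_clusters")
}

#' @export
print.syn_clusters <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "members"))
  cat("syn_clusters:", length(x), "clusters,", sum(sizes), "elements,",
      sum(sizes == 1L), "singletons\n")
  invisible(x)
}

#' Cluster assignment table
#'
#' @param clusters A `syn_clusters` object.
#' @return Data frame `element_id`, `cluster_id`.
#' @export
cluster_assignment <- function(clusters) {
  data.frame(
    element_id = unlist(lapply(clusters, `[[`, "members"), use.names = FALSE),
    cluster_id = rep(vapply(clusters, `[[`, "", "cluster_id"),
                     lengths(lapply(clusters, `[[`, "members"))),
    stringsAsFactors = FALSE
  )
}

#' Join candidate clusters across missing anchors
#'
#' Anchor blocks missing from some species (unaligned or low-quality
#' regions) split one true locus cluster into several.  Joining merges
#' cluster pairs whose anchor-projected regions overlap in at least one
#' species, provided that in every checked species (1) the members of the two
#' clusters do not interleave and the left/right orientation is consistent
#' across species, (2) no element of a third cluster lies between them,
#' (3) the merged span does not exceed `max_extent`, and the gap between the
#' outermost element boundaries of the two clusters is at most
#' `max_anchor_distance`.
#'
#' Under the relaxed mode only species having a member in either cluster are
#' checked.  The strict mode additionally requires, in species with members
#' in neither cluster but with anchor rows for both, that no foreign element
#' lies inside the joint anchor-projected region and that this region does
#' not exceed `max_extent`.
#'
#' Merging is greedy: eligible pairs are ranked by the smallest inter-member
#' gap (0 for pairs sharing no species), then lexicographically by cluster
#' id, and scanning repeats to a fixed point.
#'
#' @param clusters `syn_clusters` from [initial_partition()].
#' @param elements Element table.
#' @param blocks Filtered anchor blocks (used for projections).
#' @param mode `"strict"` or `"relaxed"`.
#' @param max_anchor_distance Maximum gap, in bases, between the two
#'   clusters' outermost element boundaries.
#' @param max_extent Maximum merged cluster span, in bases, per species.
#' @return A `syn_clusters` object.
#' @export
join_clusters <- function(clusters, elements, blocks,
                          mode = c("relaxed", "strict"),
                          max_anchor_distance = 5000, max_extent = 50000) {
  mode <- match.arg(mode)
  repeat {
    merged <- join_pass(clusters, elements, blocks, mode,
                        max_anchor_distance, max_extent)
    if (merged$n_merges == 0L) break
    clusters <- merged$clusters
  }
  structure(clusters, class = "syn_clusters")
}

#' @rdname join_clusters
#' @export
join_clusters_strict <- function(clusters, elements, blocks,
                                 max_anchor_distance = 5000,
                                 max_extent = 50000) {
  join_clusters(clusters, elements, blocks, "strict",
                max_anchor_distance, max_extent)
}

#' @rdname join_clusters
#' @export
join_clusters_relaxed <- function(clusters, elements, blocks,
                                  max_anchor_distance = 5000,
                                  max_extent = 50000) {
  join_clusters(clusters, elements, blocks, "relaxed",
                max_anchor_distance, max_extent)
}

# One pass: evaluate every currently eligible cluster pair and merge the
# connected components of the eligibility graph wholesale.  Component-wise
# union is order-independent (merging pairs one at a time can strand a
# fragment when an earlier merge tightens the anchor projection), and the
# similarity-based refinement downstream separates any over-joined members
# again.  Passes repeat to a fixed point.
join_pass <- function(clusters, elements, blocks, mode,
                      max_anchor_distance, max_extent) {
  n <- length(clusters)
  if (n < 2L) return(list(clusters = clusters, n_merges = 0L))
  ctx <- join_context(clusters, elements, blocks)
  cand <- candidate_pairs(ctx)
  if (nrow(cand) == 0L) return(list(clusters = clusters, n_merges = 0L))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    keep[r] <- joinable(cand$i[r], cand$j[r], ctx, mode,
                        max_anchor_distance, max_extent)$ok
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(clusters = clusters, n_merges = 0L))
  # union-find over eligible pairs
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(cand))) {
    a <- find(cand$i[r]); b <- find(cand$j[r])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), roots)
  merged <- lapply(comps, function(ix) {
    if (length(ix) == 1L) return(clusters[[ix]])
    cls <- clusters[ix]
    list(
      cluster_id = min(vapply(cls, `[[`, "", "cluster_id")),
      members = unlist(lapply(cls, `[[`, "members"), use.names = FALSE),
      upstream = unique(unlist(lapply(cls, `[[`, "upstream"))),
      downstream = unique(unlist(lapply(cls, `[[`, "downstream"))),
      flagged = all(vapply(cls, `[[`, TRUE, "flagged"))
    )
  })
  names(merged) <- NULL
  list(clusters = structure(merged, class = "syn_clusters"),
       n_merges = n - length(merged))
}

# Precompute, per (cluster, species+chromosome), member spans and anchor
# projections, plus element indices for betweenness queries.  A cluster's
# region in a genome is the interval between the tightest upstream-anchor end
# and downstream-anchor start; a side with no anchor at all is open (+-Inf),
# while a side whose anchors lack a row in that genome is unknown and falls
# back to the member span (or leaves the region undefined when there are no
# members either).
join_context <- function(clusters, elements, blocks) {
  n <- length(clusters)
  skey_el <- paste0(elements$species, "\r", elements$chrom)
  skey_bl <- paste0(blocks$species, "\r", blocks$chrom)
  skeys <- sort(unique(c(skey_el, skey_bl)))
  nsk <- length(skeys)
  cl_ids <- vapply(clusters, `[[`, "", "cluster_id")
  asg <- cluster_assignment(clusters)
  cl_of_el <- setNames(match(asg$cluster_id, cl_ids), asg$element_id)
  span_lo <- matrix(Inf, n, nsk, dimnames = list(NULL, skeys))
  span_hi <- matrix(-Inf, n, nsk, dimnames = list(NULL, skeys))
  ci <- cl_of_el[elements$element_id]
  si <- match(skey_el, skeys)
  for (r in seq_len(nrow(elements))) {
    span_lo[ci[r], si[r]] <- min(span_lo[ci[r], si[r]], elements$start[r])
    span_hi[ci[r], si[r]] <- max(span_hi[ci[r], si[r]], elements$end[r])
  }
  proj_l <- matrix(NA_real_, n, nsk, dimnames = list(NULL, skeys))
  proj_r <- matrix(NA_real_, n, nsk, dimnames = list(NULL, skeys))
  bsk <- factor(match(skey_bl, skeys), levels = seq_len(nsk))
  bid <- factor(blocks$block_id)
  up_end <- tapply(blocks$end, list(bid, bsk), max)
  dn_start <- tapply(blocks$start, list(bid, bsk), min)
  for (k in seq_len(n)) {
    ub <- intersect(clusters[[k]]$upstream, rownames(up_end))
    db <- intersect(clusters[[k]]$downstream, rownames(dn_start))
    for (s in seq_len(nsk)) {
      if (length(ub) == 0L) {
        proj_l[k, s] <- -Inf # no upstream anchor anywhere: open side
      } else {
        v <- up_end[ub, s]
        if (any(!is.na(v))) proj_l[k, s] <- max(v, na.rm = TRUE)
      }
      if (length(db) == 0L) {
        proj_r[k, s] <- Inf
      } else {
        v <- dn_start[db, s]
        if (any(!is.na(v))) proj_r[k, s] <- min(v, na.rm = TRUE)
      }
    }
  }
  # anchor-rank intervals: blocks keep their input (reference) order, and a
  # cluster occupies the open rank interval between its upstream and
  # downstream anchor sets; missing sides are unbounded
  rank_of <- setNames(seq_along(unique(blocks$block_id)),
                      unique(blocks$block_id))
  rank_lo <- rep(-Inf, n); rank_hi <- rep(Inf, n)
  for (k in seq_len(n)) {
    ub <- clusters[[k]]$upstream; db <- clusters[[k]]$downstream
    ur <- rank_of[ub[ub %in% names(rank_of)]]
    dr <- rank_of[db[db %in% names(rank_of)]]
    if (length(ur)) rank_lo[k] <- min(ur)
    if (length(dr)) rank_hi[k] <- max(dr)
  }
  # species+chromosomes where a cluster leaves any trace (members or
  # flanking-anchor rows); candidates must co-occur somewhere
  trace <- matrix(FALSE, n, nsk)
  trace[cbind(ci, si)] <- TRUE
  row_sk <- match(skey_bl, skeys)
  by_block <- split(row_sk, blocks$block_id)
  for (k in seq_len(n)) {
    fb <- c(clusters[[k]]$upstream, clusters[[k]]$downstream)
    sk <- unique(unlist(by_block[fb], use.names = FALSE))
    trace[k, sk] <- TRUE
  }
  species_of_skey <- sub("\r.*", "", skeys)
  list(clusters = clusters, elements = elements, skeys = skeys,
       species_of_skey = species_of_skey,
       cl_of_el = cl_of_el, span_lo = span_lo, span_hi = span_hi,
       proj_l = proj_l, proj_r = proj_r,
       rank_lo = rank_lo, rank_hi = rank_hi, trace = trace,
       el_by_skey = split(seq_len(nrow(elements)), skey_el))
}

# Pairs of clusters whose open anchor-rank intervals overlap (a shared
# facing anchor -- downstream of one equal to upstream of the other --
# yields touching intervals, which cleanly separate two loci and are not
# candidates) and that leave traces on a common species+chromosome.
candidate_pairs <- function(ctx) {
  n <- length(ctx$clusters)
  lo <- ctx$rank_lo; hi <- ctx$rank_hi
  ord <- order(lo)
  out_i <- integer(0); out_j <- integer(0)
  for (a in seq_len(n - 1L)) {
    ia <- ord[a]
    for (b in seq.int(a + 1L, n)) {
      ib <- ord[b]
      if (lo[ib] >= hi[ia]) {
        if (is.finite(hi[ia])) break else next
      }
      if (max(lo[ia], lo[ib]) < min(hi[ia], hi[ib]) &&
          any(ctx$trace[ia, ] & ctx$trace[ib, ])) {
        out_i <- c(out_i, min(ia, ib)); out_j <- c(out_j, max(ia, ib))
      }
    }
  }
  unique(data.frame(i = out_i, j = out_j))
}

joinable <- function(i, j, ctx, mode, max_anchor_distance, max_extent) {
  fail <- list(ok = FALSE, gap = Inf)
  sk_i <- which(is.finite(ctx$span_lo[i, ]))
  sk_j <- which(is.finite(ctx$span_lo[j, ]))
  sp_i <- ctx$species_of_skey[sk_i]
  sp_j <- ctx$species_of_skey[sk_j]
  # members of one species must sit on a single chromosome for a merge
  shared_sp <- intersect(sp_i, sp_j)
  shared <- intersect(sk_i, sk_j)
  if (!setequal(ctx$species_of_skey[shared], shared_sp)) {
    return(fail) # same species, different chromosomes
  }
  dir <- integer(0)
  gaps <- numeric(0)
  for (s in shared) {
    lo_i <- ctx$span_lo[i, s]; hi_i <- ctx$span_hi[i, s]
    lo_j <- ctx$span_lo[j, s]; hi_j <- ctx$span_hi[j, s]
    if (hi_i <= lo_j) {
      d <- 1L; g <- lo_j - hi_i; gl <- hi_i; gr <- lo_j
    } else if (hi_j <= lo_i) {
      d <- -1L; g <- lo_i - hi_j; gl <- hi_j; gr <- lo_i
    } else {
      return(fail) # members interleave
    }
    if (g > max_anchor_distance) return(fail)
    if (max(hi_i, hi_j) - min(lo_i, lo_j) > max_extent) return(fail)
    if (foreign_between(ctx, s, gl, gr, i, j)) return(fail)
    dir <- c(dir, d)
    gaps <- c(gaps, g)
  }
  if (length(unique(dir)) > 1L) return(fail) # inconsistent orientation
  for (s in setdiff(union(sk_i, sk_j), shared)) {
    lo <- min(ctx$span_lo[i, s], ctx$span_lo[j, s])
    hi <- max(ctx$span_hi[i, s], ctx$span_hi[j, s])
    if (is.finite(lo) && is.finite(hi) && hi - lo > max_extent) return(fail)
    # one cluster has members here; when the other projects a bounded
    # anchor region onto this genome, the members must lie in or near it
    other <- if (s %in% sk_i) j else i
    self <- if (s %in% sk_i) i else j
    pl <- ctx$proj_l[other, s]; pr <- ctx$proj_r[other, s]
    if (!is.na(pl) && !is.na(pr) && is.finite(pl) && is.finite(pr)) {
      if (ctx$span_hi[self, s] < pl - max_anchor_distance ||
          ctx$span_lo[self, s] > pr + max_anchor_distance) {
        return(fail)
      }
    }
  }
  if (mode == "strict") {
    uninvolved <- setdiff(seq_along(ctx$skeys), union(sk_i, sk_j))
    for (s in uninvolved) {
      hl <- min(ctx$proj_l[i, s], ctx$proj_l[j, s])
      hr <- max(ctx$proj_r[i, s], ctx$proj_r[j, s])
      if (is.na(hl) || is.na(hr) || !is.finite(hl) || !is.finite(hr)) next
      if (hr - hl > max_extent) return(fail)
      if (foreign_between(ctx, s, hl, hr, i, j)) return(fail)
    }
  }
  list(ok = TRUE, gap = if (length(gaps)) min(gaps) else 0)
}

# Any element of a third cluster overlapping the open interval (lo, hi)?
foreign_between <- function(ctx, s, lo, hi, i, j) {
  rows <- ctx$el_by_skey[[ctx$skeys[s]]]
  if (is.null(rows) || hi <= lo) return(FALSE)
  el <- ctx$elements
  cl <- ctx$cl_of_el[el$element_id[rows]]
  any(el$start[rows] < hi & el$end[rows] > lo & cl != i & cl != j)
}

#' Export clusters as a TSV table
#'
#' One record per cluster member with its coordinates, type and pseudogene
#' flag.
#'
#' @param clusters `syn_clusters` object.
#' @param elements Element table.
#' @param file Path or connection.
#' @export
write_cluster_table <- function(clusters, elements, file) {
  assign <- cluster_assignment(clusters)
  el <- elements[match(assign$element_id, elements$element_id), ]
  out <- data.frame(cluster_id = assign$cluster_id,
                    element_id = assign$element_id,
                    species = el$species, chrom = el$chrom,
                    start = el$start, end = el$end,
                    type = el$type, pseudo = el$pseudo,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$species, out$start), ]
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
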