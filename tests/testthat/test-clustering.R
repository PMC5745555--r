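# A two-gap, two-species scaffold used by several joining tests:
# anchors b1 [0,100), b2 [1000,1100), b3 [2000,2100) in both species.
scaffold_blocks <- function(drop = character(0)) {
  b <- make_blocks(
    list("b1", 10, "spA", "chr1", 0, 100),
    list("b1", 10, "spB", "chr1", 0, 100),
    list("b2", 10, "spA", "chr1", 1000, 1100),
    list("b2", 10, "spB", "chr1", 1000, 1100),
    list("b3", 10, "spA", "chr1", 2000, 2100),
    list("b3", 10, "spB", "chr1", 2000, 2100))
  b[!(paste(b$block_id, b$species) %in% drop), , drop = FALSE]
}

test_that("elements sharing an anchor pair form one cluster", {
  blocks <- scaffold_blocks()
  el <- make_elements(
    list("eA", "spA", "chr1", 400, 475),
    list("eB", "spB", "chr1", 420, 495),
    list("eA2", "spA", "chr1", 500, 575),  # same-species in-paralog
    list("priv", "spA", "chr1", 1500, 1575)) # its own anchor pair
  am <- build_anchor_map(blocks, el)
  cl <- initial_partition(am, el)
  asg <- cluster_assignment(cl)
  expect_equal(asg$cluster_id[asg$element_id == "eA"],
               asg$cluster_id[asg$element_id == "eB"])
  expect_equal(asg$cluster_id[asg$element_id == "eA"],
               asg$cluster_id[asg$element_id == "eA2"])
  expect_false(asg$cluster_id[asg$element_id == "priv"] %in%
                 asg$cluster_id[asg$element_id != "priv"])
  # every element in exactly one cluster
  expect_setequal(asg$element_id, el$element_id)
  expect_equal(anyDuplicated(asg$element_id), 0L)
})

test_that("elements with no anchors at all become flagged singletons", {
  blocks <- scaffold_blocks()
  el <- make_elements(list("lost", "spA", "chr9", 10, 85),
                      list("lost2", "spA", "chr9", 200, 275))
  am <- build_anchor_map(blocks, el)
  cl <- initial_partition(am, el)
  expect_equal(length(cl), 2L)
  expect_true(all(vapply(cl, `[[`, TRUE, "flagged")))
})

test_that("a fragment split by a lost anchor row is rejoined", {
  # spB lost its b2 row: its element pairs (b1, b3) instead of (b1, b2)
  blocks <- scaffold_blocks(drop = "b2 spB")
  el <- make_elements(
    list("eA", "spA", "chr1", 400, 475),
    list("eB", "spB", "chr1", 420, 495))
  am <- build_anchor_map(blocks, el)
  cl0 <- initial_partition(am, el)
  expect_equal(length(cl0), 2L)
  cl <- join_clusters_relaxed(cl0, el, blocks)
  expect_equal(length(cl), 1L)
  expect_setequal(cl[[1]]$members, c("eA", "eB"))
})

test_that("clusters separated by a shared facing anchor never join", {
  blocks <- scaffold_blocks()
  el <- make_elements(
    list("g1A", "spA", "chr1", 400, 475),
    list("g1B", "spB", "chr1", 420, 495),
    list("g2A", "spA", "chr1", 1500, 1575),
    list("g2B", "spB", "chr1", 1520, 1595))
  am <- build_anchor_map(blocks, el)
  cl0 <- initial_partition(am, el)
  cl <- join_clusters_relaxed(cl0, el, blocks)
  expect_equal(length(cl), 2L)
})

test_that("a foreign element between two clusters makes the pair ineligible", {
  blocks <- scaffold_blocks()
  el <- make_elements(
    list("pA", "spA", "chr1", 150, 225),
    list("zA", "spA", "chr1", 700, 775),
    list("qA", "spA", "chr1", 1500, 1575))
  clusters <- structure(list(
    list(cluster_id = "CL1", members = "pA", upstream = "b1",
         downstream = "b3", flagged = FALSE),
    list(cluster_id = "CL2", members = "qA", upstream = "b1",
         downstream = "b3", flagged = FALSE),
    list(cluster_id = "CL3", members = "zA", upstream = "b1",
         downstream = "b2", flagged = FALSE)
  ), class = "syn_clusters")
  ctx <- syntorth:::join_context(clusters, el, blocks)
  # zA (cluster 3) lies between the members of clusters 1 and 2
  expect_false(syntorth:::joinable(1, 2, ctx, "relaxed", 5000, 50000)$ok)
  # with zA's cluster excluded from the scan the pair is joinable
  ctx2 <- syntorth:::join_context(clusters[c(1, 2)], el[-2, ], blocks)
  expect_true(syntorth:::joinable(1, 2, ctx2, "relaxed", 5000, 50000)$ok)
})

test_that("merges respect the maximum extent", {
  blocks <- scaffold_blocks(drop = "b2 spB")
  el <- make_elements(
    list("eA", "spA", "chr1", 400, 475),
    list("eB", "spB", "chr1", 420, 495),
    list("eB2", "spB", "chr1", 1900, 1975))
  am <- build_anchor_map(blocks, el)
  cl0 <- initial_partition(am, el)
  # eB and eB2 share the pair (b1, b3) in spB, but a tight max_extent
  # prevents any join that would span them
  cl <- join_clusters_relaxed(cl0, el, blocks, max_extent = 300)
  expect_true(length(cl) >= 2L)
})

test_that("relaxed joining ignores species absent from both clusters", {
  # spC carries a foreign element inside the candidate region, but has no
  # member in either cluster: strict refuses, relaxed joins
  blocks <- make_blocks(
    list("b1", 10, "spA", "chr1", 0, 100),
    list("b1", 10, "spB", "chr1", 0, 100),
    list("b1", 10, "spC", "chr1", 0, 100),
    list("b2", 10, "spA", "chr1", 1000, 1100),
    list("b2", 10, "spC", "chr1", 1000, 1100),
    list("b3", 10, "spA", "chr1", 2000, 2100),
    list("b3", 10, "spB", "chr1", 2000, 2100),
    list("b3", 10, "spC", "chr1", 2000, 2100))
  el <- make_elements(
    list("eA", "spA", "chr1", 400, 475),
    list("eB", "spB", "chr1", 420, 495),
    list("zC", "spC", "chr1", 1500, 1575))
  am <- build_anchor_map(blocks, el)
  cl0 <- initial_partition(am, el)
  relaxed <- join_clusters_relaxed(cl0, el, blocks)
  strict <- join_clusters_strict(cl0, el, blocks)
  asg_r <- cluster_assignment(relaxed)
  asg_s <- cluster_assignment(strict)
  expect_equal(asg_r$cluster_id[asg_r$element_id == "eA"],
               asg_r$cluster_id[asg_r$element_id == "eB"])
  expect_false(asg_s$cluster_id[asg_s$element_id == "eA"] ==
                 asg_s$cluster_id[asg_s$element_id == "eB"])
})

test_that("joining preserves the partition and per-species element order", {
  bench <- generate_benchmark(n_anchors = 120, n_elements = 40, seed = 5,
                              anchor_loss = 0.3)
  blocks <- filter_anchors(bench$blocks, bench$elements)
  am <- build_anchor_map(blocks, bench$elements)
  cl0 <- initial_partition(am, bench$elements)
  for (mode in c("strict", "relaxed")) {
    cl <- join_clusters(cl0, bench$elements, blocks, mode)
    asg <- cluster_assignment(cl)
    expect_setequal(asg$element_id, bench$elements$element_id)
    expect_equal(anyDuplicated(asg$element_id), 0L)
  }
})

test_that("strict joining never yields fewer clusters than relaxed", {
  for (seed in 1:3) {
    bench <- generate_benchmark(n_anchors = 120, n_elements = 40,
                                seed = seed, anchor_loss = 0.3)
    blocks <- filter_anchors(bench$blocks, bench$elements)
    am <- build_anchor_map(blocks, bench$elements)
    cl0 <- initial_partition(am, bench$elements)
    n_strict <- length(join_clusters(cl0, bench$elements, blocks, "strict"))
    n_relaxed <- length(join_clusters(cl0, bench$elements, blocks, "relaxed"))
    expect_gte(n_strict, n_relaxed)
    expect_gte(length(cl0), n_strict)
  }
})

test_that("identical inputs give identical strict and relaxed output when all species are involved", {
  blocks <- scaffold_blocks(drop = "b2 spB")
  el <- make_elements(
    list("eA", "spA", "chr1", 400, 475),
    list("eB", "spB", "chr1", 420, 495))
  am <- build_anchor_map(blocks, el)
  cl0 <- initial_partition(am, el)
  r <- join_clusters_relaxed(cl0, el, blocks)
  s <- join_clusters_strict(cl0, el, blocks)
  expect_equal(cluster_assignment(r), cluster_assignment(s))
})
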