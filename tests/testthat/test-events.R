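fig_tree <- function() {
  read_species_tree("(((hg38,panTro4),gorGor3),(ponAbe2,(nomLeu3,rheMac3)));",
                    text = TRUE)
}

test_that("newick parsing accepts polytomies and rejects duplicates", {
  tr <- read_species_tree("((A,B),C);", text = TRUE)
  expect_equal(ape::Ntip(tr), 3L)
  expect_false(ape::getMRCA(tr, c("A", "B")) == ape::Ntip(tr) + 1L)
  poly <- read_species_tree("(A,B,C);", text = TRUE)
  expect_equal(ape::Ntip(poly), 3L)
  expect_error(read_species_tree("((A,B),(A,C));", text = TRUE), "duplicate")
})

tip_labels <- function(tree, node) {
  if (node == 0L) return(tree$tip.label)
  syntorth:::tip_labels_below(tree, node)
}

test_that("insertions are placed on the edge above the LCA", {
  tr <- fig_tree()
  ins <- place_insertion(c("hg38", "panTro4"), tr)
  expect_equal(sort(tip_labels(tr, ins$node)), c("hg38", "panTro4"))
  # all leaves: insertion before the root (virtual edge)
  root_ins <- place_insertion(tr$tip.label, tr)
  expect_equal(root_ins$node, 0L)
  expect_equal(root_ins$label, "root")
  # single species: the leaf edge
  leaf_ins <- place_insertion("hg38", tr)
  expect_equal(leaf_ins$label, "hg38")
})

test_that("species absent from the tree are an error", {
  expect_error(place_insertion("unknown", fig_tree()), "not in tree")
})

test_that("deletions land on maximal empty subtrees", {
  tr <- read_species_tree("((A,B),(C,D));", text = TRUE)
  d1 <- place_deletions(c("A", "C"), tr)
  expect_setequal(d1$label, c("B", "D"))
  d2 <- place_deletions(c("A", "B", "C"), tr)
  expect_equal(d2$label, "D")
  # a whole sigma-free cherry is one deletion, not two
  tr2 <- read_species_tree("((A,(B,C)),(D,E));", text = TRUE)
  d3 <- place_deletions(c("A", "D"), tr2)
  expect_equal(nrow(d3), 2L)
  expect_setequal(d3$n_leaves, c(2L, 1L)) # subtree (B,C) and leaf E
})

test_that("no deletion edge leads to a child of the LCA on resolved trees", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- paste0("s", seq_len(n))
    sigma <- sample(tr$tip.label, sample(2:n, 1))
    ins <- place_insertion(sigma, tr)
    dels <- place_deletions(sigma, tr)
    kids <- syntorth:::node_children(tr, ins$lca)
    expect_false(any(dels$node %in% kids))
    # deleted subtrees are sigma-free and disjoint; with sigma they cover
    # all leaves below the LCA
    del_leaves <- unlist(lapply(dels$node, function(nd)
      syntorth:::tip_labels_below(tr, nd)))
    expect_equal(anyDuplicated(del_leaves), 0L)
    expect_false(any(del_leaves %in% sigma))
    below <- syntorth:::tip_labels_below(tr, ins$lca)
    expect_setequal(c(del_leaves, sigma), below)
  }
})

test_that("deletion subtrees are maximal", {
  set.seed(5)
  for (rep in 1:10) {
    tr <- ape::rtree(8, br = NULL)
    tr$tip.label <- paste0("s", 1:8)
    sigma <- sample(tr$tip.label, 3)
    dels <- place_deletions(sigma, tr)
    # maximality: the parent of every deletion node has sigma below it
    for (nd in dels$node) {
      parent <- tr$edge[tr$edge[, 2] == nd, 1]
      expect_true(any(syntorth:::tip_labels_below(tr, parent) %in% sigma))
    }
  }
})

test_that("leaves without anchor coverage are reclassified as missing data", {
  tr <- read_species_tree("((A,B),(C,D));", text = TRUE)
  blocks <- make_blocks(
    list("u1", 10, "A", "chr1", 0, 100),
    list("u1", 10, "B", "chr1", 0, 100),
    list("u1", 10, "C", "chr1", 0, 100),
    list("d1", 10, "A", "chr1", 500, 600),
    list("d1", 10, "B", "chr1", 500, 600))
  flanking <- list(upstream = "u1", downstream = "d1")
  # D has no row in either flanking block: missing; B is covered upstream
  miss <- classify_missing_data(c("A", "C"), tr, flanking, blocks)
  expect_equal(miss, "D")
  tal <- tally_events(list(list(members = c("eA", "eC"),
                                species = c("A", "C"), dup = numeric(0),
                                flanking = flanking)),
                      tr, make_elements(list("eA", "A", "chr1", 200, 275),
                                        list("eC", "C", "chr1", 200, 275)),
                      blocks)
  expect_equal(tal$leaves$missing[tal$leaves$species == "D"], 1)
  expect_equal(tal$deletions$edge, "B")
})

test_that("missing-data reclassification never changes the insertion edge", {
  tr <- read_species_tree("((A,B),(C,D));", text = TRUE)
  blocks <- make_blocks(list("u1", 10, "A", "chr1", 0, 100),
                        list("d1", 10, "A", "chr1", 500, 600))
  grp <- list(members = c("eA", "eB"), species = c("A", "B"),
              dup = numeric(0),
              flanking = list(upstream = "u1", downstream = "d1"))
  with_blocks <- tally_events(list(grp), tr,
                              make_elements(list("eA", "A", "chr1", 1, 9)),
                              blocks)
  without <- tally_events(list(grp), tr,
                          make_elements(list("eA", "A", "chr1", 1, 9)),
                          blocks = NULL)
  expect_equal(with_blocks$insertions, without$insertions)
})

test_that("remolding and divergent pairs are reported per the threshold", {
  sq <- strrep("ACGTACGTAC", 8)
  sq_div <- strrep("GGTTCCAAGG", 8)
  el <- make_elements(
    list("r1", "spA", "chr1", 100, 175, "+", "Ala-AGC", FALSE, sq),
    list("r2", "spB", "chr1", 100, 175, "+", "Gly-GCC", FALSE, sq),
    list("d1", "spA", "chr1", 300, 375, "+", "Val-AAC", FALSE, sq),
    list("d2", "spB", "chr1", 300, 375, "+", "Val-AAC", FALSE, sq_div),
    list("alone", "spA", "chr1", 900, 975, "+", "Ala-AGC", FALSE, sq))
  clusters <- structure(list(
    list(cluster_id = "CL1", members = c("r1", "r2"),
         upstream = character(0), downstream = character(0), flagged = FALSE),
    list(cluster_id = "CL2", members = c("d1", "d2"),
         upstream = character(0), downstream = character(0), flagged = FALSE),
    list(cluster_id = "CL3", members = "alone",
         upstream = character(0), downstream = character(0), flagged = FALSE)
  ), class = "syn_clusters")
  rem <- detect_remolding(clusters, el, threshold = 0.8)
  expect_equal(nrow(rem), 2L)
  r <- rem[rem$cluster_id == "CL1", ]
  expect_equal(r$kind, "remolding")
  expect_gte(r$identity, 0.8)
  d <- rem[rem$cluster_id == "CL2", ]
  expect_equal(d$kind, "divergent-same-type")
  expect_lt(d$identity, 0.8)
  # singleton clusters contribute nothing
  expect_false("CL3" %in% rem$cluster_id)
})

test_that("same type above threshold and distinct types below are silent", {
  sq <- strrep("ACGTACGTAC", 8)
  sq_div <- strrep("GGTTCCAAGG", 8)
  el <- make_elements(
    list("s1", "spA", "chr1", 100, 175, "+", "Ala-AGC", FALSE, sq),
    list("s2", "spB", "chr1", 100, 175, "+", "Ala-AGC", FALSE, sq),
    list("s3", "spC", "chr1", 300, 375, "+", "Gly-GCC", FALSE, sq_div))
  clusters <- structure(list(
    list(cluster_id = "CL1", members = c("s1", "s2", "s3"),
         upstream = character(0), downstream = character(0), flagged = FALSE)
  ), class = "syn_clusters")
  rem <- detect_remolding(clusters, el, threshold = 0.8)
  expect_equal(nrow(rem), 0L)
})

test_that("one insertion is tallied per group", {
  tr <- read_species_tree("((A,B),(C,D));", text = TRUE)
  groups <- list(
    list(members = c("x1", "x2", "x3", "x4"),
         species = c("A", "B", "C", "D"), dup = numeric(0), flanking = NULL),
    list(members = "y1", species = "A", dup = numeric(0), flanking = NULL),
    list(members = c("z1", "z2"), species = c("A", "B"),
         dup = c(A = 1), flanking = NULL))
  el <- make_elements(list("e", "A", "chr1", 1, 9))
  tal <- tally_events(groups, tr, el)
  expect_equal(sum(tal$insertions$count), length(groups))
  expect_equal(tal$insertions$count[tal$insertions$edge == "root"], 1)
  expect_equal(tal$leaves$singletons[tal$leaves$species == "A"], 1)
  expect_equal(tal$leaves$duplications[tal$leaves$species == "A"], 1)
  expect_equal(sum(tal$deletions$count), 0)
})
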