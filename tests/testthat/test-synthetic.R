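test_that("identical seeds give identical benchmarks", {
  b1 <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 9,
                           anchor_loss = 0.2)
  b2 <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 9,
                           anchor_loss = 0.2)
  expect_identical(b1$blocks, b2$blocks)
  expect_identical(b1$elements, b2$elements)
  expect_identical(b1$truth$groups, b2$truth$groups)
  b3 <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 10,
                           anchor_loss = 0.2)
  expect_false(identical(b1$elements, b3$elements))
})

test_that("placements are shared across noise levels for one seed", {
  b0 <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 4,
                           anchor_loss = 0)
  b4 <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 4,
                           anchor_loss = 0.4)
  expect_identical(b0$elements, b4$elements)
  expect_identical(b0$truth$groups, b4$truth$groups)
})

test_that("without noise every anchor spans every species", {
  b <- generate_benchmark(n_anchors = 60, n_elements = 20, n_species = 6,
                          seed = 2, anchor_loss = 0)
  expect_equal(length(unique(b$blocks$block_id)), 60L)
  expect_equal(nrow(b$blocks), 60L * 6L)
})

test_that("anchor loss removes roughly the requested fraction of rows", {
  b <- generate_benchmark(n_anchors = 200, n_elements = 20, seed = 3,
                          anchor_loss = 0.4)
  frac <- 1 - nrow(b$blocks) / (200 * 6)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.5)
})

test_that("dup_fraction 0 leaves every species single-copy per group", {
  b <- generate_benchmark(n_anchors = 120, n_elements = 40, seed = 6,
                          dup_fraction = 0)
  for (g in b$truth$group_records) {
    el <- b$elements[match(g$members, b$elements$element_id), ]
    expect_true(all(table(el$species) == 1L))
  }
  expect_true(all(vapply(b$truth$group_records,
                         function(g) length(g$dup) == 0L, TRUE)))
})

test_that("placement modes control the species ranges", {
  ball <- generate_benchmark(n_anchors = 60, n_elements = 15, seed = 8,
                             placement = "homologous-all", dup_fraction = 0)
  expect_true(all(vapply(ball$truth$group_records,
                         function(g) length(g$species) == 6L, TRUE)))
  brand <- generate_benchmark(n_anchors = 60, n_elements = 15, seed = 8,
                              placement = "random", dup_fraction = 0)
  expect_true(all(vapply(brand$truth$group_records,
                         function(g) length(g$species) == 1L, TRUE)))
})

test_that("between-type template identity stays below 0.6", {
  b <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 12)
  types <- unique(b$elements$type)
  seqs <- vapply(types, function(t)
    b$elements$sequence[b$elements$type == t][1], "")
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in seq.int(i + 1L, length(seqs))) {
      expect_lt(pairwise_identity(seqs[i], seqs[j]), 0.6)
    }
  }
})

test_that("evaluating the truth against itself is perfect", {
  b <- generate_benchmark(n_anchors = 60, n_elements = 20, seed = 13)
  fake_result <- list(groups = b$truth$group_records, tally = b$truth$tally)
  ev <- evaluate_benchmark(fake_result, b$truth)
  expect_true(ev$exact_groups)
  expect_true(all(ev$deltas == 0))
})

test_that("mismatched element ids are an error", {
  b <- generate_benchmark(n_anchors = 60, n_elements = 10, seed = 14)
  bad <- list(groups = list(list(members = "nonsense")),
              tally = b$truth$tally)
  expect_error(evaluate_benchmark(bad, b$truth), "ids")
})

test_that("written benchmark files reproduce the in-memory pipeline run", {
  dir <- withr::local_tempdir()
  b <- generate_benchmark(n_anchors = 50, n_elements = 15, seed = 21,
                          anchor_loss = 0.2, write_dir = dir)
  expect_true(file.exists(b$files$maf))
  expect_true(all(file.exists(unlist(b$files$genomes))))
  # file-based run equals the in-memory run
  genomes <- as.list(b$files$genomes)
  res_file <- run_pipeline(b$files$maf, b$files$elements,
                           tree = b$files$tree, genomes = genomes)
  res_mem <- run_pipeline(b$blocks, b$elements, tree = b$tree)
  groups_of <- function(res) {
    canon <- lapply(res$groups, function(g) paste(sort(g$members),
                                                  collapse = ","))
    sort(unlist(canon))
  }
  expect_equal(groups_of(res_file), groups_of(res_mem))
  expect_equal(res_file$tally$insertions, res_mem$tally$insertions)
  expect_equal(res_file$tally$leaves, res_mem$tally$leaves)
})
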