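test_that("edge lists are symmetrised, deduplicated and validated", {
  gidx <- node_index(c("g1", "g2"), "gene")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2", "g2\tg1"), f)
  A <- read_edge_list(f, "symmetric", gidx)
  expect_equal(as.matrix(A), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  oidx <- node_index(c("o1", "o2"), "outlying")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\to1", f2)
  B <- read_edge_list(f2, "bipartite", node_index("g1", "gene"), oidx)
  expect_equal(as.matrix(B), matrix(c(1, 0), 1), ignore_attr = TRUE)

  # unknown id and empty file are hard errors
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tgX", f3)
  expect_error(read_edge_list(f3, "symmetric", gidx), "gX")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  file.create(f4)
  expect_error(read_edge_list(f4, "symmetric", gidx), "empty")
})

test_that("duplicate edges collapse to the distinct-pair count", {
  set.seed(11)
  gidx <- node_index(sprintf("g%02d", 1:20), "gene")
  oidx <- node_index(sprintf("o%02d", 1:20), "outlying")
  i <- sample(20, 50, replace = TRUE)
  j <- sample(20, 50, replace = TRUE)
  dup <- sample(40, 10)
  i <- c(i, i[dup]); j <- c(j, j[dup])
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(gidx$ids[i], oidx$ids[j], sep = "\t"), f)
  A <- read_edge_list(f, "bipartite", gidx, oidx)
  # set-based oracle: count distinct (i, j) pairs
  expect_equal(sum(A), length(unique(paste(i, j))))
  expect_true(all(A@x == 1))
})

test_that("attribute tables reindex, round-trip, and reject bad input", {
  gidx <- node_index(c("g1", "g2", "g3"), "gene")
  X <- matrix(round(rnorm(12), 3), 3, 4,
              dimnames = list(gidx$ids, paste0("f", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_attribute_table(X[c(3, 1, 2), ], f)  # shuffled row order
  expect_equal(read_attribute_table(f, gidx), X)

  # missing gene is an error, not imputed
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_attribute_table(X[1:2, ], f2)
  expect_error(read_attribute_table(f2, gidx), "missing node 'g3'")

  # non-numeric cell names row and column
  tab <- readLines(f)
  tab[2] <- sub("\t[^\t]*$", "\tabc", tab[2])
  writeLines(tab, f)
  expect_error(read_attribute_table(f, gidx), "row 1, column 'f4'")
})

test_that("scores are written sorted with stable id tie-breaks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(f, c("g1", "gB", "gA"), c(0.9, 0.5, 0.5), labels = c(1, NA, 0))
  out <- read_scores(f)
  expect_equal(out$gene_id, c("g1", "gA", "gB"))  # tie: gA before gB
  # round trip preserves ordering
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_scores(f2, out$gene_id, out$score, out$label)
  expect_equal(read_scores(f2), out)
  expect_error(write_scores(f, c("g1"), c(0.1, 0.2)), "length")
})

test_that("label files round-trip and keep the three sets disjoint", {
  gidx <- node_index(sprintf("g%d", 1:6), "gene")
  ls <- labeled_gene_set(c("g1", "g2"), c("g5"), gidx)
  expect_setequal(ls$unlabeled, c("g3", "g4", "g6"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(ls, f)
  ls2 <- read_labels(f, gidx)
  expect_equal(ls2$positives, ls$positives)
  expect_equal(ls2$negatives, ls$negatives)
  expect_error(labeled_gene_set(c("g1"), c("g1"), gidx), "both")
})

test_that("permuted labels keep set sizes but shuffle membership", {
  gidx <- node_index(sprintf("g%d", 1:20), "gene")
  ls <- labeled_gene_set(sprintf("g%d", 1:6), sprintf("g%d", 7:12), gidx)
  lp <- permute_labels(ls, seed = 4)
  expect_length(lp$positives, 6)
  expect_setequal(c(lp$positives, lp$negatives),
                  c(ls$positives, ls$negatives))
  expect_false(identical(sort(lp$positives), sort(ls$positives)))
})

test_that("run configuration round-trips through YAML and validates", {
  cfg <- run_config(hidden_dims = c(32L, 16L), epochs = 5L, alpha = 0.3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2, cfg)
  expect_error(run_config(alpha = 1.5), "alpha")
  expect_error(run_config(dropout_default = 1), "dropout")
  expect_error(run_config(use_gene_gene = FALSE, use_outlying = FALSE,
                          use_mirna = FALSE), "at least one network")
})
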