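test_that("contig plurality reassignment follows the stated tie-breaks", {
  labels <- c(1L, 1L, 1L, 2L)
  ids <- rep("c1", 4)
  expect_identical(reassign_by_contig(labels, ids), rep(1L, 4))

  # contig already consistent: fixpoint
  labels <- c(2L, 2L, 2L)
  expect_identical(reassign_by_contig(labels, rep("x", 3)), labels)

  # tie within the contig: the globally larger cluster wins
  labels <- c(1L, 1L, 2L, 2L, 2L, 2L, 2L)
  ids <- c("t", "t", "t", "t", "o", "o", "o")
  expect_identical(reassign_by_contig(labels, ids)[1:4], rep(2L, 4))

  # still tied globally: the smaller label wins
  labels <- c(1L, 2L, 1L, 2L)
  ids <- c("t", "t", "u", "v")
  expect_identical(reassign_by_contig(labels, ids)[1:2], c(1L, 1L))
})

test_that("reassignment is idempotent and never adds labels", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    labels <- sample.int(5, n, replace = TRUE)
    ids <- sample(paste0("c", 1:7), n, replace = TRUE)
    once <- reassign_by_contig(labels, ids)
    expect_identical(reassign_by_contig(once, ids), once)
    expect_lte(length(unique(once)), length(unique(labels)))
  }
})

test_that("the bp filter keeps clusters at the threshold and never empties", {
  ids <- c(rep("a", 2), rep("b", 2))
  lens <- c(a = 4800, b = 20000)
  asg <- filter_small_clusters(c(1L, 1L, 2L, 2L), ids, lens)
  expect_identical(asg$retained, 2L)                  # 4800 bp -> outlier
  expect_identical(asg$outlier_contigs, "a")

  lens["a"] <- 5000                                   # exactly the threshold
  asg <- filter_small_clusters(c(1L, 1L, 2L, 2L), ids, lens)
  expect_identical(asg$retained, c(1L, 2L))

  asg <- filter_small_clusters(rep(1L, 2), rep("a", 2), c(a = 3000))
  expect_identical(asg$retained, 1L)                  # largest kept as safeguard

  expect_error(filter_small_clusters(c(1L, 2L), rep("a", 2), c(a = 10)),
               "contig-consistent")
})

test_that("bp totals are conserved and lowering the threshold is monotone", {
  set.seed(15)
  for (i in 1:10) {
    ncontig <- sample(4:10, 1)
    ids <- rep(paste0("c", 1:ncontig), each = 3)
    lens <- stats::setNames(sample(500:20000, ncontig), paste0("c", 1:ncontig))
    labels <- rep(sample.int(4, ncontig, replace = TRUE), each = 3)
    prev <- NULL
    for (thr in c(20000, 5000, 1000, 0)) {
      asg <- filter_small_clusters(labels, ids, lens, min_cluster_bp = thr)
      expect_equal(sum(asg$cluster_bp) + asg$outlier_bp, sum(lens))
      if (!is.null(prev)) expect_gte(length(asg$retained), prev)
      prev <- length(asg$retained)
    }
  }
})
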