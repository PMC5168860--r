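test_that("Ward clustering recovers separated blobs and is deterministic", {
  set.seed(41)
  pts <- rbind(cbind(rnorm(30), rnorm(30)), cbind(rnorm(30, 50), rnorm(30)))
  lab <- ward_clusters(pts, 2)
  expect_equal(length(unique(lab[1:30])), 1)
  expect_equal(length(unique(lab[31:60])), 1)
  expect_false(lab[1] == lab[31])

  expect_identical(ward_clusters(pts, 2), lab)
  expect_equal(sort(unique(ward_clusters(pts, nrow(pts)))), 1:nrow(pts))
  expect_error(ward_clusters(pts, 100), "exceeds")
})

test_that("Davies-Bouldin matches hand values and the direct formula", {
  # two singleton clusters: zero scatter
  expect_equal(davies_bouldin(rbind(c(0, 0), c(5, 5)), c(1, 2)), 0)

  # hand-computable configuration: scatter 1 around centroids 10 apart
  pts <- rbind(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)),
               cbind(10 + c(1, -1, 0, 0), c(0, 0, 1, -1)))
  expect_equal(davies_bouldin(pts, rep(1:2, each = 4)), 0.2)

  # moving centroids closer at fixed scatter worsens the index
  pts2 <- pts; pts2[5:8, 1] <- pts2[5:8, 1] - 5
  expect_gt(davies_bouldin(pts2, rep(1:2, each = 4)), 0.2)

  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 0)), c(1, 2)), "coincident")
  expect_error(davies_bouldin(pts, rep(1, 8)), "at least two")

  set.seed(42)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    coords <- cbind(rnorm(n), rnorm(n))
    labels <- sample.int(sample(2:4, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_lt(abs(davies_bouldin(coords, labels) -
                  brute_davies_bouldin(coords, labels)), 1e-10)
  }
})

test_that("cleansing picks k by Davies-Bouldin and exports a partition", {
  smp <- mixture_sample(c(0.3, 0.7), seed = 13, total_bp = 100000)
  sig <- signature_matrix(smp, n = 200)
  emb <- embed_signatures(sig, seed = 13)
  dir <- withr::local_tempdir()
  res <- cleanse(smp$contigs, emb, sig$provenance, sig$contig_lengths,
                 output_dir = dir, sample_name = "mix")
  expect_equal(res$chosen_k, 2)
  expect_false(res$inconclusive)
  # exported records partition the input exactly
  exported <- unlist(lapply(res$files, function(f) names(read_contigs(f))))
  expect_setequal(exported, names(smp$contigs))
  expect_equal(anyDuplicated(exported), 0)
  # clusters align with the genome of origin
  purity <- cluster_purity(res$clusters, smp$truth, sig$contig_lengths)
  expect_true(all(purity >= 0.95))
})

test_that("forced cleansing collapses to the inconclusive path when contigs are atomic", {
  # a single contig can never split: plurality reassignment collapses every
  # Ward cut to one cluster, so cleansing reports inconclusive and exports
  # the whole assembly as one file
  set.seed(3)
  one <- c(solo = paste(sample(c("A", "C", "G", "T"), 60000, TRUE), collapse = ""))
  sig <- signature_matrix(one, n = 150)
  emb <- embed_signatures(sig, seed = 3)
  dir <- withr::local_tempdir()
  res <- cleanse(one, emb, sig$provenance, sig$contig_lengths,
                 output_dir = dir, sample_name = "solo")
  expect_true(res$inconclusive)
  expect_true(is.na(res$chosen_k))
  expect_length(res$files, 1)
  expect_setequal(names(read_contigs(res$files[1])), names(one))
})
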