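test_that("dip detector flags bimodal embeddings and spares single blobs", {
  set.seed(2)
  bimodal <- rbind(cbind(rnorm(250), rnorm(250)),
                   cbind(rnorm(250, 4), rnorm(250)))
  expect_true(dip_detector(bimodal, seed = 1)$contaminated)

  # type-I control: a single isotropic blob stays quiet on nearly every seed
  quiet <- 0
  for (s in 1:10) {
    set.seed(s)
    blob <- cbind(rnorm(500), rnorm(500))
    if (!dip_detector(blob, seed = 1)$contaminated) quiet <- quiet + 1
  }
  expect_gte(quiet, 9)

  # a 5-point satellite next to a 500-point blob is invisible to the dip
  set.seed(4)
  pts <- rbind(cbind(rnorm(500), rnorm(500)), cbind(rnorm(5, 8, .05), rnorm(5, 8, .05)))
  expect_false(dip_detector(pts, seed = 1)$contaminated)
})

test_that("CC detector counts mutual-kNN components with post-processing", {
  set.seed(6)
  two <- rbind(cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
               cbind(rnorm(20, 20, 0.1), rnorm(20, 20, 0.1)))
  ids <- block_contigs(40, per = 10)
  r <- cc_detector(two, ids, uniform_bp(ids))
  expect_true(r$contaminated)
  expect_equal(r$detail, 2)

  one <- cbind(rnorm(30, 0, 0.1), rnorm(30, 0, 0.1))
  ids1 <- block_contigs(30, per = 10)
  r1 <- cc_detector(one, ids1, uniform_bp(ids1))
  expect_false(r1$contaminated)
  expect_equal(r1$detail, 1)

  # overlapping elongated cloud: one component despite two generating centres
  over <- rbind(cbind(rnorm(250), rnorm(250)), cbind(rnorm(250, 4), rnorm(250)))
  ids2 <- block_contigs(500)
  expect_false(cc_detector(over, ids2, uniform_bp(ids2))$contaminated)
})

test_that("mutual-kNN components agree with a union-find oracle", {
  set.seed(9)
  for (i in 1:12) {
    n <- sample(c(20, 60, 200), 1)
    k <- sample(c(3, 5, 9), 1)
    coords <- cbind(rnorm(n, sample(0:8, 1)), rnorm(n))
    got <- scscreen:::mutual_knn_edges(coords, k)
    want <- brute_mutual_edges(coords, k)
    norm <- function(e) if (nrow(e) == 0) e else
      unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
    expect_equal(norm(got), norm(want), ignore_attr = TRUE)
    # component partition equality
    memb_got <- uf_components(n, got)
    memb_want <- uf_components(n, want)
    expect_identical(memb_got, memb_want)
  }
})

test_that("sub-threshold satellite clusters do not flag contamination", {
  set.seed(8)
  pts <- rbind(cbind(rnorm(60, 0, .1), rnorm(60, 0, .1)),
               cbind(rnorm(10, 30, .1), rnorm(10, 30, .1)))
  ids <- c(rep("main1", 30), rep("main2", 30), rep("tiny", 10))
  bp <- c(main1 = 40000, main2 = 40000, tiny = 3000)   # satellite under 5000 bp
  r <- cc_detector(pts, ids, bp)
  expect_false(r$contaminated)
  expect_identical(r$assignment$outlier_contigs, "tiny")
  # raising the satellite's bp over the threshold flips the verdict
  bp["tiny"] <- 6000
  expect_true(cc_detector(pts, ids, bp)$contaminated)
})
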