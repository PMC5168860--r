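test_that("bootstrap folds subsample reproducibly without replacement", {
  folds <- make_folds(1000, B = 10, fraction = 0.75, seed = 4)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 750))
  expect_true(all(vapply(folds, anyDuplicated, 0L) == 0))
  expect_false(identical(folds[[1]], folds[[2]]))

  expect_true(all(lengths(make_folds(4, fraction = 0.75, seed = 1)) == 3))

  expect_identical(make_folds(100, seed = 9), make_folds(100, seed = 9))
  expect_false(identical(make_folds(100, seed = 9), make_folds(100, seed = 10)))
})

test_that("the verdict rule uses strict thresholds", {
  expect_identical(scscreen:::verdict(0.1, 0.2), "clean")
  expect_identical(scscreen:::verdict(0.8, 0.3), "contaminated")
  expect_identical(scscreen:::verdict(0.5, 0.1), "warning")
  # boundaries: exactly 0.25 is not clean; exactly 0.75 is not contaminated
  expect_identical(scscreen:::verdict(0.25, 0.0), "warning")
  expect_identical(scscreen:::verdict(0.75, 0.0), "warning")
  expect_identical(scscreen:::verdict(0.76, 0.0), "contaminated")
  expect_identical(scscreen:::verdict(0.24, 0.24), "clean")
})

test_that("confidences are fold fractions and reflect cluster structure", {
  # two tight composition groups: every fold should flag both detectors
  set.seed(31)
  x <- rbind(matrix(rnorm(150 * 12, 0, 0.3), 150),
             matrix(rnorm(150 * 12, 4, 0.3), 150))
  sig <- fake_signatures(x[sample(300), ])
  conf <- estimate_confidence(sig, B = 5, seed = 2)
  expect_identical(conf$status, "contaminated")
  expect_equal(conf$dip_confidence, 1)
  expect_equal(conf$cc_confidence, 1)
  expect_true(all(conf$folds$rows == 225))
  expect_true(conf$dip_confidence * 5 == round(conf$dip_confidence * 5))

  conf0 <- estimate_confidence(blob_signatures(n = 300, seed = 3), B = 5, seed = 2)
  expect_identical(conf0$status, "clean")
  expect_equal(conf0$cc_confidence, 0)
})

test_that("parallel fold execution reproduces serial results", {
  set.seed(55)
  x <- rbind(matrix(rnorm(60 * 8, 0, 0.3), 60), matrix(rnorm(60 * 8, 4, 0.3), 60))
  sig <- fake_signatures(x[sample(120), ])
  serial <- estimate_confidence(sig, B = 3, seed = 11, threads = 1)
  forked <- estimate_confidence(sig, B = 3, seed = 11, threads = 2)
  expect_identical(serial$folds, forked$folds)
  expect_identical(serial$status, forked$status)
})

test_that("estimate_confidence is reproducible and degrades gracefully", {
  sig <- blob_signatures(n = 120, seed = 8)
  c1 <- estimate_confidence(sig, B = 3, seed = 5)
  c2 <- estimate_confidence(sig, B = 3, seed = 5)
  expect_identical(c1$folds, c2$folds)

  # pathologically few rows: every fold fails to embed -> warning + diagnostic
  tiny <- fake_signatures(matrix(runif(4 * 6), 4))
  conf <- suppressWarnings(estimate_confidence(tiny, B = 3, seed = 1))
  expect_identical(conf$status, "warning")
  expect_match(conf$diagnostic, "folds failed")
})
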