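test_that("genome models validate their parameters", {
  m <- genome_model("g", gc = 0.4)
  expect_equal(unname(m$base_probs), c(0.3, 0.2, 0.2, 0.3))
  expect_error(genome_model("g"), "give")
  expect_error(genome_model("g", gc = 0.4, base_probs = rep(0.25, 4)), "either")
  expect_error(genome_model("g", base_probs = c(1, 1, 0, 0) / 3), "summing to 1")
  expect_error(genome_model("g", gc = 0.5, total_bp = 100, contig_min = 500),
               "smaller than")
})

test_that("generated assemblies hit their composition and length laws", {
  m <- genome_model("g", gc = 0.5)   # default 500 kb
  smp <- generate_sample(m, seed = 1)
  seqs <- paste(smp$contigs, collapse = "")
  gc <- mean(strsplit(seqs, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)

  lens <- nchar(smp$contigs)
  expect_true(all(lens >= 5000 & lens <= 50000))
  expect_gte(sum(lens), 500000)
  expect_true(all(names(smp$truth) == names(smp$contigs)))

  # per-base frequencies within 3 sigma of the multinomial
  m2 <- genome_model("h", base_probs = c(0.1, 0.2, 0.3, 0.4), total_bp = 200000)
  smp2 <- generate_sample(m2, seed = 2)
  tab <- table(factor(strsplit(paste(smp2$contigs, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  n <- sum(tab)
  for (b in 1:4) {
    p <- c(0.1, 0.2, 0.3, 0.4)[b]
    expect_lt(abs(tab[[b]] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("generation is byte-deterministic per seed", {
  m <- list(genome_model("a", gc = 0.3, total_bp = 30000),
            genome_model("b", gc = 0.7, total_bp = 30000))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_sample(generate_sample(m, seed = 5), f1)
  write_sample(generate_sample(m, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  write_sample(generate_sample(m, seed = 6), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("order-1 models realise their transition structure", {
  # strongly self-transitioning chain: long homopolymer stretches
  tr <- matrix(0.02, 4, 4) + diag(rep(0.92, 4))
  m <- genome_model("mk", base_probs = rep(0.25, 4), transition = tr,
                    total_bp = 20000, contig_min = 5000, contig_max = 10000)
  smp <- generate_sample(m, seed = 3)
  s <- strsplit(smp$contigs[[1]], "")[[1]]
  same <- mean(s[-1] == s[-length(s)])
  expect_gt(same, 0.85)   # expected 0.92 under the model, 0.25 under order-0
})

test_that("the truth table export is usable", {
  smp <- mixture_sample(c(0.3, 0.7), seed = 2, total_bp = 20000)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tr <- withr::local_tempfile(fileext = ".tsv")
  write_sample(smp, fa, tr)
  truth <- read.delim(tr)
  expect_setequal(truth$contig_id, names(smp$contigs))
  expect_setequal(unique(truth$genome_id), c("g1", "g2"))
  expect_identical(read_contigs(fa), smp$contigs)
})
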