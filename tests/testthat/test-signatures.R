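test_that("FASTA parsing normalises records and rejects degenerate input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "GGGG"), fa)
  ctg <- read_contigs(fa)
  expect_identical(ctg, c(a = "ACGT", b = "GGGG"))

  writeLines(c(">lc some description", "acgt"), fa)
  expect_identical(unname(read_contigs(fa)[1]), "ACGT")
  expect_identical(names(read_contigs(fa)), "lc")

  writeLines(character(), fa)
  expect_error(read_contigs(fa), "no records")

  writeLines(c(">dup", "ACGT", ">dup", "AAAA"), fa)
  expect_error(read_contigs(fa), "dup")
})

test_that("window width follows the assembly-size rule with clamping", {
  cfg <- window_config(rep(1000, 1000), n = 1000)   # 1 Mb total
  expect_equal(cfg$w, 1000)
  expect_equal(cfg$dw, 500)

  cfg <- window_config(c(5000, 3000, 2000), n = 10)
  expect_equal(cfg$w, 1000)
  expect_equal(cfg$dw, 500)

  cfg <- window_config(5, n = 1000)                 # degenerate, clamped
  expect_equal(cfg$w, 1)
  expect_equal(cfg$dw, 1)

  expect_error(window_config(integer(), n = 10), "no contig")
})

test_that("canonical k-mer classes match brute-force reverse-complement pairing", {
  expect_equal(canonical_kmer_map(4)$n_classes, 136)
  expect_equal(canonical_kmer_map(1)$n_classes, 2)    # A~T, C~G: GC content
  expect_equal(canonical_kmer_map(2)$n_classes, 10)

  for (k in c(2, 4)) {
    bases <- c("A", "C", "G", "T")
    words <- apply(do.call(expand.grid, rep(list(bases), k))[, k:1, drop = FALSE],
                   1, paste, collapse = "")
    canon <- pmin(words, vapply(words, revcomp, ""))
    map <- canonical_kmer_map(k)
    expect_equal(map$n_classes, length(unique(canon)))
    expect_identical(map$classes, sort(unique(canon)))
    # every word maps to the class of its canonical representative
    expect_identical(map$classes[map$class_of], unname(canon[order(words)]))
  }
})

test_that("sliding windows cover contigs per the overlap rule", {
  cfg <- window_config(10000, n = 10)   # w = 1000, dw = 500
  sp <- sliding_windows(10000, cfg)
  expect_equal(nrow(sp), 19)
  expect_equal(unlist(sp[1, ]), c(start = 0, end = 1000))
  expect_equal(unlist(sp[19, ]), c(start = 9000, end = 10000))

  expect_equal(sliding_windows(700, cfg), data.frame(start = 0L, end = 700L))
  expect_equal(nrow(sliding_windows(1000, cfg)), 1)   # exact fit
})

test_that("window signatures count canonical k-mers and skip ambiguity", {
  map <- canonical_kmer_map(4)
  v <- window_signature("AAAAA", map)
  expect_equal(unname(v["AAAA"]), 1)
  expect_equal(sum(v), 1)

  v <- window_signature("ACGT", map)                  # self-reverse-complement
  expect_equal(unname(v["ACGT"]), 1)

  v <- window_signature("AANCGTT", map)               # only CGTT valid -> AACG
  expect_equal(unname(v["AACG"]), 1)

  expect_null(window_signature("NNNNNN", map))
})

test_that("signature matrices assemble with provenance and drop rules", {
  ctg <- c(a = paste(rep("ACGT", 2500), collapse = ""),
           b = paste(rep("GGCA", 2500), collapse = ""))
  sig <- signature_matrix(ctg, n = 20)                # w = 1000, dw = 500
  expect_equal(nrow(sig$freq), 38)                    # 19 windows per contig
  expect_equal(ncol(sig$freq), 136)
  expect_identical(unique(sig$provenance$contig_id), c("a", "b"))
  expect_true(all(abs(rowSums(sig$freq) - 1) < 1e-9))
  expect_true(all(sig$freq >= 0))

  sig1 <- signature_matrix(c(tiny = "ACGT"), n = 1)  # single minimal window
  expect_equal(nrow(sig1$freq), 1)

  expect_error(signature_matrix(c(x = strrep("N", 5000))), "no usable sequence")

  mix <- c(good = strrep("ACGTTGCA", 500), bad = strrep("N", 3000))
  sig2 <- signature_matrix(mix, n = 4)
  expect_false("bad" %in% sig2$provenance$contig_id)
  expect_true(all(sig2$dropped$contig_id == "bad"))
})

test_that("signatures are strand-invariant and row counts follow the window formula", {
  set.seed(42)
  map <- canonical_kmer_map(4)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T", "N"), 300,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    v1 <- window_signature(w, map)
    v2 <- window_signature(revcomp(w), map)
    expect_identical(v1, v2)
  }
  for (i in 1:10) {
    lens <- sample(50:5000, sample(2:6, 1))
    ctg <- stats::setNames(
      vapply(lens, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                            replace = TRUE), collapse = ""), ""),
      paste0("c", seq_along(lens)))
    n <- sample(c(5, 20, 50), 1)
    cfg <- window_config(lens, n = n)
    expected <- sum(vapply(lens, function(l) {
      if (l < cfg$w) 1L else as.integer((l - cfg$w) %/% cfg$dw + 1L)
    }, integer(1)))
    sig <- signature_matrix(ctg, cfg = cfg)
    expect_equal(nrow(sig$freq) + nrow(sig$dropped), expected)
  }
})

test_that("signature TSV export round-trips", {
  ctg <- c(a = strrep("ACGTTGCA", 100))
  sig <- signature_matrix(ctg, n = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), nrow(sig$freq))
  expect_identical(names(back)[1:3], c("contig_id", "start", "end"))
  expect_equal(as.matrix(back[, -(1:3)]), sig$freq, ignore_attr = TRUE)
})
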