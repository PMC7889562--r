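test_that("make_genome is seeded, uniform, and validates lengths", {
  g1 <- make_genome(c(chrA = 300000L, chrB = 200000L), seed = 1)
  g2 <- make_genome(c(chrA = 300000L, chrB = 200000L), seed = 1)
  g3 <- make_genome(c(chrA = 300000L, chrB = 200000L), seed = 2)
  expect_identical(g1$sequences, g2$sequences)
  expect_false(identical(g1$sequences, g3$sequences))
  expect_equal(g1$total_length, 500000)
  big <- make_genome(c(chr1 = 1000000L), seed = 3)
  gc <- mean(strsplit(big$sequences[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.005)
  expect_error(make_genome(c(chr1 = 0L)), "positive")
})

test_that("evolve hits the requested divergence and composes multiplicatively", {
  g <- make_genome(c(chr1 = 100000L), seed = 4)
  s <- g$sequences[[1]]
  expect_identical(evolve(s, 0, seed = 5), s)
  identity_pct <- function(a, b) {
    100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  e10 <- evolve(s, 10, seed = 6)
  expect_lt(abs(identity_pct(s, e10) - 90), 0.5)
  e10b <- evolve(s, 10, seed = 7)
  expect_lt(abs(identity_pct(e10, e10b) - 81), 1)   # approx multiplicative
  withindel <- evolve(s, 5, evolution_parameters(indel_rate = 1e-3), seed = 8)
  expect_false(nchar(withindel) == nchar(s))
})

test_that("fusion pairs record their breakpoint and degenerate case", {
  fp <- make_fusion_pair(c(chrA = 5000L, chrB = 3000L), 5, seed = 9)
  expect_named(fp$reference$sequences, c("chrA", "chrB"))
  expect_named(fp$sister$sequences, "chrF")
  expect_equal(nchar(fp$sister$sequences[["chrF"]]), 8000)
  expect_equal(fp$manifest$breakpoint, 5000)
  fp0 <- make_fusion_pair(c(chrA = 2000L, chrB = 1000L), 0, seed = 10)
  expect_identical(fp0$sister$sequences[["chrF"]],
                   paste0(fp0$reference$sequences[["chrA"]],
                          fp0$reference$sequences[["chrB"]]))
  expect_error(make_fusion_pair(c(a = 1000L, b = 1000L, c = 1000L)),
               "exactly two")
})

test_that("tandem arrays land at the requested genome fraction", {
  g <- make_genome(c(chr1 = 200000L), seed = 11)
  sp <- spike_tandem_array(g, 138L, target_fraction = 0.01, seed = 12)
  expect_equal(sp$manifest$monomer_length, 138)
  expect_equal(nchar(sp$manifest$monomer), 138)
  expect_lt(abs(sp$manifest$realized_fraction - 0.01), 138 / 200000)
  expect_equal(sp$genome$total_length,
               200000 + sp$manifest$copies * 138)
  # regression: insertions into chromosomes longer than 1 Mb must not
  # truncate the tail (substring() default end is 1e6)
  gbig <- make_genome(c(chr1 = 2000000L), seed = 111)
  spbig <- spike_tandem_array(gbig, 138L, target_fraction = 0.0021,
                              seed = 112)
  expect_equal(spbig$genome$total_length,
               2000000 + spbig$manifest$copies * 138)
  same <- spike_tandem_array(g, 138L, copies = 0, seed = 13)
  expect_identical(same$genome$sequences, g$sequences)
  expect_error(spike_tandem_array(g, 138L, target_fraction = 0.5),
               "20%")
})

test_that("read simulation matches the closed-form pair count and is exact", {
  g <- make_genome(c(chr1 = 300000L), seed = 14)
  reads <- simulate_reads(g, coverage = 30, seed = 15)
  expect_equal(reads$n_pairs, round(30 * 300000 / 302))
  expect_equal(unique(nchar(reads$r1)), 151)
  # error-free reads are perfect substrings of the genome or its reverse
  # complement
  rc <- revcomp(g$sequences[[1]])
  for (r in reads$r1[seq(1, reads$n_pairs, length.out = 50)]) {
    expect_true(grepl(r, g$sequences[[1]], fixed = TRUE) ||
                  grepl(r, rc, fixed = TRUE))
  }
  expect_error(simulate_reads(g, 10, insert_mean = 100), "insert mean")
})

test_that("identical seeds give byte-identical FASTQ output", {
  g <- make_genome(c(chr1 = 50000L), seed = 16)
  r1 <- simulate_reads(g, 5, error_rate = 0.01, seed = 17)
  r2 <- simulate_reads(g, 5, error_rate = 0.01, seed = 17)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_fastq_pair(r1, f1, f2)
  write_fastq_pair(r2, f3, f4)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f3)[[1]])
  expect_identical(tools::md5sum(f2)[[1]], tools::md5sum(f4)[[1]])
  back <- load_fastq_pair(f1, f2)
  expect_identical(back$r1, r1$r1)
  expect_identical(back$r2, r1$r2)
})

test_that("spiked microsatellites are recovered by the annotator", {
  g <- make_genome(c(chr1 = 20000L), seed = 18)
  sp <- spike_microsatellite(g, "GA", units = 15, n_loci = 3, seed = 19)
  for (i in seq_len(nrow(sp$manifest$loci))) {
    locus <- sp$manifest$loci[i, ]
    window <- substr(sp$genome$sequences[[locus$chromosome]],
                     locus$position - 5, locus$position + 40)
    expect_gt(nrow(annotate_microsatellites(window, "GA")), 0)
  }
})
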