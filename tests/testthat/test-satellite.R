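test_that("sample_and_trim is seeded, trims, and drops N-rich pairs", {
  g <- make_genome(c(chr1 = 60000L), seed = 70)
  reads <- simulate_reads(g, 10, seed = 71)
  s1 <- sample_and_trim(reads, 100, trim_to = 142, seed = 7)
  s2 <- sample_and_trim(reads, 100, trim_to = 142, seed = 7)
  expect_identical(s1$r1, s2$r1)
  expect_equal(s1$n_pairs, 100)
  expect_true(all(nchar(s1$r1) == 142))
  expect_true(all(nchar(s1$r2) == 142))
  expect_error(sample_and_trim(reads, reads$n_pairs + 1), "exceeds")
  expect_error(sample_and_trim(reads, 0), "positive")

  noisy <- reads
  noisy$r1[1:5] <- strrep("N", 151)
  dropped <- sample_and_trim(noisy, noisy$n_pairs, seed = 8)
  expect_equal(dropped$n_dropped_n, 5)
  expect_equal(dropped$n_pairs, reads$n_pairs - 5)
})

test_that("repeat fraction is near zero without repeats and recovers a spike", {
  # scaled to 500 kb (from the 1-Mb statement) to keep the suite fast;
  # the +/-0.02 recovery band is unchanged
  g <- make_genome(c(chr1 = 500000L), seed = 72)
  reads <- simulate_reads(g, 30, seed = 73)
  rf <- kmer_repeat_fraction(reads)
  expect_lt(rf$repeat_fraction, 0.02)

  element <- rand_seq(1000)
  s <- g$sequences[[1]]
  spiked <- paste0(substr(s, 1, 450000), strrep(element, 50))
  g2 <- genome_assembly(c(chr1 = spiked))
  reads2 <- simulate_reads(g2, 30, seed = 74)
  rf2 <- kmer_repeat_fraction(reads2)
  expect_lt(abs(rf2$repeat_fraction - 0.10), 0.02)
  expect_error(kmer_repeat_fraction(reads, k = 200), "read length")
})

test_that("monomer length recovery is exact on error-free reads (20 trials)", {
  set.seed(75)
  monomers <- sample(50:500, 20)
  for (i in seq_along(monomers)) {
    m <- monomers[i]
    g <- make_genome(c(chr1 = 80000L), seed = 100 + i)
    sp <- spike_tandem_array(g, m, copies = 25L, seed = 200 + i)
    reads <- simulate_reads(sp$genome, coverage = 35, seed = 300 + i)
    rep <- detect_satellite(reads)
    expect_true(rep$detected)
    expect_equal(rep$monomer_length, m)
    # consensus equals the planted monomer up to rotation and strand
    truth <- c(rotations_of(sp$manifest$monomer),
               rotations_of(revcomp(sp$manifest$monomer)))
    expect_true(rep$consensus %in% truth)
  }
})

test_that("monomer length survives 1% read error in at least 18/20 trials", {
  set.seed(76)
  monomers <- sample(50:500, 20)
  exact <- 0
  for (i in seq_along(monomers)) {
    g <- make_genome(c(chr1 = 80000L), seed = 400 + i)
    sp <- spike_tandem_array(g, monomers[i], copies = 25L, seed = 500 + i)
    reads <- simulate_reads(sp$genome, coverage = 35, error_rate = 0.01,
                            seed = 600 + i)
    rep <- detect_satellite(reads)
    if (rep$detected && rep$monomer_length == monomers[i]) exact <- exact + 1
  }
  expect_gte(exact, 18)
})

test_that("detection is invariant to the rotation used to build the array", {
  g <- make_genome(c(chr1 = 60000L), seed = 77)
  monomer <- with_rotation <- NULL
  set.seed(78)
  monomer <- rand_seq(138)
  rotated <- paste0(substring(monomer, 40), substring(monomer, 1, 39))
  reports <- lapply(c(monomer, rotated), function(mono) {
    s <- g$sequences[[1]]
    spiked <- genome_assembly(c(chr1 = paste0(substr(s, 1, 30000),
                                              strrep(mono, 25),
                                              substr(s, 30001, nchar(s)))))
    detect_satellite(simulate_reads(spiked, 35, seed = 79))
  })
  expect_equal(reports[[1]]$monomer_length, 138)
  expect_equal(reports[[1]]$monomer_length, reports[[2]]$monomer_length)
  expect_equal(reports[[1]]$consensus, reports[[2]]$consensus)
})

test_that("abundance scales linearly with spiked copy number", {
  fracs <- vapply(c(15L, 30L, 60L), function(copies) {
    g <- make_genome(c(chr1 = 150000L), seed = 80)
    sp <- spike_tandem_array(g, 100L, copies = copies, seed = 81)
    detect_satellite(simulate_reads(sp$genome, 30, seed = 82))$abundance_fraction
  }, numeric(1))
  expect_lt(abs(fracs[2] / fracs[1] - 2), 0.4)
  expect_lt(abs(fracs[3] / fracs[1] - 4), 0.8)
})

test_that("a repeat-free genome yields no satellite", {
  g <- make_genome(c(chr1 = 100000L), seed = 83)
  reads <- simulate_reads(g, 25, seed = 84)
  rep <- detect_satellite(reads)
  expect_false(rep$detected)
  expect_true(is.na(rep$monomer_length))
  expect_equal(rep$abundance_fraction, 0)
})

test_that("satellite reports round-trip to key/value text and FASTA", {
  g <- make_genome(c(chr1 = 60000L), seed = 85)
  sp <- spike_tandem_array(g, 120L, copies = 25L, seed = 86)
  rep <- detect_satellite(simulate_reads(sp$genome, 30, seed = 87))
  kv <- tempfile(); fa <- tempfile(fileext = ".fasta")
  write_satellite_report(rep, kv, consensus_fasta = fa)
  lines <- readLines(kv)
  expect_true(any(grepl("^monomer_length=120$", lines)))
  cons <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(cons[[1]]), rep$consensus)
})
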