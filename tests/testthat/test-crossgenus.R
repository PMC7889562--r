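# Shared small-world fixture: a two-chromosome reference and read sets from
# relatives at several divergences.  Built once per file.
cg <- local({
  ref <- make_genome(c(chrA = 40000L, chrB = 25000L), seed = 90)
  reads_at <- function(div, seed) {
    tgt <- genome_assembly(c(
      tA = evolve(ref$sequences[["chrA"]], div, seed = seed),
      tB = evolve(ref$sequences[["chrB"]], div, seed = seed + 1L)))
    simulate_reads(tgt, coverage = 6, error_rate = 0.002, seed = seed + 2L)
  }
  probes <- design_probes(ref, parse_region("chrA:1-40000", ref),
                          params = design_parameters(stride = 9L),
                          quiet = TRUE)
  list(ref = ref, probes = probes, reads_at = reads_at)
})

test_that("syntenic read selection is faithful to read origin", {
  onlyA <- simulate_reads(genome_assembly(cg$ref$sequences["chrA"]),
                          coverage = 4, seed = 91)
  binA <- select_syntenic_reads(onlyA, cg$ref, "chrA")
  mapped <- nrow(best_hits(search_hits(
    all_reads(onlyA), cg$ref, evalue_max = 1e-5)))
  expect_gt(binA$n_reads, 0.95 * mapped)
  binB <- select_syntenic_reads(onlyA, cg$ref, "chrB")
  expect_equal(binB$n_reads, 0)

  rand <- structure(list(r1 = vapply(rep(151, 200), rand_seq, character(1)),
                         r2 = vapply(rep(151, 200), rand_seq, character(1)),
                         read_length = 151L, trimmed_length = NA_integer_,
                         n_pairs = 200L), class = "read_set")
  expect_equal(select_syntenic_reads(rand, cg$ref, "chrA")$n_reads, 0)
  expect_error(select_syntenic_reads(onlyA, cg$ref, "chrZ"), "absent")
})

test_that("reads from a 15%-diverged relative bin at ~85% identity", {
  reads <- cg$reads_at(15, seed = 92)
  bin <- select_syntenic_reads(reads, cg$ref, "chrA")
  expect_gt(bin$n_reads, 100)
  expect_gt(bin$mean_identity, 80)
  expect_lt(bin$mean_identity, 92)
})

test_that("repeat screening rejects satellite and microsatellite probes", {
  set.seed(93)
  sat <- rand_seq(138)
  lib <- structure(list(satellites = sat, motifs = "GA",
                        kmer_codes = numeric(0), k = 17L),
                   class = "repeat_library")
  seqs <- c(paste0(rand_seq(16), "GAGAGAGAGAGA", rand_seq(17)),  # msat
            substr(strrep(sat, 2), 60, 104),                     # satellite
            rand_seq(45))                                        # unique
  df <- data.frame(probe_id = c("msat", "sat", "uniq"), chromosome = "chr1",
                   start = c(0, 100, 200), end = c(45, 145, 245),
                   strand = "+", sequence = seqs, predicted_tm = 70,
                   offtarget_fail = FALSE, homeolog_fail = FALSE,
                   msat_flagged = FALSE, selected = TRUE,
                   rejection_reason = "none", stringsAsFactors = FALSE)
  out <- screen_probes_against_repeats(df, lib)
  expect_setequal(out$probes$probe_id, "uniq")
  expect_setequal(out$rejected$probe_id, c("msat", "sat"))
  expect_equal(out$rejected$reason[out$rejected$probe_id == "msat"], "msat")

  empty_lib <- structure(list(satellites = character(0), motifs = character(0),
                              kmer_codes = numeric(0), k = 17L),
                         class = "repeat_library")
  expect_warning(out2 <- screen_probes_against_repeats(df, empty_lib),
                 "empty repeat library")
  expect_equal(nrow(out2$probes), 3)
})

test_that("validation rate collapses with divergence", {
  probes <- cg$probes
  bin5 <- select_syntenic_reads(cg$reads_at(5, 94), cg$ref, "chrA")
  v5 <- validate_probes_on_syntenic_reads(probes, bin5)
  expect_gt(v5$n_validated / nrow(probes$probes), 0.8)

  bin30 <- select_syntenic_reads(cg$reads_at(30, 96), cg$ref, "chrA")
  if (bin30$n_reads > 0) {
    v30 <- validate_probes_on_syntenic_reads(probes, bin30)
    expect_lt(v30$n_validated / nrow(probes$probes), 0.05)
  }
  # unrelated reads give an empty bin, which is an error for validation
  rand <- structure(list(r1 = vapply(rep(151, 50), rand_seq, character(1)),
                         r2 = vapply(rep(151, 50), rand_seq, character(1)),
                         read_length = 151L, trimmed_length = NA_integer_,
                         n_pairs = 50L), class = "read_set")
  empty_bin <- select_syntenic_reads(rand, cg$ref, "chrA")
  expect_error(validate_probes_on_syntenic_reads(probes, empty_bin), "empty")
})

test_that("raising homology_min never increases the validated count", {
  bin <- select_syntenic_reads(cg$reads_at(10, 97), cg$ref, "chrA")
  counts <- vapply(c(75, 85, 92, 97), function(hm) {
    validate_probes_on_syntenic_reads(
      cg$probes, bin, crossgenus_parameters(homology_min = hm))$n_validated
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the full workflow keeps monotone stage counts and is deterministic", {
  reads <- cg$reads_at(8, 98)
  run1 <- run_crossgenus_workflow(cg$ref, reads, "chrA",
                                  design_params = design_parameters(stride = 9L),
                                  quiet = TRUE)
  sc <- run1$stage_counts
  expect_true(sc$repeat_screen <= sc$designed)
  expect_true(sc$validated <= sc$repeat_screen)
  expect_gt(sc$validated, 0)
  run2 <- run_crossgenus_workflow(cg$ref, reads, "chrA",
                                  design_params = design_parameters(stride = 9L),
                                  quiet = TRUE)
  expect_identical(run1$probes$probes$probe_id, run2$probes$probes$probe_id)
})
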