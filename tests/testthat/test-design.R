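test_that("tiling emits the closed-form candidate counts", {
  g <- genome_assembly(c(chr1 = rand_seq(300)))
  p <- design_parameters()
  expect_equal(nrow(tile_candidates(g, parse_region("chr1:1-43", g), p)), 1)
  expect_equal(nrow(tile_candidates(g, parse_region("chr1:1-42", g), p)), 0)
  cand <- tile_candidates(g, parse_region("chr1:101-200", g), p)
  expect_equal(nrow(cand), sum(100 - (43:47) + 1))   # 280
  expect_true(all(cand$end - cand$start == nchar(cand$sequence)))
  expect_true(all(nchar(cand$sequence) >= 43 & nchar(cand$sequence) <= 47))
  expect_identical(cand$sequence[1],
                   substr(g$sequences[["chr1"]], 101, 143))
})

test_that("windows containing N are rejected when exclude_n", {
  set.seed(40)
  s <- rand_seq(200)
  substr(s, 100, 100) <- "N"
  g <- genome_assembly(c(chr1 = s))
  cand <- tile_candidates(g, parse_region("chr1:1-200", g))
  expect_false(any(grepl("N", cand$sequence)))
  expect_false(any(cand$start < 100 & cand$end > 99))
  allN <- genome_assembly(c(chr1 = strrep("N", 200)))
  cand2 <- tile_candidates(allN, parse_region("chr1:1-200", allN))
  expect_equal(nrow(cand2), 0)
  expect_gt(attr(cand2, "n_rejected_n"), 0)
})

test_that("off-target screen rejects duplicated loci and passes unique ones", {
  set.seed(41)
  base <- rand_seq(20000)
  dup <- paste0(base, substr(base, 1001, 1100), rand_seq(500))
  g <- genome_assembly(c(chr1 = dup))
  reg <- parse_region("chr1:1001-1100", g)
  cand <- tile_candidates(g, reg)
  scr <- screen_offtarget(cand, g)
  expect_true(all(scr$offtarget_fail))      # verbatim second copy
  expect_true(all(scr$rejection_reason == "offtarget"))
  # verbatim copy: hottest off-target Tm is at (or within an extension
  # nibble of) the perfect-match Tm
  expect_true(all(scr$offtarget_best_tm >= scr$predicted_tm - 5))

  g2 <- genome_assembly(c(chr1 = base))
  scr2 <- screen_offtarget(tile_candidates(g2, parse_region("chr1:1001-1100", g2)), g2)
  expect_false(any(scr2$offtarget_fail))
  expect_true(all(is.na(scr2$offtarget_best_tm)))
})

test_that("homeolog filter keeps single strong hits and tags the rest", {
  set.seed(42)
  g <- genome_assembly(c(chr1 = rand_seq(3000)))
  reg <- parse_region("chr1:501-1500", g)
  cand <- screen_offtarget(tile_candidates(g, reg), g)
  src <- substr(g$sequences[["chr1"]], 501, 1500)

  hom95 <- genome_assembly(c(chrH = paste0(rand_seq(500),
                                           evolve(src, 5, seed = 43),
                                           rand_seq(500))))
  kept <- filter_homeolog(cand, hom95)
  expect_gt(mean(kept$rejection_reason == "none"), 0.9)

  unrelated <- genome_assembly(c(chrH = rand_seq(2000)))
  none <- filter_homeolog(cand, unrelated)
  expect_true(all(none$rejection_reason == "homeolog_none"))

  # two copies of the source region: duplication forces two hits
  two <- genome_assembly(c(chrH = paste0(src, rand_seq(200), src)))
  multi <- filter_homeolog(cand, two)
  expect_equal(sum(multi$rejection_reason == "none"), 0)
  expect_true(all(multi$rejection_reason == "homeolog_multi"))
})

test_that("relaxing the E-value cutoff never decreases homeolog passes", {
  set.seed(46)
  g <- genome_assembly(c(chr1 = rand_seq(3000)))
  reg <- parse_region("chr1:501-1500", g)
  cand <- screen_offtarget(tile_candidates(g, reg), g)
  hom <- genome_assembly(c(chrH = evolve(substr(g$sequences[["chr1"]], 501, 1500),
                                         8, seed = 47)))
  passes <- vapply(c(1e-12, 1e-8, 1e-5, 1e-2), function(cut) {
    f <- filter_homeolog(cand, hom, design_parameters(evalue_cutoff = cut))
    sum(f$rejection_reason == "none")
  }, numeric(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("non-overlap selection follows the documented tie-breaks", {
  mk <- function(starts, ends) {
    n <- length(starts)
    df <- data.frame(probe_id = sprintf("p%d", seq_len(n)),
                     chromosome = "chr1", start = starts, end = ends,
                     strand = "+", sequence = strrep("A", 45),
                     predicted_tm = 70, offtarget_fail = FALSE,
                     homeolog_fail = FALSE, msat_flagged = FALSE,
                     selected = FALSE, rejection_reason = "none",
                     stringsAsFactors = FALSE)
    df$offtarget_best_tm <- NA_real_
    df
  }
  s1 <- select_nonoverlapping(mk(c(0, 1), c(45, 46)))
  expect_equal(s1$selected, c(TRUE, FALSE))
  expect_equal(s1$rejection_reason[2], "overlap_dropped")
  s2 <- select_nonoverlapping(mk(c(0, 45), c(45, 90)))
  expect_true(all(s2$selected))                    # abutment is not overlap

  g <- genome_assembly(c(chr1 = rand_seq(150)))
  cand <- tile_candidates(g, parse_region("chr1:1-100", g))
  sel <- select_nonoverlapping(cand)
  picked <- sel[sel$selected, ]
  expect_equal(picked$start, c(0, 43))
  expect_equal(picked$end, c(43, 86))
})

test_that("greedy selection is optimal on random instances (DP oracle)", {
  set.seed(48)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    starts <- sample(0:300, n)
    ends <- starts + sample(20:60, n, TRUE)
    o <- order(starts, ends)
    starts <- starts[o]; ends <- ends[o]
    df <- data.frame(probe_id = sprintf("p%d", seq_len(n)),
                     chromosome = "chr1", start = starts, end = ends,
                     strand = "+", sequence = strrep("A", 45),
                     predicted_tm = 70, offtarget_fail = FALSE,
                     homeolog_fail = FALSE, msat_flagged = FALSE,
                     selected = FALSE, rejection_reason = "none",
                     stringsAsFactors = FALSE)
    df$offtarget_best_tm <- NA_real_
    got <- sum(select_nonoverlapping(df)$selected)
    expect_equal(got, oracle_max_nonoverlap(starts, ends))
  }
})

test_that("the full pipeline is deterministic and keeps its invariants", {
  g <- make_genome(c(chrA = 6000L), seed = 49)
  hom <- genome_assembly(c(chrH = evolve(g$sequences[["chrA"]], 5, seed = 50)))
  reg <- parse_region("chrA:501-5500", g)
  ps1 <- design_probes(g, reg, hom, quiet = TRUE)
  ps2 <- design_probes(g, reg, hom, quiet = TRUE)
  expect_identical(ps1$probes, ps2$probes)
  pr <- ps1$probes
  expect_true(all(pr$end - pr$start >= 43 & pr$end - pr$start <= 47))
  expect_false(is.unsorted(pr$start))
  expect_true(all(pr$start[-1] >= pr$end[-nrow(pr)]))
  expect_true(all(pr$rejection_reason == "none"))
  # stage counts never increase along the pipeline
  sc <- ps1$stage_counts
  expect_true(sc$offtarget_pass <= sc$tiled)
  expect_true(sc$homeolog_pass <= sc$offtarget_pass)
  expect_true(sc$selected <= sc$homeolog_pass)
})

test_that("both stage orders work and select_then_filter never beats the default", {
  g <- make_genome(c(chrA = 5000L), seed = 51)
  hom <- genome_assembly(c(chrH = evolve(g$sequences[["chrA"]], 5, seed = 52)))
  reg <- parse_region("chrA:1-4000", g)
  a <- design_probes(g, reg, hom, design_parameters(order = "filter_then_select"),
                     quiet = TRUE)
  b <- design_probes(g, reg, hom, design_parameters(order = "select_then_filter"),
                     quiet = TRUE)
  expect_gte(nrow(a$probes), nrow(b$probes))
  expect_true(all(b$probes$start[-1] >= b$probes$end[-nrow(b$probes)]))
})

test_that("two-color sets from adjoining regions never share a probe", {
  fp <- make_fusion_pair(c(chrA = 8000L, chrB = 6000L), seed = 53)
  bp <- fp$manifest$breakpoint
  regA <- parse_region(sprintf("chrF:1-%d", bp), fp$sister)
  regB <- parse_region(sprintf("chrF:%d-%d", bp + 1,
                               nchar(fp$sister$sequences[["chrF"]])), fp$sister)
  green <- design_probes(fp$sister, regA, quiet = TRUE,
                         label_channel = "green")
  red <- design_probes(fp$sister, regB, quiet = TRUE, label_channel = "red")
  expect_equal(green$label_channel, "green")
  expect_length(intersect(green$probes$probe_id, red$probes$probe_id), 0)
})
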