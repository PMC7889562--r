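# Cross-genus probe design workflow: build a repeat library from shallow
# reads of the target genus, screen probes against it, select syntenic
# reads, and validate probes on them at high homology.

#' Cross-genus workflow parameters
#'
#' @param homology_min minimum identity percent for probe validation on
#'   syntenic reads (default 85).
#' @param preferential_margin a read is syntenic when its best hit lies on
#'   the chromosome of interest and out-scores the best off-chromosome hit
#'   by at least this many bits (default 5).
#' @param target_coverage intended shallow sequencing depth (informational;
#'   5-10x is sufficient to catalog the common repeats).
#' @param coverage_min_fraction a validating hit must span at least this
#'   fraction of the probe length (default 0.9).
#' @return a `crossgenus_parameters` list.
#' @export
crossgenus_parameters <- function(homology_min = 85, preferential_margin = 5,
                                  target_coverage = 7.5,
                                  coverage_min_fraction = 0.9) {
  stopifnot(homology_min > 0, homology_min <= 100)
  structure(list(homology_min = homology_min,
                 preferential_margin = preferential_margin,
                 target_coverage = target_coverage,
                 coverage_min_fraction = coverage_min_fraction),
            class = "crossgenus_parameters")
}

#' Select reads mapping preferentially to a chromosome of interest
#'
#' Each read is searched against the full reference; a read is admitted when
#' its best hit is on the target chromosome and its bit score clears the
#' best off-chromosome bit score by `preferential_margin` bits.
#'
#' @param reads a `read_set` from the target genus.
#' @param reference the reference [genome_assembly()].
#' @param chromosome chromosome of interest in `reference`.
#' @param params a [crossgenus_parameters()].
#' @param scheme a [scoring_scheme()].
#' @param evalue_max mapping E-value cutoff (default 1e-5).
#' @return a `syntenic_read_bin`: `chromosome`, `read_ids`, `sequences`,
#'   `n_reads`, `mean_identity`.
#' @export
select_syntenic_reads <- function(reads, reference, chromosome,
                                  params = crossgenus_parameters(),
                                  scheme = scoring_scheme(),
                                  evalue_max = 1e-5) {
  if (!chromosome %in% names(reference$sequences))
    stop("chromosome absent from reference: ", chromosome)
  queries <- all_reads(reads)
  hits <- search_hits(queries, reference, scheme, evalue_max = evalue_max)
  empty <- structure(list(chromosome = chromosome, read_ids = character(0),
                          sequences = character(0), n_reads = 0L,
                          mean_identity = NA_real_),
                     class = "syntenic_read_bin")
  if (nrow(hits) == 0) return(empty)
  on_t <- hits[hits$subject_id == chromosome, , drop = FALSE]
  if (nrow(on_t) == 0) return(empty)
  best_on <- tapply(on_t$bit_score, on_t$query_id, max)
  off_t <- hits[hits$subject_id != chromosome, , drop = FALSE]
  best_off <- tapply(off_t$bit_score, off_t$query_id, max)
  off_for <- best_off[names(best_on)]
  off_for[is.na(off_for)] <- -Inf
  admit <- names(best_on)[best_on >= off_for + params$preferential_margin]
  if (length(admit) == 0) return(empty)
  bh <- best_hits(on_t[on_t$query_id %in% admit, , drop = FALSE])
  structure(list(chromosome = chromosome, read_ids = bh$query_id,
                 sequences = unname(queries[bh$query_id]),
                 n_reads = length(admit),
                 mean_identity = mean(bh$identity_percent)),
            class = "syntenic_read_bin")
}

#' @export
print.syntenic_read_bin <- function(x, ...) {
  cat(sprintf("<syntenic_read_bin> %s: %d reads, mean best-hit identity %s\n",
              x$chromosome, x$n_reads,
              ifelse(is.na(x$mean_identity), "NA",
                     sprintf("%.1f%%", x$mean_identity))))
  invisible(x)
}

#' Build a repeat library from target-genus reads
#'
#' Combines the detected satellite consensus (if any), microsatellite motifs
#' whose runs cover an appreciable share of the reads, and the set of
#' high-depth k-mers.
#'
#' @param reads a `read_set`.
#' @param k k-mer size (default 17).
#' @param motifs candidate microsatellite motifs to test for (default GA,
#'   GAA).
#' @param motif_min_fraction minimum fraction of sampled read bases covered
#'   by a motif's runs for the motif to enter the library (default 0.001).
#' @param depth_multiple high-depth k-mer threshold as a multiple of modal
#'   coverage (default 4).
#' @param sample_reads number of reads scanned for motif content (default
#'   2000).
#' @param seed seed for the motif-scan subsample.
#' @return a `repeat_library`: `satellites` (character), `motifs`
#'   (character), `kmer_codes` (numeric canonical codes), `k`.
#' @export
build_repeat_library <- function(reads, k = 17L, motifs = c("GA", "GAA"),
                                 motif_min_fraction = 0.001,
                                 depth_multiple = 4, sample_reads = 2000L,
                                 seed = 1) {
  sat <- detect_satellite(reads, k = k, depth_multiple = depth_multiple)
  sp <- kmer_spectrum(reads, k)
  hi <- sp$code[sp$count > depth_multiple * sp$modal_coverage]
  pool <- all_reads(reads)
  scan <- with_seed(seed, pool[sample.int(length(pool),
                                          min(sample_reads, length(pool)))])
  total_bases <- sum(nchar(scan))
  kept_motifs <- character(0)
  for (m in motifs) {
    covered <- 0
    for (s in scan) {
      ann <- annotate_microsatellites(s, m)
      if (nrow(ann)) covered <- covered + sum(ann$span)
    }
    if (covered / total_bases >= motif_min_fraction)
      kept_motifs <- c(kept_motifs, m)
  }
  structure(list(satellites = if (sat$detected) sat$consensus else character(0),
                 motifs = kept_motifs, kmer_codes = hi, k = as.integer(k)),
            class = "repeat_library")
}

#' Screen probes against a target-genus repeat library
#'
#' A probe is rejected when it hits a satellite consensus at >= 75% identity
#' over >= 30 nt (the consensus is doubled so hits may wrap the monomer
#' junction), contains a flagged microsatellite run, or shares at least 20%
#' of its k-mers with the high-depth k-mer set.
#'
#' @param probes a `probe_set` or probe data.frame.
#' @param repeat_library a `repeat_library` from [build_repeat_library()].
#' @param scheme a [scoring_scheme()].
#' @param identity_min,span_min satellite-hit rejection thresholds
#'   (defaults 75 and 30).
#' @param kmer_share_max maximum tolerated shared k-mer fraction
#'   (default 0.2).
#' @return list with `probes` (survivors, same type as input) and
#'   `rejected` (data.frame probe_id / reason).
#' @export
screen_probes_against_repeats <- function(probes, repeat_library,
                                          scheme = scoring_scheme(),
                                          identity_min = 75, span_min = 30,
                                          kmer_share_max = 0.2) {
  is_set <- inherits(probes, "probe_set")
  df <- if (is_set) probes$probes else probes
  empty_lib <- length(repeat_library$satellites) == 0 &&
    length(repeat_library$motifs) == 0 &&
    length(repeat_library$kmer_codes) == 0
  if (empty_lib) {
    warning("empty repeat library; probes pass unchanged")
    return(list(probes = probes,
                rejected = data.frame(probe_id = character(0),
                                      reason = character(0))))
  }
  reason <- rep(NA_character_, nrow(df))
  if (length(repeat_library$satellites) && nrow(df)) {
    subj <- setNames(strrep(repeat_library$satellites, 2),
                     sprintf("satellite%d", seq_along(repeat_library$satellites)))
    hits <- search_hits(setNames(df$sequence, df$probe_id), subj, scheme)
    hits <- hits[hits$identity_percent >= identity_min &
                   hits$aligned_length >= span_min, , drop = FALSE]
    reason[df$probe_id %in% hits$query_id] <- "offtarget"
  }
  if (length(repeat_library$motifs)) {
    for (i in which(is.na(reason))) {
      ann <- annotate_microsatellites(df$sequence[i], repeat_library$motifs)
      if (nrow(ann)) reason[i] <- "msat"
    }
  }
  if (length(repeat_library$kmer_codes)) {
    k <- repeat_library$k
    for (i in which(is.na(reason))) {
      tab <- cpp_kmer_count(df$sequence[i], k)
      share <- mean(tab$code %in% repeat_library$kmer_codes)
      if (share >= kmer_share_max) reason[i] <- "offtarget"
    }
  }
  rejected <- data.frame(probe_id = df$probe_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- is.na(reason)
  df_out <- df[keep, , drop = FALSE]
  rownames(df_out) <- NULL
  if (is_set) { probes$probes <- df_out; out <- probes } else out <- df_out
  list(probes = out, rejected = rejected)
}

#' Validate probes on a bin of syntenic reads
#'
#' A probe is retained when it has at least one hit among the bin's reads
#' with identity above `homology_min` covering at least
#' `coverage_min_fraction` of the probe length.
#'
#' @param probes a `probe_set` or probe data.frame.
#' @param bin a `syntenic_read_bin`.
#' @param params a [crossgenus_parameters()].
#' @param scheme a [scoring_scheme()].
#' @return list with `probes` (validated, same type as input) and
#'   `n_validated`.
#' @export
validate_probes_on_syntenic_reads <- function(probes, bin,
                                              params = crossgenus_parameters(),
                                              scheme = scoring_scheme()) {
  if (bin$n_reads == 0) stop("empty syntenic read bin")
  is_set <- inherits(probes, "probe_set")
  df <- if (is_set) probes$probes else probes
  if (nrow(df) == 0) {
    if (is_set) { probes$probes <- df; out <- probes } else out <- df
    return(list(probes = out, n_validated = 0L))
  }
  subj <- setNames(bin$sequences, bin$read_ids)
  hits <- search_hits(setNames(df$sequence, df$probe_id), subj, scheme)
  qlen <- nchar(df$sequence)[match(hits$query_id, df$probe_id)]
  ok <- hits$identity_percent > params$homology_min &
    hits$aligned_length >= params$coverage_min_fraction * qlen
  validated <- unique(hits$query_id[ok])
  keep <- df$probe_id %in% validated
  df_out <- df[keep, , drop = FALSE]
  rownames(df_out) <- NULL
  if (is_set) { probes$probes <- df_out; out <- probes } else out <- df_out
  list(probes = out, n_validated = sum(keep))
}

#' Run the full cross-genus probe design workflow
#'
#' Design probes on the reference chromosome of interest; build a repeat
#' library from the target-genus reads; screen probes against it; select
#' syntenic reads; validate the survivors on those reads at high homology.
#' Also reports (but does not merge) supplementary candidates tiled from the
#' syntenic reads that map back uniquely to the target reference chromosome.
#'
#' @param reference reference [genome_assembly()].
#' @param target_reads `read_set` from the target genus.
#' @param chromosome reference chromosome of interest.
#' @param region optional `region_spec` to design on (default: whole
#'   chromosome).
#' @param design_params a [design_parameters()].
#' @param cg_params a [crossgenus_parameters()].
#' @param scheme a [scoring_scheme()].
#' @param dup_params a [duplex_parameters()].
#' @param homeolog optional homeolog assembly for the design stage.
#' @param supplement_candidates also tile syntenic reads into supplementary
#'   candidates that map back uniquely to the target chromosome (default
#'   FALSE; candidate list reported, never merged).
#' @param quiet suppress stage messages.
#' @return a `workflow_report`: `stage_counts` (monotone non-increasing),
#'   `probes` (final `probe_set`), `bin`, `repeat_library`, `rejected`,
#'   `supplementary_candidates`, `error` (NULL or a message when the
#'   syntenic bin is empty).
#' @export
run_crossgenus_workflow <- function(reference, target_reads, chromosome,
                                    region = NULL,
                                    design_params = design_parameters(),
                                    cg_params = crossgenus_parameters(),
                                    scheme = scoring_scheme(),
                                    dup_params = duplex_parameters(),
                                    homeolog = NULL,
                                    supplement_candidates = FALSE,
                                    quiet = FALSE) {
  if (is.null(region)) {
    region <- parse_region(sprintf("%s:1-%d", chromosome,
                                   nchar(reference$sequences[[chromosome]])),
                           reference)
  }
  pset <- design_probes(reference, region, homeolog = homeolog,
                        params = design_params, scheme = scheme,
                        dup_params = dup_params, quiet = quiet)
  counts <- list(designed = nrow(pset$probes))
  lib <- build_repeat_library(target_reads)
  scr <- suppressWarnings(
    screen_probes_against_repeats(pset, lib, scheme = scheme))
  counts$repeat_screen <- nrow(scr$probes$probes)
  bin <- select_syntenic_reads(target_reads, reference, chromosome,
                               cg_params, scheme)
  err <- NULL
  supp <- NULL
  if (bin$n_reads == 0) {
    err <- "no syntenic reads for target chromosome"
    counts$validated <- 0L
    final <- scr$probes
    final$probes <- final$probes[0, , drop = FALSE]
  } else {
    val <- validate_probes_on_syntenic_reads(scr$probes, bin, cg_params,
                                             scheme)
    counts$validated <- val$n_validated
    final <- val$probes
    if (supplement_candidates) {
      supp <- supplementary_candidates(bin, reference, chromosome,
                                       design_params, scheme, dup_params)
    }
  }
  if (!quiet)
    message(sprintf("crossgenus stages: designed %d -> repeat screen %d -> validated %d",
                    counts$designed, counts$repeat_screen, counts$validated))
  structure(list(stage_counts = counts, probes = final, bin = bin,
                 repeat_library = lib, rejected = scr$rejected,
                 supplementary_candidates = supp, error = err),
            class = "workflow_report")
}

# Tile syntenic reads into candidates and keep those mapping back uniquely
# to the intended reference target chromosome.
supplementary_candidates <- function(bin, reference, chromosome,
                                     design_params, scheme, dup_params) {
  cands <- list()
  L <- design_params$min_length
  for (i in seq_along(bin$sequences)) {
    s <- bin$sequences[i]
    if (nchar(s) < L) next
    starts <- seq.int(1L, nchar(s) - L + 1L, by = L)
    cands[[i]] <- setNames(substring(s, starts, starts + L - 1L),
                           sprintf("%s_c%d", bin$read_ids[i], seq_along(starts)))
  }
  cands <- unlist(cands)
  cands <- cands[!grepl("N", cands, fixed = TRUE)]
  if (length(cands) == 0)
    return(data.frame(candidate_id = character(0), sequence = character(0)))
  hits <- search_hits(cands, reference, scheme, evalue_max = 1e-5)
  nhits <- table(hits$query_id)
  uniq <- names(nhits)[nhits == 1]
  on_target <- hits$query_id[hits$subject_id == chromosome]
  keep <- intersect(uniq, on_target)
  data.frame(candidate_id = keep, sequence = unname(cands[keep]),
             stringsAsFactors = FALSE)
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf("<workflow_report> designed %d -> repeat screen %d -> validated %d%s\n",
              x$stage_counts$designed, x$stage_counts$repeat_screen,
              x$stage_counts$validated,
              ifelse(is.null(x$error), "", paste0(" [", x$error, "]"))))
  invisible(x)
}
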