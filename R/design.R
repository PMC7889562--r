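# The core probe-design pipeline: tile a target region into 43-47 nt
# candidates, screen off-targets by predicted hybridization Tm, keep
# candidates with exactly one strong homeolog hit, and select a maximal
# non-overlapping final set.

#' Probe design parameters
#'
#' @param min_length,max_length candidate oligo length bounds in nt
#'   (defaults 43 and 47).
#' @param stride tiling step in nt (default 1, i.e. every offset).
#' @param offtarget_tm_margin degrees C below the perfect-match Tm; an
#'   off-target site whose effective Tm comes within this margin causes
#'   rejection (default 20).
#' @param evalue_cutoff homeolog hits must have E-value below this
#'   (default 1e-5).
#' @param require_single_homeolog_hit keep a candidate only when it has
#'   exactly one qualifying homeolog hit (default TRUE).
#' @param homeolog_identity_min minimum identity percent of the single
#'   homeolog hit (default 75).
#' @param exclude_n reject windows containing N (default TRUE).
#' @param exclude_softmasked reject windows overlapping the soft-mask track
#'   (default FALSE).
#' @param order stage order: `"filter_then_select"` (default; homeolog filter
#'   before non-overlap selection, maximizes final density) or
#'   `"select_then_filter"`.
#' @param msat_policy `"none"` (default), `"flag"` or `"drop"`: optional
#'   microsatellite filtering of the final set.
#' @param msat_motifs motifs for the optional microsatellite stage.
#' @return a `design_parameters` list.
#' @export
design_parameters <- function(min_length = 43L, max_length = 47L, stride = 1L,
                              offtarget_tm_margin = 20,
                              evalue_cutoff = 1e-5,
                              require_single_homeolog_hit = TRUE,
                              homeolog_identity_min = 75,
                              exclude_n = TRUE, exclude_softmasked = FALSE,
                              order = c("filter_then_select",
                                        "select_then_filter"),
                              msat_policy = c("none", "flag", "drop"),
                              msat_motifs = c("GA", "GAA")) {
  stopifnot(min_length > 0, min_length <= max_length, stride >= 1,
            evalue_cutoff > 0, offtarget_tm_margin >= 0)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 stride = as.integer(stride),
                 offtarget_tm_margin = offtarget_tm_margin,
                 evalue_cutoff = evalue_cutoff,
                 require_single_homeolog_hit = require_single_homeolog_hit,
                 homeolog_identity_min = homeolog_identity_min,
                 exclude_n = exclude_n,
                 exclude_softmasked = exclude_softmasked,
                 order = match.arg(order),
                 msat_policy = match.arg(msat_policy),
                 msat_motifs = msat_motifs),
            class = "design_parameters")
}

new_candidates <- function(chromosome, start, end, sequence, tm) {
  n <- length(start)
  df <- data.frame(
    probe_id = sprintf("%s_%d_%d", chromosome, start + 1L, end),
    chromosome = rep(chromosome, n), start = start, end = end,
    strand = rep("+", n), sequence = sequence, predicted_tm = tm,
    offtarget_fail = rep(FALSE, n), homeolog_fail = rep(FALSE, n),
    msat_flagged = rep(FALSE, n), selected = rep(FALSE, n),
    rejection_reason = rep("none", n), stringsAsFactors = FALSE)
  df$offtarget_best_tm <- rep(NA_real_, n)
  df
}

#' Tile a region into overlapping probe candidates
#'
#' Every window of every length in `[min_length, max_length]` starting at
#' every `stride`-th offset is emitted (sense strand), except windows
#' containing N when `exclude_n`.
#'
#' @param assembly a [genome_assembly()].
#' @param region a `region_spec` (see [parse_region()]).
#' @param params a [design_parameters()].
#' @param dup_params a [duplex_parameters()] for the per-candidate
#'   perfect-match Tm.
#' @return candidate data.frame sorted by start (regions shorter than
#'   `min_length` give zero rows).
#' @export
tile_candidates <- function(assembly, region, params = design_parameters(),
                            dup_params = duplex_parameters()) {
  chrom_seq <- assembly$sequences[[region$chromosome]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", region$chromosome)
  rl <- region_length(region)
  starts <- integer(0); ends <- integer(0)
  for (L in params$min_length:params$max_length) {
    if (rl < L) next
    s <- region$start + seq.int(0L, rl - L, by = params$stride)
    starts <- c(starts, as.integer(s)); ends <- c(ends, as.integer(s + L))
  }
  if (length(starts) == 0)
    return(new_candidates(region$chromosome, integer(0), integer(0),
                          character(0), numeric(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  seqs <- substring(chrom_seq, starts + 1L, ends)
  keep <- rep(TRUE, length(seqs))
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (params$exclude_n) keep <- keep & !has_n
  if (params$exclude_softmasked && !is.null(assembly$mask[[region$chromosome]])) {
    msk <- assembly$mask[[region$chromosome]]
    in_mask <- vapply(seq_along(starts), function(i)
      any(msk$start < ends[i] & msk$end > starts[i]), logical(1))
    keep <- keep & !in_mask
  }
  n_rej <- sum(!keep)
  starts <- starts[keep]; ends <- ends[keep]; seqs <- seqs[keep]
  tm <- if (length(seqs)) predict_tm(seqs, dup_params) else numeric(0)
  cand <- new_candidates(region$chromosome, starts, ends, seqs, tm)
  attr(cand, "n_rejected_n") <- n_rej
  cand
}

#' Screen candidates for cross-hybridization elsewhere in the genome
#'
#' Each candidate is searched against the whole assembly; hits overlapping
#' its own source interval are ignored.  Every off-source hit is converted to
#' an effective duplex Tm through its identity percent; the candidate is
#' rejected when the hottest off-target Tm exceeds
#' `perfect_tm - offtarget_tm_margin`.
#'
#' @param candidates candidate data.frame from [tile_candidates()].
#' @param assembly the design [genome_assembly()].
#' @param params a [design_parameters()].
#' @param scheme a [scoring_scheme()].
#' @param dup_params a [duplex_parameters()].
#' @return candidates with `offtarget_fail`, `offtarget_best_tm` and
#'   `rejection_reason` updated.
#' @export
screen_offtarget <- function(candidates, assembly,
                             params = design_parameters(),
                             scheme = scoring_scheme(),
                             dup_params = duplex_parameters()) {
  if (nrow(candidates) == 0) return(candidates)
  queries <- setNames(candidates$sequence, candidates$probe_id)
  hits <- search_hits(queries, assembly, scheme)
  if (nrow(hits)) {
    idx <- match(hits$query_id, candidates$probe_id)
    self <- hits$subject_id == candidates$chromosome[idx] &
      hits$subject_start < candidates$end[idx] &
      hits$subject_end > candidates$start[idx]
    hits <- hits[!self, , drop = FALSE]
    idx <- idx[!self]
  }
  if (nrow(hits)) {
    eff <- effective_duplex_tm(candidates$predicted_tm[idx],
                               hits$identity_percent, dup_params)$tm_celsius
    best <- tapply(eff, hits$query_id, max)
    at <- match(names(best), candidates$probe_id)
    candidates$offtarget_best_tm[at] <- as.numeric(best)
  }
  fail <- !is.na(candidates$offtarget_best_tm) &
    candidates$offtarget_best_tm >
      candidates$predicted_tm - params$offtarget_tm_margin
  candidates$offtarget_fail <- fail
  candidates$rejection_reason[fail & candidates$rejection_reason == "none"] <-
    "offtarget"
  candidates
}

#' Filter candidates by single-hit presence on the homeologous chromosome
#'
#' A candidate is kept when the number of its homeolog hits with
#' `evalue < evalue_cutoff` is exactly one (when
#' `require_single_homeolog_hit`) and that hit's identity is at least
#' `homeolog_identity_min`; otherwise it is tagged `homeolog_none` or
#' `homeolog_multi`.
#'
#' @param candidates candidate data.frame (survivors of earlier screens are
#'   evaluated; rows already rejected pass through untouched).
#' @param homeolog a [genome_assembly()] restricted to the homeologous
#'   chromosome (or a named character vector).
#' @param params a [design_parameters()].
#' @param scheme a [scoring_scheme()].
#' @return candidates with `homeolog_fail` and `rejection_reason` updated.
#' @export
filter_homeolog <- function(candidates, homeolog,
                            params = design_parameters(),
                            scheme = scoring_scheme()) {
  if (nrow(candidates) == 0) return(candidates)
  live <- candidates$rejection_reason == "none"
  if (!any(live)) return(candidates)
  queries <- setNames(candidates$sequence[live], candidates$probe_id[live])
  hits <- search_hits(queries, homeolog, scheme,
                      evalue_max = params$evalue_cutoff)
  hits <- hits[hits$evalue < params$evalue_cutoff, , drop = FALSE]
  nhits <- table(hits$query_id)
  cnt <- as.integer(nhits[candidates$probe_id])
  cnt[is.na(cnt)] <- 0L
  single_ok <- if (params$require_single_homeolog_hit) cnt == 1L else cnt >= 1L
  id_ok <- rep(FALSE, nrow(candidates))
  if (nrow(hits)) {
    one <- hits[hits$query_id %in% names(nhits)[nhits == 1L], , drop = FALSE]
    at <- match(one$query_id, candidates$probe_id)
    id_ok[at] <- one$identity_percent >= params$homeolog_identity_min
  }
  if (!params$require_single_homeolog_hit && nrow(hits)) {
    bh <- best_hits(hits)
    at <- match(bh$query_id, candidates$probe_id)
    id_ok[at] <- id_ok[at] | bh$identity_percent >= params$homeolog_identity_min
  }
  fail <- live & !(single_ok & id_ok)
  candidates$homeolog_fail[fail] <- TRUE
  reason <- ifelse(cnt >= 2L, "homeolog_multi", "homeolog_none")
  candidates$rejection_reason[fail & candidates$rejection_reason == "none"] <-
    reason[fail & candidates$rejection_reason == "none"]
  candidates
}

#' Select a maximal set of pairwise non-overlapping candidates
#'
#' Earliest-end-first greedy scan (optimal for interval scheduling).  Ties on
#' end coordinate are broken by lower start, then lexicographically smaller
#' sequence.  Abutting half-open intervals do not overlap.
#'
#' @param candidates candidate data.frame; only rows with
#'   `rejection_reason == "none"` compete.
#' @return candidates with `selected` set and losers tagged
#'   `overlap_dropped`.
#' @export
select_nonoverlapping <- function(candidates) {
  live <- which(candidates$rejection_reason == "none")
  if (length(live) == 0) return(candidates)
  for (chrom in unique(candidates$chromosome[live])) {
    rows <- live[candidates$chromosome[live] == chrom]
    o <- rows[order(candidates$end[rows], candidates$start[rows],
                    candidates$sequence[rows])]
    last_end <- -Inf
    for (r in o) {
      if (candidates$start[r] >= last_end) {
        candidates$selected[r] <- TRUE
        last_end <- candidates$end[r]
      } else {
        candidates$rejection_reason[r] <- "overlap_dropped"
      }
    }
  }
  candidates
}

#' Run the full probe design pipeline on one region
#'
#' Stages: tile, off-target Tm screen, homeolog single-hit filter, optional
#' microsatellite filter, non-overlap selection (stage order per
#' `params$order`).  A per-stage count log is reported via [message()] and
#' returned.
#'
#' @param assembly design [genome_assembly()].
#' @param region `region_spec` within `assembly`.
#' @param homeolog optional homeolog [genome_assembly()] (NULL skips the
#'   homeolog stage).
#' @param params a [design_parameters()].
#' @param scheme a [scoring_scheme()].
#' @param dup_params a [duplex_parameters()].
#' @param label_channel channel identifier carried on the result (e.g.
#'   `"green"`).
#' @param quiet suppress the stage log.
#' @return a `probe_set`: list with `probes` (selected rows, sorted,
#'   non-overlapping), `candidates` (all rows with status), `source_region`,
#'   `label_channel` and `stage_counts`.
#' @export
design_probes <- function(assembly, region, homeolog = NULL,
                          params = design_parameters(),
                          scheme = scoring_scheme(),
                          dup_params = duplex_parameters(),
                          label_channel = "green", quiet = FALSE) {
  log_counts <- list()
  cand <- tile_candidates(assembly, region, params, dup_params)
  log_counts$tiled <- nrow(cand)
  log_counts$rejected_contains_n <- attr(cand, "n_rejected_n")
  cand <- screen_offtarget(cand, assembly, params, scheme, dup_params)
  log_counts$offtarget_pass <- sum(cand$rejection_reason == "none")
  run_homeolog <- function(cand) {
    if (is.null(homeolog)) return(cand)
    filter_homeolog(cand, homeolog, params, scheme)
  }
  run_msat <- function(cand) {
    if (params$msat_policy == "none") return(cand)
    ann_idx <- which(cand$rejection_reason == "none")
    for (i in ann_idx) {
      ann <- annotate_microsatellites(cand$sequence[i], params$msat_motifs)
      if (nrow(ann)) {
        cand$msat_flagged[i] <- TRUE
        if (params$msat_policy == "drop") cand$rejection_reason[i] <- "msat"
      }
    }
    cand
  }
  if (params$order == "filter_then_select") {
    cand <- run_homeolog(cand)
    log_counts$homeolog_pass <- sum(cand$rejection_reason == "none")
    cand <- run_msat(cand)
    log_counts$msat_pass <- sum(cand$rejection_reason == "none")
    cand <- select_nonoverlapping(cand)
  } else {
    cand <- select_nonoverlapping(cand)
    keep <- cand$selected
    cand <- run_homeolog(cand)
    cand <- run_msat(cand)
    cand$selected <- keep & cand$rejection_reason == "none"
    log_counts$homeolog_pass <- sum(cand$rejection_reason == "none")
    log_counts$msat_pass <- log_counts$homeolog_pass
  }
  log_counts$selected <- sum(cand$selected)
  if (!quiet) {
    for (nm in names(log_counts))
      message(sprintf("design %s: %d", nm, log_counts[[nm]]))
  }
  probes <- cand[cand$selected, , drop = FALSE]
  probes <- probes[order(probes$chromosome, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes, candidates = cand, source_region = region,
                 label_channel = label_channel, stage_counts = log_counts,
                 params = params),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d probes on %s (channel %s)\n",
              nrow(x$probes), format_region(x$source_region),
              x$label_channel))
  invisible(x)
}
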