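# Microsatellite motif annotation in oligo sequences, motif-based probe
# filtering, and blocking-oligo recommendations.

#' Canonical representative of a microsatellite motif class
#'
#' The class of a motif contains all cyclic rotations of the motif and of its
#' reverse complement (probes hybridize double-strandedly, so GA, AG, TC and
#' CT runs are one class).  The representative is the lexicographically
#' smallest member.
#'
#' @param motif repeat unit of 1-6 nt (A/C/G/T).
#' @return character scalar.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) min(motif_patterns(m)), character(1),
         USE.NAMES = FALSE)
}

motif_patterns <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 1 || nchar(motif) > 6) stop("motif unit must be 1-6 nt")
  if (grepl("[^ACGT]", motif)) stop("motif unit must contain only A/C/G/T")
  u <- nchar(motif)
  rots <- vapply(seq_len(u), function(i)
    paste0(substring(motif, i, u), substring(motif, 1, i - 1)), character(1))
  rc <- revcomp(motif)
  rots_rc <- vapply(seq_len(u), function(i)
    paste0(substring(rc, i, u), substring(rc, 1, i - 1)), character(1))
  unique(c(rots, rots_rc))
}

# Maximal high-purity period-u runs of one anchored pattern in one sequence.
pattern_runs <- function(chars, pattern, min_units, min_span, purity_min) {
  n <- length(chars)
  u <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  m <- chars == pat[((seq_len(n) - 1) %% u) + 1]
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  true_runs <- which(r$values)
  out <- list()
  for (i in true_runs) {
    a <- starts[i]; j <- i
    # greedily absorb later match runs while overall purity holds
    while (j + 2 <= length(r$values) && r$values[j + 2]) {
      b2 <- ends[j + 2]
      if (sum(m[a:b2]) / (b2 - a + 1) >= purity_min) j <- j + 2 else break
    }
    b <- ends[j]
    span <- b - a + 1
    if (span >= min_span && span / u >= min_units)
      out[[length(out) + 1]] <- c(a, b, sum(m[a:b]))
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      purity = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end", "nmatch")
  # drop runs contained in a longer run from the same pattern
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (any(df$start <= df$start[i] & df$end >= df$end[i] &
            (df$end - df$start > df$end[i] - df$start[i])))
      keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  data.frame(start = df$start - 1L, end = df$end,          # 0-based half-open
             purity = df$nmatch / (df$end - df$start + 1))
}

#' Annotate microsatellite runs in a sequence
#'
#' Finds maximal runs of each motif (including all rotations and the reverse
#' complement phase) with at least `min_units` repeat units, `min_span` nt,
#' and purity at or above `purity_min`.  Overlapping annotations of different
#' motifs are all reported.
#'
#' @param sequence a single nucleotide string.
#' @param motifs character vector of repeat units (default GA and GAA).
#' @param min_units minimum repeat units (may be fractional in the output).
#' @param min_span minimum annotated span in nt.
#' @param purity_min minimum fraction of positions matching a perfect repeat.
#' @return data.frame with `motif`, `canonical`, `start`, `end` (0-based
#'   half-open within the sequence), `span`, `units`, `purity`.
#' @export
annotate_microsatellites <- function(sequence, motifs = c("GA", "GAA"),
                                     min_units = 3, min_span = 10,
                                     purity_min = 0.9) {
  stopifnot(length(sequence) == 1, nzchar(sequence))
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  res <- list()
  for (motif in motifs) {
    pats <- motif_patterns(motif)
    runs <- do.call(rbind, lapply(pats, function(p)
      pattern_runs(chars, p, min_units, min_span, purity_min)))
    if (is.null(runs) || nrow(runs) == 0) next
    runs <- runs[!duplicated(runs[, c("start", "end")]), , drop = FALSE]
    keep <- rep(TRUE, nrow(runs))
    for (i in seq_len(nrow(runs))) {
      if (any(runs$start <= runs$start[i] & runs$end >= runs$end[i] &
              (runs$end - runs$start > runs$end[i] - runs$start[i])))
        keep[i] <- FALSE
    }
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0) next
    runs$motif <- motif
    runs$canonical <- canonical_motif(motif)
    res[[length(res) + 1]] <- runs
  }
  if (length(res) == 0)
    return(data.frame(motif = character(0), canonical = character(0),
                      start = integer(0), end = integer(0),
                      span = integer(0), units = numeric(0),
                      purity = numeric(0)))
  ann <- do.call(rbind, res)
  ann$span <- ann$end - ann$start
  ann$units <- ann$span / nchar(ann$motif)
  ann <- ann[order(ann$start, ann$end, ann$motif),
             c("motif", "canonical", "start", "end", "span", "units",
               "purity")]
  rownames(ann) <- NULL
  ann
}

#' Flag or drop motif-containing probes from a probe set
#'
#' @param probes a `probe_set` from [design_probes()] or a probe data.frame.
#' @param motifs repeat units to scan for.
#' @param policy `"flag"` marks probes (`msat_flagged`); `"drop"` also
#'   removes them from the selected set.
#' @param ... thresholds passed to [annotate_microsatellites()].
#' @return list with `probes` (same type as input, updated) and `flags`
#'   (data.frame of per-probe annotations: probe_id, motif, start, end,
#'   units, purity).
#' @export
filter_probes_by_motif <- function(probes, motifs = c("GA", "GAA"),
                                   policy = c("flag", "drop"), ...) {
  policy <- match.arg(policy)
  is_set <- inherits(probes, "probe_set")
  df <- if (is_set) probes$probes else probes
  flags <- list()
  flagged <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ann <- annotate_microsatellites(df$sequence[i], motifs, ...)
    if (nrow(ann)) {
      flagged[i] <- TRUE
      ann$probe_id <- df$probe_id[i]
      flags[[length(flags) + 1]] <- ann
    }
  }
  df$msat_flagged <- df$msat_flagged | flagged
  if (policy == "drop") {
    dropped <- df[flagged, , drop = FALSE]
    df <- df[!flagged, , drop = FALSE]
    rownames(df) <- NULL
  }
  flag_df <- if (length(flags)) do.call(rbind, flags) else
    data.frame(motif = character(0), canonical = character(0),
               start = integer(0), end = integer(0), span = integer(0),
               units = numeric(0), purity = numeric(0),
               probe_id = character(0))
  if (is_set) {
    probes$probes <- df
    if (policy == "drop" && any(flagged)) {
      idx <- match(flag_df$probe_id, probes$candidates$probe_id)
      idx <- unique(idx[!is.na(idx)])
      probes$candidates$msat_flagged[idx] <- TRUE
      probes$candidates$selected[idx] <- FALSE
      probes$candidates$rejection_reason[idx] <- "msat"
    }
    out <- probes
  } else out <- df
  list(probes = out, flags = flag_df)
}

#' Propose blocking oligos for the motifs seen in a probe set
#'
#' One unlabeled blocker per distinct motif class, sized to about 30 nt
#' (`ceiling(30 / unit_length)` units: (GA)15, (GAA)10), to be added in molar
#' excess over the labeled probes.
#'
#' @param annotations annotation data.frame (e.g. the `flags` element of
#'   [filter_probes_by_motif()]).
#' @param blocker_length target blocker length in nt (default 30).
#' @param excess_ratio molar excess of each blocker over total labeled
#'   probes; the default 2.5 reflects 50 pmol blocker per 20 pmol probes.
#' @return data.frame with `motif`, `units`, `sequence`, `length`,
#'   `excess_ratio`.
#' @export
propose_blocking <- function(annotations, blocker_length = 30,
                             excess_ratio = 2.5) {
  stopifnot(excess_ratio > 0)
  if (nrow(annotations) == 0) stop("no annotations to block")
  motifs <- unique(annotations$motif)
  units <- ceiling(blocker_length / nchar(motifs))
  seqs <- strrep(motifs, units)
  data.frame(motif = motifs, units = units, sequence = seqs,
             length = nchar(seqs), excess_ratio = excess_ratio,
             stringsAsFactors = FALSE)
}
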