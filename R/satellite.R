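# Read-based repeat analysis: subsample/trim reads, estimate the repeat
# fraction from the k-mer depth spectrum, and detect tandem satellites
# (monomer length, consensus, abundance) as the highest-coverage simple
# cycle in a graph of high-depth k-mers.
#
# Rationale for the cycle method: a monomer longer than read_length - k
# cannot recur within a single read, so its period must be assembled across
# reads; following (k-1)-overlaps among high-depth k-mers does this without
# full assembly, and the cycle length equals the monomer period.

#' Subsample and trim a paired read set
#'
#' Uniform random sample of pairs without replacement; reads truncated to
#' `trim_to` from the 5' end; pairs where either mate has more than 10% N
#' after trimming are dropped (count recorded in `n_dropped_n`).
#'
#' @param reads a `read_set` (see [simulate_reads()], [load_fastq_pair()]).
#' @param n_pairs number of pairs to sample (at most the available pairs).
#' @param trim_to target read length in nt (default 142).
#' @param seed RNG seed.
#' @return a trimmed `read_set`.
#' @export
sample_and_trim <- function(reads, n_pairs = reads$n_pairs, trim_to = 142L,
                            seed = 1) {
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (n_pairs > reads$n_pairs) stop("sample size exceeds available pairs")
  with_seed(seed, {
    sel <- sort(sample.int(reads$n_pairs, n_pairs))
    r1 <- substring(reads$r1[sel], 1, trim_to)
    r2 <- substring(reads$r2[sel], 1, trim_to)
    nfrac <- function(x) {
      (nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))) / nchar(x)
    }
    bad <- nfrac(r1) > 0.1 | nfrac(r2) > 0.1
    structure(list(r1 = r1[!bad], r2 = r2[!bad],
                   read_length = reads$read_length,
                   trimmed_length = as.integer(trim_to),
                   n_pairs = sum(!bad), n_dropped_n = sum(bad)),
              class = "read_set")
  })
}

# k-mer spectrum with a modal (single-copy) depth estimate.  The error peak
# at depth 1 is excluded by walking past the first valley of the histogram.
kmer_spectrum <- function(reads, k) {
  if (k > min(nchar(c(reads$r1[1], reads$r2[1]))))
    stop("k larger than read length")
  tab <- cpp_kmer_count(c(reads$r1, reads$r2), k)
  h <- tabulate(tab$count)
  valley <- 1L
  while (valley < length(h) && h[valley + 1] <= h[valley]) valley <- valley + 1L
  modal <- if (valley >= length(h)) which.max(h)
           else valley + which.max(h[(valley + 1):length(h)])
  list(code = tab$code, count = tab$count, histogram = h,
       modal_coverage = as.integer(modal))
}

#' Estimate the repetitive fraction of a genome from read k-mers
#'
#' Canonical k-mers are counted; the modal depth of the spectrum (excluding
#' the depth-1 error peak) estimates single-copy coverage, and the repeat
#' fraction is the depth-weighted share of k-mers deeper than
#' `repeat_threshold` times modal.
#'
#' @param reads a `read_set` with at least 1e5 total k-mers.
#' @param k k-mer size (default 17).
#' @param repeat_threshold multiple of modal depth above which a k-mer is
#'   called repetitive (default 4).
#' @return a `repeat_fraction_report` list: `k`, `modal_coverage`,
#'   `repeat_fraction`.
#' @export
kmer_repeat_fraction <- function(reads, k = 17L, repeat_threshold = 4) {
  sp <- kmer_spectrum(reads, k)
  total <- sum(sp$count)
  if (total < 1e5) stop("need at least 1e5 k-mers for a stable spectrum")
  rep_mass <- sum(sp$count[sp$count > repeat_threshold * sp$modal_coverage])
  structure(list(k = as.integer(k), modal_coverage = sp$modal_coverage,
                 repeat_fraction = rep_mass / total),
            class = "repeat_fraction_report")
}

#' @export
print.repeat_fraction_report <- function(x, ...) {
  cat(sprintf("<repeat_fraction_report> k=%d modal=%dx repeat_fraction=%.4f\n",
              x$k, x$modal_coverage, x$repeat_fraction))
  invisible(x)
}

# -- double-precision k-mer code arithmetic (exact for k <= 26) -------------
decode_kmer <- function(code, k) {
  out <- character(k)
  for (i in k:1) {
    out[i] <- BASES[code %% 4 + 1]
    code <- code %/% 4
  }
  paste(out, collapse = "")
}

revcomp_code <- function(code, k) {
  out <- 0
  for (i in seq_len(k)) {
    out <- out * 4 + (3 - code %% 4)
    code <- code %/% 4
  }
  out
}

canonical_code <- function(code, k) pmin(code, revcomp_code(code, k))

#' Detect the dominant tandem satellite from reads
#'
#' Builds a directed graph on k-mers deeper than `depth_multiple` times the
#' modal coverage (node = k-mer, edge = (k-1)-overlap), starts from the
#' deepest node and greedily follows the deepest successor until a node
#' repeats; the resulting simple cycle gives the monomer: its length is the
#' period, its consensus is read off the cycle and reported as the
#' lexicographically smallest rotation, and its abundance is the
#' depth-weighted share of cycle k-mers among all non-singleton read k-mers
#' (singletons are dominated by sequencing errors and excluded).
#'
#' @param reads a `read_set`.
#' @param k k-mer size (default 17).
#' @param depth_multiple node depth threshold as a multiple of modal
#'   coverage (default 3).
#' @return a `satellite_report`: `detected`, `monomer_length`, `consensus`,
#'   `abundance_fraction`, `supporting_kmer_count`, `modal_coverage`.
#' @export
detect_satellite <- function(reads, k = 17L, depth_multiple = 3) {
  sp <- kmer_spectrum(reads, k)
  threshold <- depth_multiple * sp$modal_coverage
  hi <- sp$count > threshold
  none <- structure(list(detected = FALSE, monomer_length = NA_integer_,
                         consensus = NA_character_,
                         abundance_fraction = 0,
                         supporting_kmer_count = 0L,
                         modal_coverage = sp$modal_coverage),
                    class = "satellite_report")
  if (!any(hi)) return(none)
  hi_code <- sp$code[hi]
  hi_count <- sp$count[hi]
  lookup <- function(oriented) {
    # depth of an oriented k-mer via its canonical form; 0 when absent
    i <- match(canonical_code(oriented, k), hi_code)
    ifelse(is.na(i), 0, hi_count[i])
  }
  start <- hi_code[which.max(hi_count)]
  path <- numeric(0)
  cycle <- NULL
  node <- start
  base_pow <- 4^(k - 1)
  for (step in seq_len(length(hi_code) + 1L)) {
    at <- match(node, path)
    if (!is.na(at)) { cycle <- path[at:length(path)]; break }
    path <- c(path, node)
    succ <- (node %% base_pow) * 4 + 0:3
    depths <- vapply(succ, lookup, numeric(1))
    if (all(depths == 0)) return(none)   # dead end, no cycle
    node <- succ[which.max(depths)]
  }
  if (is.null(cycle)) return(none)
  first_base <- vapply(cycle, function(cc) BASES[cc %/% base_pow + 1],
                       character(1))
  monomer <- paste(first_base, collapse = "")
  # canonical form: lexicographically smallest rotation over both strands
  # (the cycle has no canonical start and the walk no canonical orientation)
  rot_all <- function(s) vapply(seq_len(nchar(s)), function(i)
    paste0(substring(s, i), substring(s, 1, i - 1)), character(1))
  consensus <- min(c(rot_all(monomer), rot_all(revcomp(monomer))))
  cyc_canon <- unique(vapply(cycle, canonical_code, numeric(1), k = k))
  idx <- match(cyc_canon, sp$code)
  num <- sum(sp$count[idx[!is.na(idx)]])
  den <- sum(sp$count[sp$count >= 2])
  structure(list(detected = TRUE, monomer_length = length(cycle),
                 consensus = consensus,
                 abundance_fraction = num / den,
                 supporting_kmer_count = length(cyc_canon),
                 modal_coverage = sp$modal_coverage),
            class = "satellite_report")
}

#' @export
print.satellite_report <- function(x, ...) {
  if (!x$detected) cat("<satellite_report> no satellite detected\n")
  else cat(sprintf(
    "<satellite_report> monomer %d bp, abundance %.4f%% of genome, %d k-mers\n",
    x$monomer_length, 100 * x$abundance_fraction, x$supporting_kmer_count))
  invisible(x)
}

#' Write a satellite report as a plain-text key/value file
#'
#' @param report a `satellite_report`.
#' @param path output file.
#' @param consensus_fasta optional path for a FASTA of the consensus monomer
#'   (usable directly as a FISH probe source).
#' @export
write_satellite_report <- function(report, path, consensus_fasta = NULL) {
  kv <- c(detected = report$detected,
          monomer_length = report$monomer_length,
          consensus = report$consensus,
          abundance_fraction = report$abundance_fraction,
          supporting_kmer_count = report$supporting_kmer_count,
          modal_coverage = report$modal_coverage)
  writeLines(sprintf("%s=%s", names(kv), as.character(kv)), path)
  if (!is.null(consensus_fasta) && isTRUE(report$detected)) {
    ss <- Biostrings::DNAStringSet(setNames(report$consensus, "satellite_consensus"))
    Biostrings::writeXStringSet(ss, consensus_fasta, width = 80L)
  }
  invisible(path)
}
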