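# Seed-and-extend ungapped local similarity search with Karlin-Altschul
# E-values, and per-chromosome best-hit tallies.

#' Nucleotide scoring scheme with Karlin-Altschul statistics
#'
#' Lambda is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` at uniform base frequencies;
#' K uses the lattice approximation `K = A * (1 - exp(-lambda * delta))`
#' with `A = sum_s s p(s) exp(lambda s)` and `delta` the score lattice gcd
#' (exact for the default +1/-2 scheme).
#'
#' @param match_reward positive match score (default +1).
#' @param mismatch_penalty negative mismatch score (default -2).
#' @param gap_open,gap_extend gap scores, recorded for interface completeness
#'   (the search engine extends without gaps).
#' @param min_word exact seed word length (default 11).
#' @param xdrop X-drop threshold in raw score units for ungapped extension.
#' @param min_raw_score minimum raw score for a hit to be reported.
#' @return a `scoring_scheme` list including `lambda` and `K`.
#' @export
scoring_scheme <- function(match_reward = 1L, mismatch_penalty = -2L,
                           gap_open = -5L, gap_extend = -2L,
                           min_word = 11L, xdrop = 15L, min_raw_score = 18L) {
  lk <- compute_lambda_k(match_reward, mismatch_penalty)
  structure(list(match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_word = as.integer(min_word), xdrop = as.integer(xdrop),
                 min_raw_score = as.integer(min_raw_score),
                 lambda = lk$lambda, K = lk$K),
            class = "scoring_scheme")
}

#' Karlin-Altschul lambda and K for a match/mismatch scheme
#'
#' @param match_reward positive match score.
#' @param mismatch_penalty negative mismatch score.
#' @return list with `lambda` and `K`.
#' @export
compute_lambda_k <- function(match_reward, mismatch_penalty) {
  stopifnot(match_reward > 0)
  p_match <- 0.25; p_mis <- 0.75
  expected <- p_match * match_reward + p_mis * mismatch_penalty
  if (expected >= 0)
    stop("expected score per aligned pair must be negative")
  f <- function(l) p_match * exp(l * match_reward) +
    p_mis * exp(l * mismatch_penalty) - 1
  lambda <- stats::uniroot(f, c(1e-9, 20), tol = 1e-12)$root
  A <- p_match * match_reward * exp(lambda * match_reward) +
    p_mis * mismatch_penalty * exp(lambda * mismatch_penalty)
  delta <- gcd2(abs(match_reward), abs(mismatch_penalty))
  K <- A * (1 - exp(-lambda * delta))
  list(lambda = lambda, K = K)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

as_subject <- function(subject) {
  if (inherits(subject, "genome_assembly"))
    return(subject$sequences)
  if (inherits(subject, "read_set"))
    return(all_reads(subject))
  if (is.character(subject)) {
    if (is.null(names(subject)))
      names(subject) <- sprintf("subject%d", seq_along(subject))
    return(subject)
  }
  stop("subject must be a genome_assembly, read_set, or named character vector")
}

#' Local similarity search
#'
#' Exact-word seeding, ungapped X-drop extension, both strands.  Overlapping
#' extensions on the same diagonal are merged.  E-value uses
#' `E = m * n * 2^(-bit_score)` with `m` the query length and `n` the total
#' subject length (summed over chromosomes or reads).
#'
#' @param query named character vector of query sequences (a single unnamed
#'   string is accepted).
#' @param subject a [genome_assembly()], `read_set`, or named character
#'   vector.
#' @param scheme a [scoring_scheme()].
#' @param evalue_max report only hits with E-value at or below this (default
#'   `Inf`: report everything above the raw-score floor).
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end` (0-based
#'   half-open), `strand`, `aligned_length`, `matches`, `mismatches`, `gaps`,
#'   `identity_percent`, `raw_score`, `bit_score`, `evalue`; sorted by query
#'   then increasing E-value.
#' @export
search_hits <- function(query, subject, scheme = scoring_scheme(),
                        evalue_max = Inf) {
  if (is.null(names(query)) && length(query) == 1) names(query) <- "query"
  stopifnot(!is.null(names(query)))
  query <- toupper(query)
  nfrac <- vapply(query, function(q) {
    mean(strsplit(q, "")[[1]] == "N")
  }, numeric(1))
  if (any(nfrac > 0.5)) stop("query with more than 50% N")
  subj <- as_subject(subject)
  if (length(subj) == 0 || all(!nzchar(subj))) stop("empty subject")
  if (any(nchar(query) < scheme$min_word))
    stop("query shorter than seed word length")
  raw <- cpp_search(unname(query), unname(subj),
                    scheme$match_reward, scheme$mismatch_penalty,
                    scheme$min_word, scheme$xdrop, scheme$min_raw_score)
  n_total <- sum(nchar(subj))
  hits <- data.frame(
    query_id = names(query)[raw$query],
    subject_id = names(subj)[raw$subject],
    query_start = raw$qstart, query_end = raw$qend,
    subject_start = raw$sstart, subject_end = raw$send,
    strand = raw$strand,
    aligned_length = raw$qend - raw$qstart,
    matches = raw$matches, mismatches = raw$mismatches,
    gaps = rep(0L, nrow(raw)),
    stringsAsFactors = FALSE)
  hits$identity_percent <- 100 * hits$matches / pmax(1L, hits$aligned_length)
  hits$raw_score <- raw$score
  hits$bit_score <- (scheme$lambda * hits$raw_score - log(scheme$K)) / log(2)
  m <- nchar(query)[raw$query]
  hits$evalue <- m * n_total * 2^(-hits$bit_score)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits <- hits[order(match(hits$query_id, names(query)), hits$evalue,
                     hits$subject_id, hits$subject_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Best hit per query
#'
#' Lowest E-value wins; ties broken by subject id then lowest subject
#' coordinate.
#'
#' @param hits a hit table from [search_hits()].
#' @return one row per query id present.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, hits$evalue, hits$subject_id, hits$subject_start)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Tally each query's best hit by chromosome
#'
#' @param hits a hit table (one probe set against one assembly).
#' @param evalue_cutoff hits above this E-value are ignored (default 1e-5).
#' @return a `chromosome_tally` list with `counts` (named integer vector),
#'   `total`, `preferential_chromosome` and `off_preferential_fraction`.
#' @export
tally_by_chromosome <- function(hits, evalue_cutoff = 1e-5) {
  hits <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  best <- best_hits(hits)
  if (nrow(best) == 0)
    return(structure(list(counts = integer(0), total = 0L,
                          preferential_chromosome = NA_character_,
                          off_preferential_fraction = NA_real_),
                     class = "chromosome_tally"))
  counts <- sort(table(best$subject_id), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  pref <- names(counts)[1]
  structure(list(counts = counts, total = sum(counts),
                 preferential_chromosome = pref,
                 off_preferential_fraction = 1 - counts[[pref]] / sum(counts)),
            class = "chromosome_tally")
}

#' @export
print.chromosome_tally <- function(x, ...) {
  cat(sprintf("<chromosome_tally> %d best hits, preferential = %s (off-fraction %.3f)\n",
              x$total, x$preferential_chromosome, x$off_preferential_fraction))
  invisible(x)
}

#' Write a hit table as TSV
#'
#' @param hits hit table from [search_hits()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
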