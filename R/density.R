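# D100: probe density of a moving window of 100 contiguous probes, in
# probes per kb of DNA spanned by those probes (first probe start to last
# probe end, inter-probe gaps included).

#' Density profile parameters
#'
#' @param window_probes number of contiguous probes per window (default 100).
#' @param step window advance in probes (default 1).
#' @return a `density_parameters` list.
#' @export
density_parameters <- function(window_probes = 100L, step = 1L) {
  stopifnot(window_probes >= 2, step >= 1)
  structure(list(window_probes = as.integer(window_probes),
                 step = as.integer(step)),
            class = "density_parameters")
}

#' Moving-window probe density profile for one chromosome
#'
#' Each window of `window_probes` consecutive probes spans from the start of
#' its first probe to the end of its last; its value is
#' `window_probes / (span / 1000)` probes per kb.  Chromosomes with fewer
#' probes than the window contribute no windows and report a missing median.
#'
#' @param starts,ends probe intervals (0-based half-open), sorted and
#'   non-overlapping, all on one chromosome.  Alternatively `starts` may be a
#'   probe data.frame with `start`/`end` (and optionally `chromosome`)
#'   columns.
#' @param params a [density_parameters()].
#' @param chromosome optional chromosome label for the profile.
#' @return a `density_profile` list: `chromosome`, `window_values`,
#'   `window_spans` (data.frame start/end), `median_d100`, `n_probes`.
#' @export
d100_profile <- function(starts, ends = NULL, params = density_parameters(),
                         chromosome = NA_character_) {
  if (is.data.frame(starts)) {
    df <- starts
    if ("chromosome" %in% names(df) && nrow(df) > 0) {
      if (length(unique(df$chromosome)) > 1)
        stop("d100_profile expects probes from a single chromosome")
      chromosome <- df$chromosome[1]
    }
    ends <- df$end; starts <- df$start
  }
  n <- length(starts)
  stopifnot(length(ends) == n)
  if (n > 1) {
    if (is.unsorted(starts)) stop("probe intervals must be sorted by start")
    if (any(starts[-1] < ends[-n])) stop("probe intervals must not overlap")
  }
  w <- params$window_probes
  if (n < w) {
    return(structure(list(chromosome = chromosome,
                          window_values = numeric(0),
                          window_spans = data.frame(start = integer(0),
                                                    end = integer(0)),
                          median_d100 = NA_real_, n_probes = n),
                     class = "density_profile"))
  }
  first <- seq.int(1L, n - w + 1L, by = params$step)
  last <- first + w - 1L
  span <- ends[last] - starts[first]
  vals <- w / (span / 1000)
  structure(list(chromosome = chromosome, window_values = vals,
                 window_spans = data.frame(start = starts[first],
                                           end = ends[last]),
                 median_d100 = median(vals), n_probes = n),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s: %d probes, %d windows, median D100 %s\n",
              x$chromosome, x$n_probes, length(x$window_values),
              ifelse(is.na(x$median_d100), "NA",
                     sprintf("%.3f probes/kb", x$median_d100))))
  invisible(x)
}

#' Pooled median D100 over one probe set's target chromosomes
#'
#' Pools the window values of all profiles and takes one median (pooling, not
#' a mean of per-chromosome medians).
#'
#' @param profiles a `density_profile` or list of them.
#' @return median D100 in probes/kb.
#' @export
median_d100 <- function(profiles) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  vals <- unlist(lapply(profiles, function(p) p$window_values))
  if (length(vals) == 0) stop("all profiles are empty")
  median(vals)
}

#' Fold reduction between an intra-genus and a cross-genus median D100
#'
#' @param intra_median origin-chromosome median D100 (probes/kb).
#' @param cross_median cross-genus median D100 (probes/kb).
#' @return `intra_median / cross_median` (vectorized).
#' @export
fold_reduction <- function(intra_median, cross_median) {
  if (any(intra_median <= 0) || any(cross_median <= 0))
    stop("medians must be positive")
  intra_median / cross_median
}

#' Write a density profile report as TSV
#'
#' @param profile a `density_profile`.
#' @param path output file.
#' @export
write_density_report <- function(profile, path) {
  df <- data.frame(chromosome = profile$chromosome,
                   window = seq_along(profile$window_values),
                   start = profile$window_spans$start,
                   end = profile$window_spans$end,
                   d100 = profile$window_values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
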