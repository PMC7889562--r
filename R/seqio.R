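# Sequence and table I/O.  One coordinate convention throughout: internally
# everything is 0-based half-open; user-facing region strings are 1-based
# inclusive ("chrSp19:30246-3907208" style).

#' Construct a genome assembly object
#'
#' @param sequences named character vector of chromosome sequences
#'   (A/C/G/T/N, uppercased on construction).
#' @param mask optional named list of data.frames with `start`/`end`
#'   (0-based half-open) giving soft-masked runs per chromosome.
#' @return an object of class `genome_assembly` with elements `sequences`,
#'   `mask` and `total_length`.
#' @export
genome_assembly <- function(sequences, mask = NULL) {
  if (length(sequences) == 0) stop("assembly must contain at least one sequence")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome identifiers")
  sequences <- vapply(sequences, toupper, character(1))
  if (any(!nzchar(sequences))) stop("empty sequence")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-nucleotide characters in: ", paste(names(sequences)[bad], collapse = ", "))
  structure(list(sequences = sequences, mask = mask,
                 total_length = sum(nchar(sequences))),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), %s bp total\n",
              length(x$sequences), format(x$total_length, big.mark = ",")))
  invisible(x)
}

chrom_lengths <- function(assembly) nchar(assembly$sequences)

#' Load a genome assembly from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Sequences are uppercased; lowercase (soft-masked) runs are preserved as a
#' mask track.
#'
#' @param path FASTA file (line-wrapped or single-line).
#' @return a [genome_assembly()].
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1L)
  seqs <- as.character(ss)
  names(seqs) <- ids
  mask <- lapply(seqs, function(s) {
    m <- gregexpr("[acgtn]+", s)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  mask <- mask[!vapply(mask, is.null, logical(1))]
  genome_assembly(seqs, mask = if (length(mask)) mask else NULL)
}

#' Write a genome assembly to FASTA (wrapped at 80 columns)
#'
#' @param assembly a [genome_assembly()].
#' @param path output file.
#' @export
write_genome <- function(assembly, path) {
  ss <- Biostrings::DNAStringSet(assembly$sequences)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Parse a 1-based inclusive region string
#'
#' `"chr1:1-100"` denotes the first 100 bases of chr1; internally the region
#' is stored 0-based half-open, so this parses to start 0, end 100.
#'
#' @param text region string `"<chrom>:<start>-<end>"`.
#' @param assembly optional [genome_assembly()] to validate against.
#' @return a `region_spec` list with `chromosome`, `start`, `end`,
#'   `source_text`.
#' @export
parse_region <- function(text, assembly = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4) stop("malformed region string: ", text)
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (end1 < start1) stop("region end before start: ", text)
  if (start1 < 1) stop("1-based coordinates must be >= 1: ", text)
  r <- structure(list(chromosome = m[2], start = start1 - 1, end = end1,
                      source_text = text), class = "region_spec")
  if (!is.null(assembly)) {
    if (!r$chromosome %in% names(assembly$sequences))
      stop("unknown chromosome: ", r$chromosome)
    if (r$end > nchar(assembly$sequences[[r$chromosome]]))
      stop("region extends past end of ", r$chromosome)
  }
  r
}

#' Format a region back to its 1-based inclusive string form
#'
#' @param region a `region_spec`.
#' @return character scalar; `parse_region(format_region(r))` equals `r`.
#' @export
format_region <- function(region) {
  sprintf("%s:%d-%d", region$chromosome, region$start + 1, region$end)
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s (length %s)\n", format_region(x),
              format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

region_length <- function(region) region$end - region$start

# Canonical probe table columns.  `start`/`end` are 0-based half-open.
PROBE_COLUMNS <- c("probe_id", "chromosome", "start", "end", "strand",
                   "sequence", "predicted_tm", "offtarget_fail",
                   "homeolog_fail", "msat_flagged", "selected",
                   "rejection_reason")

empty_probe_table <- function() {
  data.frame(probe_id = character(), chromosome = character(),
             start = integer(), end = integer(), strand = character(),
             sequence = character(), predicted_tm = numeric(),
             offtarget_fail = logical(), homeolog_fail = logical(),
             msat_flagged = logical(), selected = logical(),
             rejection_reason = character(), stringsAsFactors = FALSE)
}

check_probe_table <- function(probes) {
  missing <- setdiff(PROBE_COLUMNS, names(probes))
  if (length(missing)) stop("probe table missing columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(probes) > 1) {
    o <- order(probes$chromosome, probes$start)
    if (!identical(o, seq_len(nrow(probes))))
      stop("probe table must be sorted by (chromosome, start)")
  }
  invisible(probes)
}

#' Write a probe table as TSV or BED6
#'
#' BED output is 0-based half-open with score = `round(predicted_tm * 10)`;
#' TSV carries all columns including status flags and round-trips losslessly
#' through [read_probe_table()].
#'
#' @param probes probe data.frame sorted by (chromosome, start).
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_probe_table <- function(probes, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  check_probe_table(probes)
  if (format == "tsv") {
    write.table(probes[, PROBE_COLUMNS], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    bed <- data.frame(chrom = probes$chromosome, start = probes$start,
                      end = probes$end, name = probes$probe_id,
                      score = round(probes$predicted_tm * 10),
                      strand = probes$strand)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a probe table written by [write_probe_table()] (TSV format)
#'
#' @param path TSV file.
#' @return probe data.frame.
#' @export
read_probe_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(predicted_tm = "numeric"))
  if (nrow(df) == 0) return(empty_probe_table())
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  check_probe_table(df)
  df
}
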