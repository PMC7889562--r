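# Seeded synthetic-data generators: random genomes, diverged homeologs,
# chromosome fusions, satellite / microsatellite spikes, and 2 x 151 nt
# paired-end read simulation.  Every generator is a pure function of its
# arguments plus the seed.

#' Evolution parameters for sequence divergence
#'
#' @param indel_rate indel events per bp (default 0).
#' @param mean_indel_length mean indel length (geometric; default 3).
#' @return an `evolution_parameters` list.
#' @export
evolution_parameters <- function(indel_rate = 0, mean_indel_length = 3) {
  stopifnot(indel_rate >= 0, mean_indel_length >= 1)
  structure(list(indel_rate = indel_rate,
                 mean_indel_length = mean_indel_length),
            class = "evolution_parameters")
}

random_sequence <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

#' Generate a random genome assembly
#'
#' I.i.d. uniform A/C/G/T per chromosome.
#'
#' @param lengths named (or unnamed; names auto-assigned chr1, chr2, ...)
#'   integer vector of chromosome lengths.
#' @param seed RNG seed.
#' @return a [genome_assembly()].
#' @export
make_genome <- function(lengths, seed = 1) {
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(lengths)))
    names(lengths) <- sprintf("chr%d", seq_along(lengths))
  with_seed(seed, {
    seqs <- vapply(lengths, random_sequence, character(1))
    genome_assembly(seqs)
  })
}

# Substitute at `idx` (1-based) with uniformly chosen different bases.
substitute_bases <- function(seq, idx) {
  if (length(idx) == 0) return(seq)
  raw <- charToRaw(seq)
  cur <- rawToChar(raw[idx], multiple = TRUE)
  pick <- vapply(cur, function(b) sample(setdiff(BASES, b), 1), character(1))
  raw[idx] <- charToRaw(paste(pick, collapse = ""))
  rawToChar(raw)
}

#' Evolve a sequence to a requested divergence
#'
#' Substitutions are placed uniformly (without replacement) so the realized
#' substitution divergence equals the request up to rounding; indels (if any)
#' are applied afterwards with geometric lengths.
#'
#' @param sequence nucleotide string.
#' @param divergence_percent requested substitution divergence in `[0, 100)`.
#' @param params an [evolution_parameters()].
#' @param seed RNG seed.
#' @return evolved sequence string.
#' @export
evolve <- function(sequence, divergence_percent,
                   params = evolution_parameters(), seed = 1) {
  stopifnot(divergence_percent >= 0, divergence_percent < 100)
  with_seed(seed, {
    n <- nchar(sequence)
    nsub <- round(n * divergence_percent / 100)
    if (nsub > 0)
      sequence <- substitute_bases(sequence, sample.int(n, nsub))
    if (params$indel_rate > 0) {
      n <- nchar(sequence)
      nev <- rbinom(1, n, params$indel_rate)
      if (nev > 0) {
        at <- sort(sample.int(n, nev))
        lens <- 1 + stats::rgeom(nev, 1 / params$mean_indel_length)
        isdel <- runif(nev) < 0.5
        pieces <- character(0)
        prev <- 1
        for (i in seq_len(nev)) {
          if (isdel[i]) {
            stop_at <- min(n, at[i] + lens[i] - 1)
            pieces <- c(pieces, substring(sequence, prev, at[i] - 1))
            prev <- stop_at + 1
          } else {
            pieces <- c(pieces, substring(sequence, prev, at[i] - 1),
                        random_sequence(lens[i]))
            prev <- at[i]
          }
        }
        pieces <- c(pieces, substring(sequence, prev, n))
        sequence <- paste(pieces, collapse = "")
      }
    }
    sequence
  })
}

#' Build a reference genome and a sister genome with a chromosome fusion
#'
#' The reference carries two chromosomes; the sister carries their diverged
#' fusion (`chrF = evolve(chrA) ++ evolve(chrB)`), emulating a pair of
#' homeologous chromosomes fused into one in a sister species.
#'
#' @param chr_lengths lengths of the two reference chromosomes.
#' @param divergence_percent per-branch divergence applied to each segment
#'   (default 5, a typical intra-genus distance).
#' @param params an [evolution_parameters()].
#' @param seed RNG seed.
#' @return list with `reference` and `sister` ([genome_assembly()]s) and a
#'   `manifest` (fused chromosome name, breakpoint coordinate, per-segment
#'   source chromosomes and divergence).
#' @export
make_fusion_pair <- function(chr_lengths = c(chrA = 300000L, chrB = 200000L),
                             divergence_percent = 5,
                             params = evolution_parameters(), seed = 1) {
  if (length(chr_lengths) != 2) stop("fusion requires exactly two chromosomes")
  if (is.null(names(chr_lengths))) names(chr_lengths) <- c("chrA", "chrB")
  reference <- make_genome(chr_lengths, seed = seed)
  segA <- evolve(reference$sequences[[1]], divergence_percent, params,
                 seed = seed + 1L)
  segB <- evolve(reference$sequences[[2]], divergence_percent, params,
                 seed = seed + 2L)
  sister <- genome_assembly(c(chrF = paste0(segA, segB)))
  list(reference = reference, sister = sister,
       manifest = list(fused_chromosome = "chrF",
                       breakpoint = nchar(segA),
                       segment_sources = names(chr_lengths),
                       divergence_percent = divergence_percent,
                       seed = seed))
}

#' Spike a tandem satellite array into a genome
#'
#' A seeded random monomer is tandemly repeated and split across `n_loci`
#' random insertion points so that the total array length is as close to
#' `target_fraction` of the genome as whole monomers allow.
#'
#' @param genome a [genome_assembly()].
#' @param monomer_length monomer length in bp.
#' @param target_fraction fraction of the (pre-insertion) genome the array
#'   should occupy; alternatively give `copies` directly.
#' @param copies total monomer copies (overrides `target_fraction`).
#' @param n_loci number of insertion loci (default 1).
#' @param seed RNG seed.
#' @return list with `genome` (spiked assembly) and `manifest` (monomer,
#'   loci, copies and realized fraction).
#' @export
spike_tandem_array <- function(genome, monomer_length,
                               target_fraction = NULL, copies = NULL,
                               n_loci = 1L, seed = 1) {
  glen <- genome$total_length
  if (is.null(copies)) {
    if (is.null(target_fraction)) stop("give target_fraction or copies")
    copies <- round(target_fraction * glen / monomer_length)
  }
  if (copies * monomer_length > 0.2 * glen)
    stop("array would exceed 20% of the genome")
  with_seed(seed, {
    monomer <- random_sequence(monomer_length)
    if (copies == 0) {
      return(list(genome = genome,
                  manifest = list(monomer = monomer,
                                  monomer_length = monomer_length,
                                  copies = 0L, loci = data.frame(),
                                  realized_fraction = 0)))
    }
    per_locus <- diff(round(seq(0, copies, length.out = n_loci + 1)))
    per_locus <- per_locus[per_locus > 0]
    seqs <- genome$sequences
    loci <- data.frame(chromosome = character(0), position = integer(0),
                       copies = integer(0))
    for (cp in per_locus) {
      ci <- sample.int(length(seqs), 1)
      pos <- sample.int(nchar(seqs[[ci]]) - 1L, 1)
      seqs[[ci]] <- paste0(substring(seqs[[ci]], 1, pos),
                           strrep(monomer, cp),
                           substring(seqs[[ci]], pos + 1, nchar(seqs[[ci]])))
      loci <- rbind(loci, data.frame(chromosome = names(seqs)[ci],
                                     position = pos, copies = cp))
    }
    spiked <- genome_assembly(seqs)
    list(genome = spiked,
         manifest = list(monomer = monomer, monomer_length = monomer_length,
                         copies = as.integer(sum(per_locus)), loci = loci,
                         realized_fraction =
                           sum(per_locus) * monomer_length / spiked$total_length))
  })
}

#' Spike microsatellite runs into a genome
#'
#' @param genome a [genome_assembly()].
#' @param motif repeat unit (e.g. `"GA"`).
#' @param units repeat units per spike.
#' @param n_loci number of insertion loci.
#' @param seed RNG seed.
#' @return list with `genome` and `manifest` (loci data.frame).
#' @export
spike_microsatellite <- function(genome, motif = "GA", units = 15,
                                 n_loci = 5L, seed = 1) {
  with_seed(seed, {
    seqs <- genome$sequences
    run <- strrep(toupper(motif), units)
    loci <- data.frame(chromosome = character(0), position = integer(0))
    for (i in seq_len(n_loci)) {
      ci <- sample.int(length(seqs), 1)
      pos <- sample.int(nchar(seqs[[ci]]) - 1L, 1)
      seqs[[ci]] <- paste0(substring(seqs[[ci]], 1, pos), run,
                           substring(seqs[[ci]], pos + 1, nchar(seqs[[ci]])))
      loci <- rbind(loci, data.frame(chromosome = names(seqs)[ci],
                                     position = pos))
    }
    list(genome = genome_assembly(seqs),
         manifest = list(motif = motif, units = units, loci = loci))
  })
}

#' Simulate paired-end reads
#'
#' Fragments are placed uniformly with normal insert sizes; each pair is R1
#' from one end and R2 reverse-complemented from the other, fragment strand
#' chosen at random.  Per-base errors substitute a uniformly chosen
#' different base.  The expected pair count is
#' `coverage * genome_length / (2 * read_length)`.
#'
#' @param genome a [genome_assembly()].
#' @param coverage target depth.
#' @param read_length read length in nt (default 151).
#' @param insert_mean,insert_sd fragment length distribution (defaults 350
#'   and 50).
#' @param error_rate per-base substitution error rate (default 0).
#' @param seed RNG seed.
#' @return a `read_set`: list with `r1`, `r2` (character vectors),
#'   `read_length`, `trimmed_length` (NA until trimming), `n_pairs`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 151L,
                           insert_mean = 350, insert_sd = 50,
                           error_rate = 0, seed = 1) {
  stopifnot(coverage > 0)
  if (insert_mean < read_length) stop("insert mean shorter than read length")
  with_seed(seed, {
    lens <- chrom_lengths(genome)
    n_pairs_total <- round(coverage * sum(lens) / (2 * read_length))
    chrom_idx <- sample.int(length(lens), n_pairs_total, replace = TRUE,
                            prob = lens / sum(lens))
    r1 <- character(n_pairs_total); r2 <- character(n_pairs_total)
    for (ci in seq_along(lens)) {
      sel <- which(chrom_idx == ci)
      if (length(sel) == 0) next
      L <- lens[ci]
      ins <- pmin(pmax(round(rnorm(length(sel), insert_mean, insert_sd)),
                       read_length), L)
      start <- floor(runif(length(sel), min = 0, max = L - ins)) + 1L
      fwd <- substring(genome$sequences[[ci]], start, start + read_length - 1L)
      rev <- revcomp(substring(genome$sequences[[ci]],
                               start + ins - read_length, start + ins - 1L))
      flip <- runif(length(sel)) < 0.5
      r1[sel] <- ifelse(flip, rev, fwd)
      r2[sel] <- ifelse(flip, fwd, rev)
    }
    if (error_rate > 0) {
      for (mate in 1:2) {
        reads <- if (mate == 1) r1 else r2
        total <- length(reads) * read_length
        nerr <- rbinom(1, total, error_rate)
        if (nerr > 0) {
          at <- sample.int(total, nerr)
          ridx <- (at - 1L) %/% read_length + 1L
          pos <- (at - 1L) %% read_length + 1L
          cur <- substring(reads[ridx], pos, pos)
          newb <- vapply(cur, function(b) sample(setdiff(BASES, b), 1),
                         character(1), USE.NAMES = FALSE)
          reads <- cpp_apply_subs(reads, ridx, pos, newb)
        }
        if (mate == 1) r1 <- reads else r2 <- reads
      }
    }
    structure(list(r1 = r1, r2 = r2, read_length = as.integer(read_length),
                   trimmed_length = NA_integer_,
                   n_pairs = n_pairs_total),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d pairs, read length %d%s\n", x$n_pairs,
              x$read_length,
              ifelse(is.na(x$trimmed_length), "",
                     sprintf(" (trimmed to %d)", x$trimmed_length))))
  invisible(x)
}

all_reads <- function(reads) {
  out <- c(reads$r1, reads$r2)
  names(out) <- c(sprintf("read%d/1", seq_along(reads$r1)),
                  sprintf("read%d/2", seq_along(reads$r2)))
  out
}

#' Write a read set as a FASTQ pair
#'
#' Constant high base quality ("I"); quality modeling is out of scope.
#'
#' @param reads a `read_set`.
#' @param path1,path2 output FASTQ files for mates 1 and 2.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  qual <- strrep("I", nchar(reads$r1[1]))
  for (mate in 1:2) {
    rr <- if (mate == 1) reads$r1 else reads$r2
    path <- if (mate == 1) path1 else path2
    lines <- as.vector(rbind(sprintf("@read%d/%d", seq_along(rr), mate),
                             rr, "+", strrep("I", nchar(rr))))
    writeLines(lines, path)
  }
  invisible(c(path1, path2))
}

#' Load a FASTQ pair into a read set
#'
#' @param path1,path2 FASTQ files (plain text) for mates 1 and 2.
#' @return a `read_set`.
#' @export
load_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) stop("mismatched pair files")
  structure(list(r1 = unname(as.character(s1)),
                 r2 = unname(as.character(s2)),
                 read_length = max(Biostrings::width(s1)),
                 trimmed_length = NA_integer_, n_pairs = length(s1)),
            class = "read_set")
}
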