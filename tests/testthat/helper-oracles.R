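# Independent oracles, written against the published formulas before the
# package implementations and kept separate from them.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Second, literal transcription of the unified nearest-neighbor table
# (dH kcal/mol, dS cal/mol/K) with the entropy salt correction; structured
# deliberately differently from the package (matrix lookup, explicit loop).
oracle_tm <- function(seq, na_molar = 0.33, ct_molar = 0.25e-6) {
  tab <- rbind(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9),
    # complementary-strand equivalents
    TT = c(-7.9, -22.2), TG = c(-8.5, -22.7), AC = c(-8.4, -22.4),
    AG = c(-7.8, -21.0), TC = c(-8.2, -22.2), CC = c(-8.0, -19.9))
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  dh <- 0; ds <- 0
  for (i in 1:(L - 1)) {
    row <- tab[paste0(ch[i], ch[i + 1]), ]
    dh <- dh + row[1]; ds <- ds + row[2]
  }
  for (term in c(ch[1], ch[L])) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (L - 1) * log(na_molar)
  1000 * dh / (ds + 1.9872 * log(ct_molar / 4)) - 273.15
}

# Bracketed bisection for the Karlin-Altschul lambda at uniform base
# frequencies.
oracle_lambda <- function(match, mismatch, iters = 200) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lo <- 1e-9; hi <- 20
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Exact maximum-cardinality non-overlapping subset by dynamic programming
# over intervals sorted by start (independent of the greedy scan).
oracle_max_nonoverlap <- function(starts, ends) {
  n <- length(starts)
  if (n == 0) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  best <- integer(n + 1)           # best[i] = optimum using intervals i..n
  for (i in n:1) {
    nxt <- which(starts[(i + 1):n] >= ends[i])
    take <- 1L + if (i < n && length(nxt)) best[i + nxt[1]] else 0L
    best[i] <- max(best[i + 1], take)
  }
  best[1]
}

# Exhaustive both-strand scan for exact occurrences of a query.
oracle_exact_positions <- function(query, subject) {
  fwd <- gregexpr(query, subject, fixed = TRUE)[[1]]
  rev <- gregexpr(revcomp(query), subject, fixed = TRUE)[[1]]
  list(fwd = if (fwd[1] == -1) integer(0) else as.integer(fwd) - 1L,
       rev = if (rev[1] == -1) integer(0) else as.integer(rev) - 1L)
}

rotations_of <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i) paste0(substring(s, i, n),
                                        substring(s, 1, i - 1)), character(1))
}

extdata <- function(file) system.file("extdata", file, package = "chromopaint")
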