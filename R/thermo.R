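# Nearest-neighbor duplex melting temperature at the hybridization salt
# condition (330 mM monovalent cation, i.e. 2x SSC), plus a linear
# identity-based penalty for mismatched probe/target duplexes.

# Unified nearest-neighbor parameters (DNA/DNA, 1 M NaCl): dH in kcal/mol,
# dS in cal/(mol K), indexed by the top-strand dinucleotide.
NN_UNIFIED <- local({
  din <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
           "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  dh <- c(-7.9, -8.4, -7.8, -7.2, -8.5, -8.0, -10.6, -7.8,
          -8.2, -9.8, -8.0, -8.4, -7.2, -8.2, -8.5, -7.9)
  ds <- c(-22.2, -22.4, -21.0, -20.4, -22.7, -19.9, -27.2, -21.0,
          -22.2, -24.4, -19.9, -22.4, -21.3, -22.2, -22.7, -22.2)
  list(dinucleotides = din, dh = setNames(dh, din), ds = setNames(ds, din),
       init_gc = c(dh = 0.1, ds = -2.8), init_at = c(dh = 2.3, ds = 4.1))
})

#' Duplex prediction parameters
#'
#' @param sodium_molar monovalent cation concentration in mol/L.  The default
#'   0.33 M corresponds to the 2x SSC wash condition.
#' @param strand_molar assumed probe strand concentration for the Tm formula
#'   (mol/L).  Shifts all Tm values equally, so relative screening is
#'   unaffected by this convention.
#' @param mismatch_penalty_per_percent Tm penalty in degrees C per percentage
#'   point of identity lost in a mismatched duplex (linear rule of thumb).
#' @param nn_table_name name of the nearest-neighbor table; only
#'   `"unified"` is shipped.
#' @return a `duplex_parameters` list.
#' @export
duplex_parameters <- function(sodium_molar = 0.33, strand_molar = 0.25e-6,
                              mismatch_penalty_per_percent = 1.0,
                              nn_table_name = "unified") {
  stopifnot(sodium_molar > 0, strand_molar > 0,
            mismatch_penalty_per_percent >= 0)
  if (!identical(nn_table_name, "unified"))
    stop("unknown nn_table_name: ", nn_table_name)
  nn <- NN_UNIFIED
  if (length(nn$dh) != 16) stop("nn table must cover all 16 dinucleotides")
  structure(list(sodium_molar = sodium_molar, strand_molar = strand_molar,
                 mismatch_penalty_per_percent = mismatch_penalty_per_percent,
                 nn_table_name = nn_table_name, nn_table = nn),
            class = "duplex_parameters")
}

# Order dH/dS by 4*first+second (A=0,C=1,G=2,T=3) for the C++ kernel.
nn_vectors <- function(params) {
  din <- paste0(rep(BASES, each = 4), rep(BASES, 4))  # AA, AC, AG, AT, CA, ...
  list(dh = unname(params$nn_table$dh[din]), ds = unname(params$nn_table$ds[din]))
}

#' Predict perfect-match duplex melting temperature
#'
#' Nearest-neighbor model:
#' `Tm = 1000 * dH / (dS_salt + R * ln(CT/4)) - 273.15`, where the salt
#' correction adds `0.368 * (L - 1) * ln([Na+])` cal/(mol K) to the duplex
#' entropy.
#'
#' @param sequence character vector of probe sequences (A/C/G/T, length >= 8).
#' @param params a [duplex_parameters()].
#' @return numeric vector of Tm in degrees C.
#' @export
predict_tm <- function(sequence, params = duplex_parameters()) {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) < 8)) stop("sequence shorter than 8 nt")
  if (any(grepl("[^ACGT]", sequence)))
    stop("sequence must contain only A/C/G/T")
  nn <- nn_vectors(params)
  cpp_tm(sequence, nn$dh, nn$ds,
         NN_UNIFIED$init_gc[["dh"]], NN_UNIFIED$init_gc[["ds"]],
         NN_UNIFIED$init_at[["dh"]], NN_UNIFIED$init_at[["ds"]],
         params$sodium_molar, params$strand_molar)
}

#' Effective Tm of a mismatched duplex
#'
#' Applies the linear identity penalty: each percentage point of identity
#' below 100% lowers the perfect-match Tm by
#' `mismatch_penalty_per_percent` degrees C.
#'
#' @param perfect_tm perfect-match Tm in degrees C (vectorized).
#' @param identity_percent identity of the duplex in (0, 100].
#' @param params a [duplex_parameters()].
#' @return list with `tm_celsius`, `identity_percent` and `basis`
#'   (`"perfect_match"` or `"identity_adjusted"`).
#' @export
effective_duplex_tm <- function(perfect_tm, identity_percent,
                                params = duplex_parameters()) {
  if (any(identity_percent <= 0) || any(identity_percent > 100))
    stop("identity_percent must be in (0, 100]")
  tm <- perfect_tm - params$mismatch_penalty_per_percent * (100 - identity_percent)
  list(tm_celsius = tm, identity_percent = identity_percent,
       basis = ifelse(identity_percent < 100, "identity_adjusted",
                      "perfect_match"))
}
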