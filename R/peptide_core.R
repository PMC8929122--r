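# Canonical peptide representation: validation, positional access, residue
# feature sets and monoisotopic mass. Everything downstream builds on these.

# Monoisotopic residue masses (Da), standard values for the 20 canonical
# amino acids; peptide mass = sum(residues) + one water.
.RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_MONO_MASS <- 18.0105646863

.CANONICAL_AA <- names(.RESIDUE_MONO_MASS)

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes accepted throughout the
#' package. Ambiguous and non-standard codes (B, J, O, U, X, Z) are rejected
#' by [validate_sequence()].
#'
#' @return Character vector of 20 single-letter codes.
#' @export
canonical_residues <- function() .CANONICAL_AA

#' Positional residue feature sets used by the SAR engine
#'
#' Fixed residue sets describing the positional features repeatedly observed
#' in potent DPP-IV-inhibitory peptides: a hydrophobic N-terminal residue, a
#' P/A residue in second position, a hydrophobic C-terminus for tri-peptides,
#' and P/L/R at the C-terminus with A/V/G/P in third position for
#' tetra-peptides and longer.
#'
#' @return Named list of character vectors:
#'   `hydrophobic_nterm` (I, L, V, A, F, W), `hydrophobic_cterm_tri`
#'   (A, I, L, G, M, F), `pos2_set` (P, A), `cterm_tetra_set` (P, L, R),
#'   `pos3_tetra_set` (A, V, G, P).
#' @export
residue_feature_sets <- function() {
  list(
    hydrophobic_nterm     = c("I", "L", "V", "A", "F", "W"),
    hydrophobic_cterm_tri = c("A", "I", "L", "G", "M", "F"),
    pos2_set              = c("P", "A"),
    cterm_tetra_set       = c("P", "L", "R"),
    pos3_tetra_set        = c("A", "V", "G", "P")
  )
}

#' Validate and normalize a peptide sequence
#'
#' Uppercases the input and checks every character against the canonical
#' 20-letter amino-acid alphabet. Validation is idempotent: a validated
#' sequence passes through unchanged.
#'
#' @param raw Single character string, the peptide sequence.
#' @param min_length Minimum accepted length (default 1; screening pools
#'   require 2, see [read_peptide_pool()]).
#' @return The normalized (uppercase) sequence.
#' @examples
#' validate_sequence("sapi")  # "SAPI"
#' @export
validate_sequence <- function(raw, min_length = 1L) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("peptide sequence must be a single character string", call. = FALSE)
  }
  if (nchar(raw) == 0L) {
    stop("peptide sequence is empty", call. = FALSE)
  }
  seq <- toupper(raw)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .CANONICAL_AA)
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid residue '%s' at position %d in sequence '%s'",
      chars[bad[1L]], bad[1L], raw
    ), call. = FALSE)
  }
  if (nchar(seq) < min_length) {
    stop(sprintf(
      "sequence '%s' shorter than minimum length %d", seq, min_length
    ), call. = FALSE)
  }
  seq
}

#' Residue at a named or indexed position
#'
#' Positions are 1-based from the N-terminus. `"n_term"` is position 1,
#' `"c_term"` the last residue and `"penultimate"` the second-to-last.
#'
#' @param p Peptide sequence (validated with [validate_sequence()]).
#' @param where Either an integer index or one of `"n_term"`, `"c_term"`,
#'   `"penultimate"`.
#' @return Single-character residue.
#' @examples
#' residue_at("SAPI", "n_term")  # "S"
#' residue_at("FVPH", 3)         # "P"
#' @export
residue_at <- function(p, where) {
  p <- validate_sequence(p)
  n <- nchar(p)
  idx <- if (is.character(where)) {
    switch(where,
      n_term = 1L,
      c_term = n,
      penultimate = n - 1L,
      stop(sprintf("unknown position spec '%s'", where), call. = FALSE)
    )
  } else {
    as.integer(where)
  }
  if (is.na(idx) || idx < 1L || idx > n) {
    stop(sprintf(
      "position %s out of range for peptide '%s' (length %d)",
      as.character(where), p, n
    ), call. = FALSE)
  }
  substr(p, idx, idx)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, accurate to well under
#' 1e-3 Da against independent mass calculators.
#'
#' @param p Peptide sequence.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("SAPI")  # 386.2165
#' @export
monoisotopic_mass <- function(p) {
  p <- validate_sequence(p)
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  sum(.RESIDUE_MONO_MASS[chars]) + .WATER_MONO_MASS
}

#' Read a peptide pool table
#'
#' Reads a TSV or CSV peptide pool with required column `sequence` and
#' optional columns `precursor`, `rank_score` (bioactivity-rank prediction in
#' \[0,1\]) and `binding_pvalue` (active-site binding p-value in (0,1\]).
#' Sequences are validated and uppercased; pool members must have at least
#' two residues. Missing optional values stay `NA` — the funnel treats a
#' missing score as "not scored", never as a pass.
#'
#' @param path Path to the pool file. Separator is inferred from the
#'   extension (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param sep Optional field separator override.
#' @return Data frame with columns `sequence`, `precursor`, `rank_score`,
#'   `binding_pvalue`; class `c("peptide_pool", "data.frame")`.
#' @export
read_peptide_pool <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("pool file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          na.strings = c("", "NA"))
  if (!"sequence" %in% names(df)) {
    stop("pool file must have a 'sequence' column", call. = FALSE)
  }
  as_peptide_pool(df)
}

#' Build a peptide pool from a data frame
#'
#' Validates sequences (minimum length 2), normalizes to uppercase, checks
#' `rank_score` is in \[0,1\] and `binding_pvalue` in (0,1\] where present,
#' and fills absent optional columns with `NA`.
#'
#' @param df Data frame with at least a `sequence` column.
#' @return Data frame of class `c("peptide_pool", "data.frame")`.
#' @export
as_peptide_pool <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sequence" %in% names(df)) stop("'sequence' column required", call. = FALSE)
  df$sequence <- vapply(df$sequence, validate_sequence, character(1L),
                        min_length = 2L, USE.NAMES = FALSE)
  n <- nrow(df)
  if (!"precursor" %in% names(df)) df$precursor <- rep(NA_character_, n)
  if (!"rank_score" %in% names(df)) df$rank_score <- rep(NA_real_, n)
  if (!"binding_pvalue" %in% names(df)) df$binding_pvalue <- rep(NA_real_, n)
  df$rank_score <- as.numeric(df$rank_score)
  df$binding_pvalue <- as.numeric(df$binding_pvalue)
  bad_rank <- !is.na(df$rank_score) & (df$rank_score < 0 | df$rank_score > 1)
  if (any(bad_rank)) {
    stop(sprintf("rank_score outside [0,1] for '%s'",
                 df$sequence[which(bad_rank)[1L]]), call. = FALSE)
  }
  bad_p <- !is.na(df$binding_pvalue) &
    (df$binding_pvalue <= 0 | df$binding_pvalue > 1)
  if (any(bad_p)) {
    stop(sprintf("binding_pvalue outside (0,1] for '%s'",
                 df$sequence[which(bad_p)[1L]]), call. = FALSE)
  }
  df <- df[, c("sequence", "precursor", "rank_score", "binding_pvalue",
               setdiff(names(df), c("sequence", "precursor", "rank_score",
                                    "binding_pvalue")))]
  class(df) <- c("peptide_pool", "data.frame")
  df
}
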