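# Rule-based structure-activity-relationship engine for DPP-IV-inhibitory
# peptides. Each feature is a pure predicate on the sequence with a length
# applicability class; selection requires a minimum number of matched
# selection-eligible features (default 2).

#' The SAR feature catalog
#'
#' Positional residue features associated with potent (IC50 < 100 umol/L)
#' DPP-IV-inhibitory peptides:
#' \describe{
#'   \item{F1_HYDRO_NTERM}{hydrophobic residue (I, L, V, A, F, W) at the
#'     N-terminus; any length.}
#'   \item{F2_PA_POS2}{P or A in second position; any length.}
#'   \item{F3_Q_NTERM}{Q at the N-terminus; tri-peptides only.}
#'   \item{F4_HYDRO_CTERM}{hydrophobic residue (A, I, L, G, M, F) at the
#'     C-terminus; tri-peptides only.}
#'   \item{F5_PLR_CTERM}{P, L or R at the C-terminus; tetra-peptides and
#'     longer.}
#'   \item{F6_AVGP_POS3}{A, V, G or P in third position; tetra-peptides and
#'     longer.}
#'   \item{S_NTERM_NOVEL}{S at the N-terminus — an annotation-only feature
#'     proposed from the validated candidates; reported but never counted
#'     towards selection.}
#' }
#'
#' For peptides longer than four residues the "third position" reading
#' (from the N-terminus) is used for F6 and a warning notes that it then
#' differs from the penultimate-position reading, which coincides with it
#' only for tetra-peptides.
#'
#' @param min_features Minimum number of matched eligible features required
#'   for selection (default 2).
#' @return Object of class `sar_catalog`.
#' @export
sar_catalog <- function(min_features = 2L) {
  fs <- residue_feature_sets()
  features <- list(
    F1_HYDRO_NTERM = list(
      description = "hydrophobic N-terminal residue (I/L/V/A/F/W)",
      applicable = function(n) n >= 2L,
      predicate = function(p) residue_at(p, "n_term") %in% fs$hydrophobic_nterm,
      eligible = TRUE
    ),
    F2_PA_POS2 = list(
      description = "P or A in second position",
      applicable = function(n) n >= 2L,
      predicate = function(p) residue_at(p, 2L) %in% fs$pos2_set,
      eligible = TRUE
    ),
    F3_Q_NTERM = list(
      description = "Q at the N-terminus (tri-peptides)",
      applicable = function(n) n == 3L,
      predicate = function(p) residue_at(p, "n_term") == "Q",
      eligible = TRUE
    ),
    F4_HYDRO_CTERM = list(
      description = "hydrophobic C-terminal residue (A/I/L/G/M/F, tri-peptides)",
      applicable = function(n) n == 3L,
      predicate = function(p) residue_at(p, "c_term") %in% fs$hydrophobic_cterm_tri,
      eligible = TRUE
    ),
    F5_PLR_CTERM = list(
      description = "P, L or R at the C-terminus (tetra-peptides and longer)",
      applicable = function(n) n >= 4L,
      predicate = function(p) residue_at(p, "c_term") %in% fs$cterm_tetra_set,
      eligible = TRUE
    ),
    F6_AVGP_POS3 = list(
      description = "A, V, G or P in third position (tetra-peptides and longer)",
      applicable = function(n) n >= 4L,
      predicate = function(p) residue_at(p, 3L) %in% fs$pos3_tetra_set,
      eligible = TRUE
    ),
    S_NTERM_NOVEL = list(
      description = "S at the N-terminus (annotation only)",
      applicable = function(n) n >= 2L,
      predicate = function(p) residue_at(p, "n_term") == "S",
      eligible = FALSE
    )
  )
  structure(list(features = features, min_features = as.integer(min_features)),
            class = "sar_catalog")
}

#' Match SAR features against a peptide
#'
#' Evaluates every feature whose length-applicability holds; features of the
#' wrong length class are never reported.
#'
#' @param p Peptide sequence (length >= 2).
#' @param catalog A [sar_catalog()].
#' @return Character vector of matched feature ids.
#' @examples
#' match_features("SAPI")  # F2_PA_POS2, F6_AVGP_POS3, S_NTERM_NOVEL
#' @export
match_features <- function(p, catalog = sar_catalog()) {
  p <- validate_sequence(p, min_length = 2L)
  n <- nchar(p)
  if (n > 4L) {
    warning(sprintf(
      "peptide '%s' is longer than 4 residues: 'third position' and 'penultimate position' readings of the position-3 feature diverge; using third position from the N-terminus",
      p), call. = FALSE)
  }
  ids <- names(catalog$features)
  hit <- vapply(ids, function(id) {
    f <- catalog$features[[id]]
    f$applicable(n) && f$predicate(p)
  }, logical(1L))
  ids[hit]
}

#' SAR selection verdict for one peptide
#'
#' A peptide is selected when at least `catalog$min_features` (default 2)
#' selection-eligible features match. Annotation-only features are reported
#' in the match set and rationale but never counted.
#'
#' @param p Peptide sequence.
#' @param catalog A [sar_catalog()].
#' @return Object of class `sar_result`: list with `sequence`,
#'   `matched_features`, `eligible_matches`, `selected`, `rationale`.
#' @examples
#' sar_select("SIPR")$selected  # TRUE
#' sar_select("FV")$selected    # FALSE
#' @export
sar_select <- function(p, catalog = sar_catalog()) {
  matched <- suppressWarnings(match_features(p, catalog))
  eligible <- matched[vapply(matched, function(id) catalog$features[[id]]$eligible,
                             logical(1L))]
  selected <- length(eligible) >= catalog$min_features
  rationale <- if (length(matched) == 0L) {
    "no SAR features matched"
  } else {
    paste(vapply(matched, function(id) catalog$features[[id]]$description,
                 character(1L)), collapse = "; ")
  }
  structure(
    list(sequence = validate_sequence(p), matched_features = matched,
         eligible_matches = eligible, selected = selected,
         rationale = rationale),
    class = "sar_result"
  )
}

#' @export
print.sar_result <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$sequence,
              if (x$selected) "SELECTED" else "not selected", x$rationale))
  invisible(x)
}

#' SAR selection over a set of peptide records
#'
#' @param records A `peptide_pool` data frame or character vector of
#'   sequences.
#' @param catalog A [sar_catalog()].
#' @return Data frame in input order with columns `sequence`,
#'   `matched_features` (semicolon-joined ids), `n_eligible`, `selected`,
#'   `rationale`; attribute `n_selected` carries the summary count.
#' @export
batch_sar <- function(records, catalog = sar_catalog()) {
  seqs <- if (is.character(records)) records else records$sequence
  results <- lapply(seqs, sar_select, catalog = catalog)
  out <- data.frame(
    sequence = vapply(results, `[[`, character(1L), "sequence"),
    matched_features = vapply(results, function(r)
      paste(r$matched_features, collapse = ";"), character(1L)),
    n_eligible = vapply(results, function(r) length(r$eligible_matches),
                        integer(1L)),
    selected = vapply(results, `[[`, logical(1L), "selected"),
    rationale = vapply(results, `[[`, character(1L), "rationale"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_selected") <- sum(out$selected)
  out
}
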