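# Known-bioactive-peptide reference table (BIOPEP-style): exact full-sequence
# lookup and activity-category counting. A 37-entry table of peptides found in
# in vitro-digested pinto bean protein extract ships with the package.

.ACTIVITY_LABELS <- c("ACE-inhibition", "DPP-IV-inhibition", "Antioxidant")

#' Path to the bundled known-bioactivity reference table
#'
#' A 37-entry table of short peptides (di- to tetra-peptides) with previously
#' reported ACE-inhibitory, DPP-IV-inhibitory or antioxidant activity, as
#' identified by exact-match database search in a digested pinto bean
#' protein extract.
#'
#' @return Path to the bundled TSV file.
#' @export
bundled_reference_path <- function() {
  system.file("extdata", "known_bioactive_peptides.tsv",
              package = "pepfunnel", mustWork = TRUE)
}

#' Path to the bundled screening-candidate fixture
#'
#' The 15-peptide screening table used in the worked example: sequences with
#' active-site binding p-values against DPP-IV (PDB 1NU6) and a flag marking
#' those already characterized as DPP-IV inhibitors.
#'
#' @return Path to the bundled TSV file.
#' @export
bundled_candidates_path <- function() {
  system.file("extdata", "dppiv_screen_candidates.tsv",
              package = "pepfunnel", mustWork = TRUE)
}

#' Load a bioactivity reference table
#'
#' Reads a TSV with columns `sequence`, `activities` (semicolon-separated
#' labels) and `precursor_note`. Sequences must be unique; every activity
#' label must be recognized and every entry must carry at least one.
#'
#' @param path Path to the reference TSV; defaults to the bundled table.
#' @return Data frame of class `c("bioactivity_reference", "data.frame")`
#'   with columns `sequence`, `activities` (list column of character
#'   vectors), `precursor_note`.
#' @export
load_reference <- function(path = bundled_reference_path()) {
  if (!file.exists(path)) {
    stop(sprintf("reference file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character(0), comment.char = "",
                          encoding = "UTF-8")
  required <- c("sequence", "activities", "precursor_note")
  if (!all(required %in% names(df))) {
    stop(sprintf("reference file must have columns: %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    df$sequence <- vapply(df$sequence, validate_sequence, character(1L),
                          USE.NAMES = FALSE)
    dup <- duplicated(df$sequence)
    if (any(dup)) {
      stop(sprintf("duplicate sequence in reference: %s (line %d)",
                   df$sequence[which(dup)[1L]], which(dup)[1L] + 1L),
           call. = FALSE)
    }
    acts <- strsplit(df$activities, ";", fixed = TRUE)
    acts <- lapply(acts, trimws)
    for (i in seq_along(acts)) {
      if (length(acts[[i]]) == 0L || any(!nzchar(acts[[i]]))) {
        stop(sprintf("empty activity set at line %d", i + 1L), call. = FALSE)
      }
      unknown <- setdiff(acts[[i]], .ACTIVITY_LABELS)
      if (length(unknown) > 0L) {
        stop(sprintf("unrecognized activity label '%s' at line %d",
                     unknown[1L], i + 1L), call. = FALSE)
      }
    }
    df$activities <- acts
  } else {
    df$activities <- list()
  }
  class(df) <- c("bioactivity_reference", "data.frame")
  df
}

#' Write a bioactivity reference table
#'
#' Inverse of [load_reference()]: serializes the list-column of activities
#' back to semicolon-separated strings. Loading a written file reproduces
#' the table up to row order.
#'
#' @param ref A `bioactivity_reference` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  out <- data.frame(
    sequence = ref$sequence,
    activities = vapply(ref$activities, paste, character(1L), collapse = ";"),
    precursor_note = ref$precursor_note,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up known activities of a peptide
#'
#' Exact full-sequence identity match (case-insensitive) against the
#' reference table — no substring or partial-homology matching, the only
#' reading of "100% sequence homology" consistent with di-peptide entries.
#'
#' @param p Peptide sequence.
#' @param ref Reference table from [load_reference()].
#' @return Character vector of activity labels (empty if the sequence is
#'   absent).
#' @examples
#' ref <- load_reference()
#' lookup_activities("IP", ref)    # ACE- and DPP-IV-inhibition
#' lookup_activities("SAPI", ref)  # character(0): novel
#' @export
lookup_activities <- function(p, ref) {
  p <- validate_sequence(p)
  hit <- match(p, ref$sequence)
  if (is.na(hit)) character(0) else ref$activities[[hit]]
}

#' Is a peptide a known carrier of an activity?
#'
#' @param p Peptide sequence.
#' @param activity One of the recognized labels (`"ACE-inhibition"`,
#'   `"DPP-IV-inhibition"`, `"Antioxidant"`).
#' @param ref Reference table.
#' @return `TRUE` iff `activity` is among the peptide's known activities.
#' @export
is_known_inhibitor <- function(p, activity, ref) {
  if (!activity %in% .ACTIVITY_LABELS) {
    stop(sprintf("unknown activity label '%s' (expected one of: %s)",
                 activity, paste(.ACTIVITY_LABELS, collapse = ", ")),
         call. = FALSE)
  }
  activity %in% lookup_activities(p, ref)
}

#' Partition a reference table by inhibitory-activity category
#'
#' Counts entries that are DPP-IV-inhibitory only, ACE-inhibitory only,
#' carriers of both, or carriers of neither (e.g. antioxidant-only). The
#' four counts always sum to the table size.
#'
#' @param ref Reference table.
#' @return Named integer vector `dppiv_only`, `ace_only`, `both`, `other`.
#' @export
classify_counts <- function(ref) {
  dpp <- vapply(ref$activities, function(a) "DPP-IV-inhibition" %in% a,
                logical(1L))
  ace <- vapply(ref$activities, function(a) "ACE-inhibition" %in% a,
                logical(1L))
  c(
    dppiv_only = sum(dpp & !ace),
    ace_only   = sum(ace & !dpp),
    both       = sum(dpp & ace),
    other      = sum(!dpp & !ace)
  )
}

#' @export
print.bioactivity_reference <- function(x, ...) {
  cat(sprintf("Bioactivity reference table: %d peptides\n", nrow(x)))
  cc <- classify_counts(x)
  cat(sprintf("  DPP-IV-inhibition only: %d\n  ACE-inhibition only: %d\n  both: %d\n  other: %d\n",
              cc["dppiv_only"], cc["ace_only"], cc["both"], cc["other"]))
  invisible(x)
}
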