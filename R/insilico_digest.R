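# In silico gastrointestinal digestion: cleavage-rule simulation (gastric
# pepsin phase followed by an intestinal trypsin + chymotrypsin phase),
# peptide-to-precursor mapping and pool summaries. The simulator is a
# no-download generator of realistic peptide pools, not a kinetic model.

#' Define a protease cleavage rule
#'
#' A rule cleaves the peptide bond after any residue in `p1_residues` unless
#' the following residue is in `blocked_p1prime` (the usual proline block).
#'
#' @param enzyme_name Name of the protease.
#' @param p1_residues Residues cleaved after (P1 side).
#' @param blocked_p1prime Residues blocking cleavage when immediately
#'   C-terminal to the site (P1' side). Default none.
#' @return Object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(enzyme_name, p1_residues, blocked_p1prime = character(0)) {
  p1_residues <- toupper(p1_residues)
  blocked_p1prime <- toupper(blocked_p1prime)
  stopifnot(length(p1_residues) > 0L,
            all(p1_residues %in% canonical_residues()),
            all(blocked_p1prime %in% canonical_residues()))
  structure(
    list(enzyme_name = enzyme_name, p1_residues = p1_residues,
         blocked_p1prime = blocked_p1prime),
    class = "cleavage_rule"
  )
}

#' Built-in protease rules
#'
#' PeptideCutter-style specificities: pepsin (pH > 2) cleaves after F, L, W
#' or Y; trypsin after K or R; chymotrypsin (high specificity) after F, Y or
#' W. All three are blocked by a P in P1'. Pancreatin is approximated by
#' trypsin plus chymotrypsin.
#'
#' @param name One of `"pepsin"`, `"trypsin"`, `"chymotrypsin"`.
#' @return A [cleavage_rule()].
#' @export
enzyme_rule <- function(name = c("pepsin", "trypsin", "chymotrypsin")) {
  name <- match.arg(name)
  switch(name,
    pepsin       = cleavage_rule("pepsin", c("F", "L", "W", "Y"), "P"),
    trypsin      = cleavage_rule("trypsin", c("K", "R"), "P"),
    chymotrypsin = cleavage_rule("chymotrypsin", c("F", "Y", "W"), "P")
  )
}

#' Default two-phase digestion scheme
#'
#' Gastric phase: pepsin. Intestinal phase: trypsin and chymotrypsin applied
#' jointly (union of cleavage sites), standing in for pancreatin.
#'
#' @return Named list of phases, each a list of [cleavage_rule()]s.
#' @export
digestion_phases <- function() {
  list(
    gastric    = list(enzyme_rule("pepsin")),
    intestinal = list(enzyme_rule("trypsin"), enzyme_rule("chymotrypsin"))
  )
}

#' Cleavage sites of a rule on a protein
#'
#' @param sequence Protein or peptide sequence (canonical residues).
#' @param rule A [cleavage_rule()], or a list of rules (union of sites).
#' @return Strictly increasing integer vector of cut positions: a cut at
#'   position `i` separates residues `i` and `i+1`. The bond after the final
#'   residue is never a site.
#' @examples
#' cleavage_sites("AKFGR", enzyme_rule("trypsin"))  # 2
#' @export
cleavage_sites <- function(sequence, rule) {
  sequence <- validate_sequence(sequence)
  if (inherits(rule, "cleavage_rule")) rule <- list(rule)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  sites <- integer(0)
  for (r in rule) {
    hit <- which(chars[-n] %in% r$p1_residues &
                   !chars[-1L] %in% r$blocked_p1prime)
    sites <- union(sites, hit)
  }
  sort(sites)
}

# Fragments of one sequence given cut sites, allowing up to `missed` uncut
# internal sites. Returns start/end (1-based, inclusive, local coordinates)
# and the number of missed sites in each fragment.
.fragments_from_sites <- function(n, sites, missed) {
  bounds <- c(0L, sites, n)
  k <- length(bounds)
  out <- vector("list", k - 1L)
  idx <- 1L
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + missed)
    for (j in (i + 1L):jmax) {
      out[[idx]] <- c(start = bounds[i] + 1L, end = bounds[j],
                      missed = j - i - 1L)
      idx <- idx + 1L
    }
  }
  do.call(rbind, out[seq_len(idx - 1L)])
}

#' Simulate multi-phase enzymatic digestion
#'
#' Phase 1 rules are applied to the intact protein; each later phase is
#' applied to every fragment from the previous phase. Fragments containing
#' up to `missed_cleavages` uncut internal sites are emitted alongside the
#' fully cut ones. The result records the fragment set as of the end of each
#' phase, with 1-based inclusive precursor coordinates.
#'
#' @param proteins Named character vector of protein sequences, a data frame
#'   with columns `id` and `sequence`, or a `Biostrings::AAStringSet` (e.g.
#'   from [read_proteins()]).
#' @param phases Named list of phases as in [digestion_phases()]; a single
#'   rule or flat list of rules is treated as one phase. An empty list
#'   returns each protein intact.
#' @param missed_cleavages Non-negative integer, per phase (default 0).
#' @return Object of class `digest_result`: a data frame with columns
#'   `sequence`, `precursor`, `start`, `end`, `phase`, `missed`, plus an
#'   attribute `missed_cleavages`. Rows for non-final phases describe
#'   intermediate fragments.
#' @examples
#' digest(c(toy = "AKFGR"), list(tryptic = list(enzyme_rule("trypsin"))))
#' @export
digest <- function(proteins, phases = digestion_phases(), missed_cleavages = 0L) {
  proteins <- .as_protein_set(proteins)
  missed_cleavages <- as.integer(missed_cleavages)
  stopifnot(missed_cleavages >= 0L)
  if (inherits(phases, "cleavage_rule")) phases <- list(phase1 = list(phases))
  if (length(phases) > 0L && all(vapply(phases, inherits, logical(1L), "cleavage_rule"))) {
    phases <- list(phase1 = phases)
  }
  if (is.null(names(phases)) && length(phases) > 0L) {
    names(phases) <- paste0("phase", seq_along(phases))
  }

  rows <- list()
  for (pid in names(proteins)) {
    pseq <- proteins[[pid]]
    # current: fragments carried into the next phase (fully cut, 0 missed)
    current <- data.frame(sequence = pseq, start = 1L, end = nchar(pseq),
                          stringsAsFactors = FALSE)
    if (length(phases) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pseq, precursor = pid, start = 1L, end = nchar(pseq),
        phase = "undigested", missed = 0L, stringsAsFactors = FALSE)
      next
    }
    for (ph in names(phases)) {
      nxt <- list()
      emitted <- list()
      for (f in seq_len(nrow(current))) {
        fseq <- current$sequence[f]
        offset <- current$start[f] - 1L
        sites <- cleavage_sites(fseq, phases[[ph]])
        frs <- .fragments_from_sites(nchar(fseq), sites, missed_cleavages)
        frs_df <- data.frame(
          sequence = substring(fseq, frs[, "start"], frs[, "end"]),
          precursor = pid,
          start = frs[, "start"] + offset,
          end = frs[, "end"] + offset,
          phase = ph,
          missed = frs[, "missed"],
          stringsAsFactors = FALSE
        )
        emitted[[f]] <- frs_df
        nxt[[f]] <- frs_df[frs_df$missed == 0L, c("sequence", "start", "end")]
      }
      emitted <- do.call(rbind, emitted)
      emitted <- emitted[!duplicated(emitted[, c("sequence", "start", "end", "phase")]), ]
      rows[[length(rows) + 1L]] <- emitted
      current <- do.call(rbind, nxt)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "missed_cleavages") <- missed_cleavages
  class(res) <- c("digest_result", "data.frame")
  res
}

#' Final-phase fragments of a digest, as a screening pool
#'
#' Keeps the last phase's fragments and drops those shorter than two
#' residues (free amino acids are not screenable pool members).
#'
#' @param result A `digest_result` from [digest()].
#' @param min_length Minimum fragment length retained (default 2).
#' @return A `peptide_pool` data frame (unique sequence/precursor pairs).
#' @export
digest_pool <- function(result, min_length = 2L) {
  last_phase <- result$phase[nrow(result)]
  frags <- result[result$phase == last_phase & nchar(result$sequence) >= min_length, ]
  frags <- frags[!duplicated(frags[, c("sequence", "precursor")]), ]
  as_peptide_pool(data.frame(sequence = frags$sequence,
                             precursor = frags$precursor,
                             stringsAsFactors = FALSE))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (multi-record).
#' @return Named character vector of uppercase sequences.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

.as_protein_set <- function(proteins) {
  if (inherits(proteins, "AAStringSet")) {
    seqs <- toupper(as.character(proteins))
    names(seqs) <- sub("\\s.*$", "", names(proteins))
    proteins <- seqs
  }
  if (is.data.frame(proteins)) {
    stopifnot(all(c("id", "sequence") %in% names(proteins)))
    seqs <- proteins$sequence
    names(seqs) <- proteins$id
    proteins <- seqs
  }
  stopifnot(is.character(proteins), length(proteins) > 0L)
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    names(proteins) <- paste0("protein", seq_along(proteins))
  }
  vapply(proteins, validate_sequence, character(1L))
}

#' Map a peptide onto precursor proteins
#'
#' Finds every exact substring occurrence (overlapping occurrences included)
#' of a peptide in a set of proteins, with 1-based inclusive coordinates.
#'
#' @param p Peptide sequence.
#' @param proteins As in [digest()].
#' @return Data frame with columns `precursor`, `start`, `end` (zero rows if
#'   the peptide occurs nowhere).
#' @examples
#' map_peptide_to_proteins("AA", c(x = "AAA"))  # (1,2) and (2,3)
#' @export
map_peptide_to_proteins <- function(p, proteins) {
  p <- validate_sequence(p)
  proteins <- .as_protein_set(proteins)
  out <- list()
  for (pid in names(proteins)) {
    hits <- gregexpr(paste0("(?=", p, ")"), proteins[[pid]], perl = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    out[[pid]] <- data.frame(precursor = pid, start = as.integer(hits),
                             end = as.integer(hits) + nchar(p) - 1L,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(precursor = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a peptide pool or fragment set
#'
#' @param pool A `peptide_pool`, `digest_result`, or character vector of
#'   sequences.
#' @return List with `count`, `length_histogram` (named integer vector,
#'   names = lengths), `per_precursor` (named counts, if precursors known),
#'   and `flagged` (sequences with length outside \[2, 50\]).
#' @export
pool_statistics <- function(pool) {
  if (is.character(pool)) {
    seqs <- pool
    prec <- NULL
  } else {
    seqs <- pool$sequence
    prec <- pool$precursor
  }
  lens <- nchar(seqs)
  hist <- table(lens)
  out <- list(
    count = length(seqs),
    length_histogram = stats::setNames(as.integer(hist), names(hist)),
    flagged = seqs[lens < 2L | lens > 50L]
  )
  if (!is.null(prec) && any(!is.na(prec))) {
    out$per_precursor <- table(prec, useNA = "no")
  }
  out
}
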