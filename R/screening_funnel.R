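# The staged candidate-selection funnel: bioactivity-rank filter ->
# active-site-binding filter -> novelty partition against the known-bioactive
# reference -> SAR selection, with a machine-readable report. Rank scores and
# binding p-values are consumed from the input pool, never computed: the
# external predictors that produce them are not reimplemented here.

#' Funnel configuration
#'
#' @param rank_threshold Bioactivity-rank cut: records with score strictly
#'   above it survive. Default 0.4. Set to `NA` for a pre-ranked pool (the
#'   rank stage then passes everything through).
#' @param pvalue_threshold Binding p-value cut: records strictly below it
#'   survive. Default 0.01.
#' @param target_activity Activity label used for the novelty partition.
#'   Default `"DPP-IV-inhibition"`.
#' @param min_features Minimum matched SAR features for selection, forwarded
#'   to [sar_catalog()]. Default 2.
#' @return Object of class `funnel_config`.
#' @export
funnel_config <- function(rank_threshold = 0.4, pvalue_threshold = 0.01,
                          target_activity = "DPP-IV-inhibition",
                          min_features = 2L) {
  if (!is.na(rank_threshold) && (rank_threshold < 0 || rank_threshold > 1)) {
    stop("rank_threshold must be in [0,1] (or NA to skip the stage)",
         call. = FALSE)
  }
  if (pvalue_threshold <= 0 || pvalue_threshold >= 1) {
    stop("pvalue_threshold must be in (0,1)", call. = FALSE)
  }
  structure(list(rank_threshold = rank_threshold,
                 pvalue_threshold = pvalue_threshold,
                 target_activity = target_activity,
                 min_features = as.integer(min_features)),
            class = "funnel_config")
}

#' Bioactivity-rank filter
#'
#' Retains records whose `rank_score` is strictly greater than the
#' threshold. Records without a score are excluded: an unscored peptide is
#' not a pass.
#'
#' @param pool A `peptide_pool` data frame.
#' @param threshold Rank cut in \[0,1\] (default 0.4).
#' @return The retained rows, in input order. Attribute `removed` lists
#'   excluded sequences with reasons.
#' @export
rank_filter <- function(pool, threshold = 0.4) {
  if (is.na(threshold)) return(pool)
  if (threshold < 0 || threshold > 1) {
    stop("rank threshold must be in [0,1]", call. = FALSE)
  }
  keep <- !is.na(pool$rank_score) & pool$rank_score > threshold
  reason <- ifelse(is.na(pool$rank_score), "rank_score missing",
                   sprintf("rank_score %.3g <= %.3g", pool$rank_score, threshold))
  out <- pool[keep, , drop = FALSE]
  attr(out, "removed") <- data.frame(sequence = pool$sequence[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Active-site-binding filter
#'
#' Retains records whose `binding_pvalue` is strictly less than the
#' threshold (more confident predicted binding). Records without a p-value
#' are excluded. When a record carries several p-values the caller should
#' have reduced them to the minimum beforehand.
#'
#' @param pool A `peptide_pool` data frame.
#' @param threshold P-value cut in (0,1) (default 0.01).
#' @return The retained rows, in input order, with a `removed` attribute.
#' @export
binding_filter <- function(pool, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) {
    stop("p-value threshold must be in (0,1)", call. = FALSE)
  }
  bad <- !is.na(pool$binding_pvalue) &
    (pool$binding_pvalue <= 0 | pool$binding_pvalue > 1)
  if (any(bad)) {
    stop(sprintf("binding_pvalue outside (0,1] for '%s'",
                 pool$sequence[which(bad)[1L]]), call. = FALSE)
  }
  keep <- !is.na(pool$binding_pvalue) & pool$binding_pvalue < threshold
  reason <- ifelse(is.na(pool$binding_pvalue), "binding_pvalue missing",
                   sprintf("binding_pvalue %.3g >= %.3g",
                           pool$binding_pvalue, threshold))
  out <- pool[keep, , drop = FALSE]
  attr(out, "removed") <- data.frame(sequence = pool$sequence[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Partition records into known and novel carriers of an activity
#'
#' A record is "known" when the target activity is among its reference-table
#' activities (exact full-sequence match); otherwise it is novel. The
#' partition is exhaustive and disjoint.
#'
#' @param pool A `peptide_pool` data frame.
#' @param ref A `bioactivity_reference` from [load_reference()].
#' @param activity Target activity label (default `"DPP-IV-inhibition"`).
#' @return List with elements `known` and `novel`, both `peptide_pool`
#'   subsets in input order.
#' @export
novelty_partition <- function(pool, ref, activity = "DPP-IV-inhibition") {
  known <- vapply(pool$sequence, is_known_inhibitor, logical(1L),
                  activity = activity, ref = ref, USE.NAMES = FALSE)
  list(known = pool[known, , drop = FALSE],
       novel = pool[!known, , drop = FALSE])
}

#' Run the full screening funnel
#'
#' Applies, in order: the bioactivity-rank filter, the binding filter, the
#' novelty partition against the reference table, and SAR selection on the
#' novel records only (known carriers need no rediscovery). Every exclusion
#' is recorded with its stage and reason in the per-peptide trail.
#'
#' @param pool A `peptide_pool` data frame (see [read_peptide_pool()]).
#' @param config A [funnel_config()].
#' @param ref A `bioactivity_reference`; defaults to the bundled table.
#' @param catalog A [sar_catalog()]; defaults to one built from
#'   `config$min_features`.
#' @return Object of class `funnel_report`: list with `stage_counts`
#'   (input, after_rank, after_binding, known, novel, sar_selected),
#'   `selected` (character vector of selected sequences), `sar` (the
#'   [batch_sar()] table for novel records), `trail` (per-peptide fate) and
#'   `config`.
#' @examples
#' pool <- read_peptide_pool(bundled_candidates_path())
#' run_funnel(pool, funnel_config(rank_threshold = NA))
#' @export
run_funnel <- function(pool, config = funnel_config(),
                       ref = load_reference(),
                       catalog = sar_catalog(config$min_features)) {
  stopifnot(inherits(config, "funnel_config"))
  trail <- data.frame(sequence = pool$sequence,
                      fate = rep("sar_rejected", nrow(pool)),
                      detail = rep("", nrow(pool)),
                      stringsAsFactors = FALSE)
  set_fate <- function(seqs, fate, detail = "") {
    i <- trail$sequence %in% seqs
    trail$fate[i] <<- fate
    trail$detail[i] <<- detail
  }

  after_rank <- rank_filter(pool, config$rank_threshold)
  rem <- attr(after_rank, "removed")
  if (!is.null(rem) && nrow(rem) > 0L) {
    for (i in seq_len(nrow(rem))) set_fate(rem$sequence[i], "removed_rank", rem$reason[i])
  }

  after_binding <- binding_filter(after_rank, config$pvalue_threshold)
  rem <- attr(after_binding, "removed")
  if (!is.null(rem) && nrow(rem) > 0L) {
    for (i in seq_len(nrow(rem))) set_fate(rem$sequence[i], "removed_binding", rem$reason[i])
  }

  parts <- novelty_partition(after_binding, ref, config$target_activity)
  set_fate(parts$known$sequence, "known",
           sprintf("already reported: %s", config$target_activity))

  sar <- batch_sar(parts$novel, catalog)
  if (nrow(sar) > 0L) {
    for (i in seq_len(nrow(sar))) {
      set_fate(sar$sequence[i],
               if (sar$selected[i]) "sar_selected" else "sar_rejected",
               sar$rationale[i])
    }
  }

  structure(list(
    stage_counts = c(input = nrow(pool),
                     after_rank = nrow(after_rank),
                     after_binding = nrow(after_binding),
                     known = nrow(parts$known),
                     novel = nrow(parts$novel),
                     sar_selected = sum(sar$selected)),
    selected = sar$sequence[sar$selected],
    sar = sar,
    trail = trail,
    config = config
  ), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("Peptide screening funnel\n")
  cat(sprintf("  input pool:          %d\n", sc["input"]))
  cat(sprintf("  after rank filter:   %d%s\n", sc["after_rank"],
              if (is.na(x$config$rank_threshold)) " (pre-ranked pool, stage skipped)"
              else sprintf(" (score > %.2f)", x$config$rank_threshold)))
  cat(sprintf("  after binding filter:%d (p < %.3g)\n", sc["after_binding"],
              x$config$pvalue_threshold))
  cat(sprintf("  known %s: %d\n", x$config$target_activity, sc["known"]))
  cat(sprintf("  novel candidates:    %d\n", sc["novel"]))
  cat(sprintf("  SAR-selected:        %d%s\n", sc["sar_selected"],
              if (length(x$selected) > 0L)
                paste0(" (", paste(x$selected, collapse = ", "), ")") else ""))
  invisible(x)
}

#' @export
summary.funnel_report <- function(object, ...) {
  print(object)
  if (nrow(object$trail) > 0L) {
    cat("\nPer-peptide trail:\n")
    print(object$trail, row.names = FALSE)
  }
  invisible(object)
}

#' Serialize a funnel report to JSON
#'
#' @param report A `funnel_report`.
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
funnel_report_json <- function(report, path = NULL) {
  obj <- list(
    stage_counts = as.list(report$stage_counts),
    selected = report$selected,
    trail = report$trail,
    config = list(
      rank_threshold = report$config$rank_threshold,
      pvalue_threshold = report$config$pvalue_threshold,
      target_activity = report$config$target_activity,
      min_features = report$config$min_features
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
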