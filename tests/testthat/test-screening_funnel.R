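make_pool <- function(seqs, rank = NA_real_, pval = NA_real_) {
  as_peptide_pool(data.frame(sequence = seqs,
                             rank_score = rep_len(rank, length(seqs)),
                             binding_pvalue = rep_len(pval, length(seqs)),
                             stringsAsFactors = FALSE))
}

test_that("rank filter is strictly greater-than and drops unscored records", {
  pool <- make_pool(c("AL", "IP", "GL", "VF"),
                    rank = c(0.41, 0.40, NA, 0.9))
  kept <- rank_filter(pool, 0.4)
  expect_identical(kept$sequence, c("AL", "VF"))
  removed <- attr(kept, "removed")
  expect_setequal(removed$sequence, c("IP", "GL"))
  expect_match(removed$reason[removed$sequence == "GL"], "missing")
  expect_error(rank_filter(pool, 1.5), "\\[0,1\\]")
  # NA threshold: pre-ranked pool, stage passes through
  expect_identical(rank_filter(pool, NA)$sequence, pool$sequence)
})

test_that("binding filter is strictly less-than with (0,1] domain checks", {
  pool <- make_pool(c("SIPR", "AL", "IP"), pval = c(1.77e-3, 0.01, NA))
  kept <- binding_filter(pool, 0.01)
  expect_identical(kept$sequence, "SIPR")
  expect_setequal(attr(kept, "removed")$sequence, c("AL", "IP"))
  expect_error(binding_filter(pool, 1), "\\(0,1\\)")
})

test_that("novelty partition against the bundled reference matches the candidate table", {
  ref <- load_reference()
  pool <- read_peptide_pool(bundled_candidates_path())
  parts <- novelty_partition(pool, ref)
  expect_setequal(parts$known$sequence,
                  c("IP", "LP", "LPQ", "GI", "MI", "ML", "GL", "VF", "AL"))
  expect_setequal(parts$novel$sequence,
                  c("PR", "FT", "SIPR", "SAPI", "FVPH", "FV"))
  # the bundled known-inhibitor flags agree with the reference lookup
  expect_identical(pool$sequence[pool$known_dppiv_inhibitor],
                   parts$known$sequence)
  # FVPH is known only as an antioxidant, so it is novel for DPP-IV
  expect_true("FVPH" %in% parts$novel$sequence)
})

test_that("the full funnel reproduces the 15 -> 9+6 -> 3 narrative on the candidate fixture", {
  pool <- read_peptide_pool(bundled_candidates_path())
  report <- run_funnel(pool, funnel_config(rank_threshold = NA))
  expect_equal(unname(report$stage_counts),
               c(15L, 15L, 15L, 9L, 6L, 3L))
  expect_identical(report$selected, c("SIPR", "SAPI", "FVPH"))
  fate <- setNames(report$trail$fate, report$trail$sequence)
  expect_identical(unname(fate["ML"]), "known")
  expect_identical(unname(fate["FV"]), "sar_rejected")
  expect_identical(unname(fate["SAPI"]), "sar_selected")
})

test_that("funnel stage identities hold on random pools", {
  set.seed(41)
  ref <- load_reference()
  for (i in 1:20) {
    n <- sample(5:30, 1)
    pool <- make_pool(
      vapply(seq_len(n), function(j) random_peptide(sample(2:6, 1)), character(1)),
      rank = ifelse(runif(n) < 0.1, NA, runif(n)),
      pval = ifelse(runif(n) < 0.1, NA, 10^runif(n, -4, 0)))
    rep <- run_funnel(pool, funnel_config(), ref)
    sc <- rep$stage_counts
    expect_true(sc["after_rank"] <= sc["input"])
    expect_true(sc["after_binding"] <= sc["after_rank"])
    expect_equal(unname(sc["known"] + sc["novel"]), unname(sc["after_binding"]))
    expect_true(sc["sar_selected"] <= sc["novel"])
    # the trail covers every input record exactly once, in input order
    expect_identical(rep$trail$sequence, pool$sequence)
  }
})

test_that("degenerate pools give zero reports, not errors", {
  empty <- make_pool(character(0))
  rep <- run_funnel(empty)
  expect_true(all(rep$stage_counts == 0))
  expect_length(rep$selected, 0)

  # nothing passes the binding filter
  pool <- make_pool(c("AL", "IP"), rank = c(0.9, 0.9), pval = c(0.5, 0.9))
  rep2 <- run_funnel(pool)
  expect_equal(unname(rep2$stage_counts[c("after_binding", "known", "novel", "sar_selected")]),
               c(0L, 0L, 0L, 0L))
})

test_that("funnel reports serialize to JSON with counts and trail", {
  pool <- read_peptide_pool(bundled_candidates_path())
  report <- run_funnel(pool, funnel_config(rank_threshold = NA))
  js <- jsonlite::fromJSON(funnel_report_json(report))
  expect_equal(js$stage_counts$sar_selected, 3L)
  expect_identical(js$selected, c("SIPR", "SAPI", "FVPH"))
  expect_equal(nrow(js$trail), 15L)
})
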