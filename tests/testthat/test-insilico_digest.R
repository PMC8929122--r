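test_that("cleavage sites follow P1 specificity with P1' blocking", {
  trypsin <- enzyme_rule("trypsin")
  # K followed by A cut; R followed by P blocked; no cut after terminal residue
  expect_identical(cleavage_sites("MKARP", trypsin), 2L)
  # both K and R are followed by non-P residues here
  expect_identical(cleavage_sites("MKRAP", trypsin), c(2L, 3L))
  expect_identical(cleavage_sites("GGGG", trypsin), integer(0))
  # terminal K is never a site
  expect_identical(cleavage_sites("KKK", trypsin), c(1L, 2L))
  # union over a rule list
  expect_identical(
    cleavage_sites("AKFGR", list(trypsin, enzyme_rule("chymotrypsin"))),
    c(2L, 3L))
})

test_that("digestion yields hand-checked fragments, with and without missed cleavages", {
  res0 <- digest(c(p = "AKFGR"), list(tryptic = list(enzyme_rule("trypsin"))),
                 missed_cleavages = 0)
  expect_setequal(res0$sequence, c("AK", "FGR"))
  expect_equal(res0$start[res0$sequence == "FGR"], 3L)
  expect_equal(res0$end[res0$sequence == "FGR"], 5L)

  res1 <- digest(c(p = "AKFGR"), list(tryptic = list(enzyme_rule("trypsin"))),
                 missed_cleavages = 1)
  expect_setequal(res1$sequence, c("AK", "FGR", "AKFGR"))
  expect_equal(res1$missed[res1$sequence == "AKFGR"], 1L)

  # empty rule set: identity
  resid <- digest(c(p = "AKFGR"), list())
  expect_identical(resid$sequence, "AKFGR")
})

test_that("two-phase digestion applies intestinal rules to gastric fragments", {
  # pepsin cuts after L (not before P); trypsin then cuts after K
  res <- digest(c(p = "GLAKGG"), digestion_phases())
  gast <- res[res$phase == "gastric", ]
  expect_setequal(gast$sequence, c("GL", "AKGG"))
  intes <- res[res$phase == "intestinal", ]
  expect_setequal(intes$sequence, c("GL", "AK", "GG"))
  # no final-phase fragment retains an unblocked intestinal site internally
  for (i in seq_len(nrow(intes))) {
    sites <- cleavage_sites(intes$sequence[i], digestion_phases()$intestinal)
    expect_length(sites, 0)
  }
})

test_that("fragment coordinates are sound and fully-cut fragments tile the protein", {
  set.seed(21)
  phases <- list(tryptic = list(enzyme_rule("trypsin")))
  for (i in 1:15) {
    prot <- random_protein(sample(20:60, 1))
    res <- digest(c(x = prot), phases, missed_cleavages = sample(0:2, 1))
    # coordinate soundness for every fragment
    expect_identical(substring(prot, res$start, res$end), res$sequence)
    # conservation: 0-missed fragments concatenate back to the protein
    full <- res[res$missed == 0L, ]
    full <- full[order(full$start), ]
    expect_identical(paste(full$sequence, collapse = ""), prot)
  }
})

test_that("fragment sets are monotone in allowed missed cleavages", {
  set.seed(22)
  phases <- digestion_phases()
  for (i in 1:8) {
    prot <- random_protein(40)
    frag_k <- lapply(0:2, function(k)
      with(digest(c(x = prot), phases, k), paste(sequence, start, end, phase)))
    expect_true(all(frag_k[[1]] %in% frag_k[[2]]))
    expect_true(all(frag_k[[2]] %in% frag_k[[3]]))
  }
})

test_that("peptides map to all (overlapping) precursor occurrences", {
  hits <- map_peptide_to_proteins("SAPI", toy_proteins)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 6L)

  aa <- map_peptide_to_proteins("AA", c(x = "AAA"))
  expect_equal(aa$start, c(1L, 2L))
  expect_equal(aa$end, c(2L, 3L))

  expect_equal(nrow(map_peptide_to_proteins("FVPH", toy_proteins)), 0L)
})

test_that("FASTA input feeds the digester", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toyA some description", "MKSAPIR", ">toyB", "AKFGR"), fa)
  prots <- read_proteins(fa)
  expect_identical(prots, c(toyA = "MKSAPIR", toyB = "AKFGR"))
  res <- digest(prots, list(tryptic = list(enzyme_rule("trypsin"))))
  expect_setequal(res$sequence[res$precursor == "toyB"], c("AK", "FGR"))
})

test_that("pool statistics count lengths and flag out-of-range members", {
  st <- pool_statistics(c("AL", "LPQ", "SAPI"))
  expect_equal(st$count, 3L)
  expect_equal(st$length_histogram, c(`2` = 1L, `3` = 1L, `4` = 1L))
  expect_length(st$flagged, 0)

  expect_equal(pool_statistics(character(0))$count, 0L)

  # union of the two bundled fixtures: 41 unique peptides
  seqs <- union(load_reference()$sequence,
                read_peptide_pool(bundled_candidates_path())$sequence)
  expect_equal(pool_statistics(seqs)$count, 41L)
})
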