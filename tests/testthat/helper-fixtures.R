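# Shared helpers: random sequence generation and small synthetic proteins.

random_peptide <- function(len) {
  paste(sample(canonical_residues(), len, replace = TRUE), collapse = "")
}

random_protein <- function(len) random_peptide(len)

# A synthetic protein whose tryptic digest is easy to verify by hand.
toy_proteins <- c(
  toyA = "MKSAPIR",
  toyB = "AKFGR"
)
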