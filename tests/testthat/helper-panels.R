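# Shared fixture builders: tiny records and weight vectors built in code.

rec_of <- function(codons, id = "g") {
  gene_record(id, paste(codons, collapse = ""))
}

# a 64-wide named weight vector, zero except for the given entries
weights_of <- function(...) {
  vals <- c(...)
  w <- stats::setNames(rep(0, 64), names(Biostrings::GENETIC_CODE))
  w[names(vals)] <- vals
  w
}

# one-codon-per-family weights (maximal bias)
one_codon_weights <- function() {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc)[gc != "*"], gc[gc != "*"])
  w <- stats::setNames(rep(0, 64), names(gc))
  for (f in fams) w[f[1]] <- 1
  w
}

fam_of <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == gc[[codon]]]
}

syn_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  setdiff(names(gc)[gc != "*"], c("ATG", "TGG"))
}
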