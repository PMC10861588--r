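# Constant tables: genetic code, synonymous families, amino-acid scales.

# Standard nuclear genetic code (DNA alphabet), from Biostrings.
.GC <- Biostrings::GENETIC_CODE

.CODONS <- names(.GC)
.STOP_CODONS <- .CODONS[.GC == "*"]
.SENSE_CODONS <- .CODONS[.GC != "*"]
# 59 codons with a synonymous choice: sense minus Met (ATG) and Trp (TGG)
.SYN_CODONS <- setdiff(.SENSE_CODONS, c("ATG", "TGG"))

# synonymous families: list aa -> codons (20 amino acids)
.FAMILIES <- split(.SENSE_CODONS, .GC[.SENSE_CODONS])
.FAMILY_SIZE <- vapply(.FAMILIES, length, integer(1))

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

# pKa set used by ProtParam (Bjellqvist): side chains plus termini
.PKA_POS <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.PKA_NEG <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

.HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")
.ACIDIC_AA <- c("D", "E")
.BASIC_AA <- c("K", "R", "H")
.AROMATIC_AA <- c("F", "W", "Y")

# cached package data read from extdata
.cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "codonpanel", mustWork = TRUE)
  path
}

# Guruprasad et al. (1990) dipeptide instability weights, 20 x 20
.diwv <- function() {
  if (is.null(.cache$diwv)) {
    d <- utils::read.delim(.extdata("diwv_instability.tsv"),
                           row.names = 1, check.names = FALSE)
    .cache$diwv <- as.matrix(d)
  }
  .cache$diwv
}

#' Translate a DNA codon string to one-letter amino-acid code
#'
#' Vectorised lookup in the standard nuclear genetic code; stop codons
#' translate to `"*"`.
#'
#' @param codons character vector of 3-letter DNA codons.
#' @return character vector of one-letter amino acids.
#' @export
codon_aa <- function(codons) {
  aa <- unname(.GC[codons])
  if (anyNA(aa)) stop("unknown codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' Codons written in the RNA alphabet
#'
#' Reports use the RNA alphabet (GUG-GUG rather than GTG-GTG) to match the
#' conventional naming of codon pairs; internally all codons are DNA.
#'
#' @param codons character vector of DNA codons.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(codons) chartr("T", "U", codons)
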