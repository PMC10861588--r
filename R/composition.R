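# Nucleotide composition by codon position, GC metrics, skews, and
# dinucleotide odds ratios.

.base_counts <- function(chars) {
  stats::setNames(vapply(c("A", "C", "G", "T"),
                         function(b) sum(chars == b), numeric(1)),
                  c("A", "C", "G", "T"))
}

#' Nucleotide composition of a coding sequence
#'
#' Overall base composition is computed on the full normalised sequence;
#' positional composition (codon positions 1/2/3, hence GC1/GC2/GC3 and the
#' third-position counts used by parity analysis) is computed on the sense
#' codons, excluding the terminal stop codon.
#'
#' @param record a [gene_record()].
#' @return object of class `composition_profile`: overall counts and
#'   percents, a 4 x 3 positional percent matrix, third-position counts
#'   (A3/T3/G3/C3), GC1/GC2/GC3/GC12 percents and `length_nt`.
#' @export
nucleotide_composition <- function(record) {
  stopifnot(inherits(record, "gene_record"))
  codons <- record$codons
  if (length(codons) == 0L) stop("empty record")
  all_chars <- strsplit(record$sequence, "")[[1]]
  all_chars <- all_chars[all_chars %in% c("A", "C", "G", "T")]
  counts <- .base_counts(all_chars)

  # positional counts on codons minus a terminal stop
  n <- length(codons)
  if (codons[n] %in% .STOP_CODONS) codons <- codons[-n]
  if (length(codons) == 0L) stop("no sense codons in record")
  pos <- vapply(1:3, function(p) .base_counts(substr(codons, p, p)),
                numeric(4))
  dimnames(pos) <- list(c("A", "C", "G", "T"), paste0("pos", 1:3))
  pos_pct <- sweep(pos, 2, colSums(pos), "/") * 100
  gc_pos <- colSums(pos_pct[c("C", "G"), ])
  structure(list(
    gene_id = record$gene_id,
    base_counts = counts,
    base_percent = 100 * counts / sum(counts),
    pos_counts = pos,
    pos_percent = pos_pct,
    A3 = pos["A", 3], T3 = pos["T", 3], G3 = pos["G", 3], C3 = pos["C", 3],
    GC1 = unname(gc_pos[1]), GC2 = unname(gc_pos[2]), GC3 = unname(gc_pos[3]),
    GC12 = unname((gc_pos[1] + gc_pos[2]) / 2),
    length_nt = record$length_nt
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", x$gene_id, ": ", x$length_nt, " nt; GC1 ",
      round(x$GC1, 2), " GC2 ", round(x$GC2, 2), " GC3 ", round(x$GC3, 2),
      "\n", sep = "")
  invisible(x)
}

#' Six nucleotide skews
#'
#' Normalised base-count differences on the overall composition:
#' AT = (A-T)/(A+T), GC = (G-C)/(G+C), purine = (A-G)/(A+G),
#' pyrimidine = (C-T)/(C+T), keto = (G-T)/(G+T), amino = (A-C)/(A+C).
#' A zero denominator yields NA (undefined), never 0.
#'
#' @param profile a `composition_profile`, or a `gene_record` (profiled
#'   first).
#' @return named numeric vector of the six skews, each in \[-1, 1\] or NA.
#' @export
skews <- function(profile) {
  if (inherits(profile, "gene_record")) profile <- nucleotide_composition(profile)
  stopifnot(inherits(profile, "composition_profile"))
  ct <- profile$base_counts
  sk <- function(x, y) {
    d <- ct[[x]] + ct[[y]]
    if (d == 0) NA_real_ else (ct[[x]] - ct[[y]]) / d
  }
  c(at_skew = sk("A", "T"), gc_skew = sk("G", "C"),
    purine_skew = sk("A", "G"), pyrimidine_skew = sk("C", "T"),
    keto_skew = sk("G", "T"), amino_skew = sk("A", "C"))
}

#' Dinucleotide odds ratios
#'
#' For each of the 16 dinucleotides, the ratio of its observed frequency
#' (over all overlapping dinucleotides of the full CDS, codon junctions
#' included) to the product of the mononucleotide frequencies of the same
#' sequence. Ratios below `lower` are classified under-represented, above
#' `upper` over-represented, otherwise random.
#'
#' @param record a [gene_record()].
#' @param lower,upper classification thresholds (defaults 0.73 and 1.23).
#' @return data.frame with columns `dinucleotide`, `ratio`, `classification`.
#' @export
dinucleotide_odds <- function(record, lower = 0.73, upper = 1.23) {
  stopifnot(inherits(record, "gene_record"))
  seq <- paste(record$codons, collapse = "")
  n <- nchar(seq)
  if (n < 2) stop("sequence too short for dinucleotide analysis")
  chars <- strsplit(seq, "")[[1]]
  mono <- .base_counts(chars) / n
  dints <- paste0(chars[-n], chars[-1])
  bases <- c("A", "C", "G", "T")
  all16 <- as.vector(outer(bases, bases, paste0))
  f <- vapply(all16, function(d) sum(dints == d), numeric(1)) / (n - 1)
  expf <- mono[substr(all16, 1, 1)] * mono[substr(all16, 2, 2)]
  ratio <- ifelse(expf > 0, f / expf, NA_real_)
  cls <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio < lower, "under",
                       ifelse(ratio > upper, "over", "random")))
  data.frame(dinucleotide = all16, ratio = unname(ratio),
             classification = cls, stringsAsFactors = FALSE)
}
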