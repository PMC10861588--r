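# Codon counting and the codon-usage-bias indices: RSCU, ENc, scaled
# chi-square, CAI and the translational-selection index P2.

#' Codon counts of a gene
#'
#' Exact counts over all 64 codons. A terminal stop codon is counted in the
#' 64-wide table (codon-pair analysis needs it) but excluded from
#' `total_sense_codons`.
#'
#' @param record a [gene_record()].
#' @return object of class `codon_count_table`: `gene_id`, integer `counts`
#'   named by the 64 codons, and `total_sense_codons`.
#' @export
codon_counts <- function(record) {
  stopifnot(inherits(record, "gene_record"))
  tab <- table(factor(record$codons, levels = .CODONS))
  counts <- stats::setNames(as.integer(tab), .CODONS)
  structure(list(gene_id = record$gene_id, counts = counts,
                 total_sense_codons = sum(counts[.SENSE_CODONS])),
            class = "codon_count_table")
}

#' Pool codon-count tables elementwise
#'
#' @param tables list of `codon_count_table`s.
#' @param gene_id label for the pooled table.
#' @return a `codon_count_table` of summed counts.
#' @export
pool_codon_counts <- function(tables, gene_id = "pooled") {
  stopifnot(length(tables) > 0,
            all(vapply(tables, inherits, logical(1), "codon_count_table")))
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  structure(list(gene_id = gene_id, counts = counts,
                 total_sense_codons = sum(counts[.SENSE_CODONS])),
            class = "codon_count_table")
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat("<codon_count_table> ", x$gene_id, ": ", x$total_sense_codons,
      " sense codons\n", sep = "")
  invisible(x)
}

# RSCU over the 59 synonymous codons from a 64-wide count vector.
# Families with zero total are NA (missing, not 0).
.rscu_of_counts <- function(counts) {
  out <- stats::setNames(rep(NA_real_, length(.SYN_CODONS)), .SYN_CODONS)
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    ni <- length(fam)
    if (ni < 2) next
    tot <- sum(counts[fam])
    if (tot > 0) out[fam] <- counts[fam] / (tot / ni)
  }
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of codon j in family i is the observed count divided by the count
#' expected under equal usage within the family, X_ij / ((1/n_i) sum_j X_ij).
#' Met, Trp and stop codons are excluded (59 codons). Families with zero
#' observed codons give NA.
#'
#' @param counts a `codon_count_table` (or a `gene_record`, counted first).
#' @param under,over classification thresholds (defaults 0.6 and 1.6).
#' @return object of class `rscu_table`: named `rscu` vector over the 59
#'   synonymous codons and a parallel `classification` vector
#'   (under/normal/over).
#' @export
rscu <- function(counts, under = 0.6, over = 1.6) {
  if (inherits(counts, "gene_record")) counts <- codon_counts(counts)
  stopifnot(inherits(counts, "codon_count_table"))
  values <- .rscu_of_counts(counts$counts)
  cls <- ifelse(is.na(values), NA_character_,
                ifelse(values < under, "under",
                       ifelse(values > over, "over", "normal")))
  structure(list(gene_id = counts$gene_id, rscu = values,
                 classification = cls),
            class = "rscu_table")
}

#' @export
print.rscu_table <- function(x, ...) {
  cat("<rscu_table> ", x$gene_id, ": ",
      sum(x$classification == "over", na.rm = TRUE), " over, ",
      sum(x$classification == "under", na.rm = TRUE),
      " under-represented codons\n", sep = "")
  invisible(x)
}

# degeneracy class per amino acid (Leu/Ser/Arg as 6-fold; Ile the only
# 3-fold; Met/Trp excluded)
.DEGENERACY <- .FAMILY_SIZE[.FAMILY_SIZE >= 2]

#' Effective number of codons (Wright's estimator)
#'
#' Per synonymous family with total n >= 2, the codon homozygosity is
#' F = (n * sum p_k^2 - 1) / (n - 1). F2/F3/F4/F6 average F over the
#' families of each degeneracy class, and
#' ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to \[20, 61\].
#' If a degeneracy class has no computable family (or mean F of 0), the mean
#' of the observed class means is substituted and the result flagged via
#' `families_missing`.
#'
#' @param counts a `codon_count_table` (or `gene_record`).
#' @return object of class `enc_result`: `F2`, `F3`, `F4`, `F6`, `enc`,
#'   `families_missing`.
#' @export
enc <- function(counts) {
  if (inherits(counts, "gene_record")) counts <- codon_counts(counts)
  stopifnot(inherits(counts, "codon_count_table"))
  if (counts$total_sense_codons == 0) stop("empty gene")
  fam_F <- fam_deg <- numeric(0)
  for (aa in names(.DEGENERACY)) {
    fam <- .FAMILIES[[aa]]
    n <- sum(counts$counts[fam])
    if (n < 2) next
    p <- counts$counts[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    fam_F <- c(fam_F, f)
    fam_deg <- c(fam_deg, length(fam))
  }
  class_sizes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  Fbar <- vapply(c(2, 3, 4, 6), function(d) {
    fs <- fam_F[fam_deg == d]
    if (length(fs) == 0) NA_real_ else mean(fs)
  }, numeric(1))
  names(Fbar) <- c("F2", "F3", "F4", "F6")
  usable <- !is.na(Fbar) & Fbar > 0
  missing_n <- sum(!usable)
  if (all(!usable)) stop("no computable synonymous family")
  Fsub <- Fbar
  Fsub[!usable] <- mean(Fbar[usable])
  enc_val <- 2 + 9 / Fsub["F2"] + 1 / Fsub["F3"] + 5 / Fsub["F4"] +
    3 / Fsub["F6"]
  structure(list(F2 = unname(Fbar["F2"]), F3 = unname(Fbar["F3"]),
                 F4 = unname(Fbar["F4"]), F6 = unname(Fbar["F6"]),
                 enc = unname(min(max(enc_val, 20), 61)),
                 families_missing = missing_n),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat("<enc_result> ENc = ", round(x$enc, 2),
      if (x$families_missing > 0)
        paste0(" (", x$families_missing, " degeneracy class(es) substituted)"),
      "\n", sep = "")
  invisible(x)
}

#' Expected ENc under mutation pressure alone
#'
#' The null ENc-GC3 curve: ENc = 2 + s + 29 / (s^2 + (1-s)^2) with s the
#' GC3 fraction. Genes far below the curve indicate selection on codon use.
#'
#' @param gc3 GC3 fraction(s) in (0, 1).
#' @return expected ENc, vectorised over `gc3`.
#' @export
expected_enc <- function(gc3) {
  stopifnot(all(gc3 > 0 & gc3 < 1))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Scaled chi-square (SCS)
#'
#' For each synonymous family (n_i >= 2), the chi-square statistic of the
#' observed codon counts against equal usage (expected = family total /
#' n_i); SCS is the sum over families divided by the total number of codons
#' in those families. 0 means equal usage; larger values mean stronger bias.
#'
#' @param counts a `codon_count_table` (or `gene_record`).
#' @return non-negative scalar.
#' @export
scaled_chi_square <- function(counts) {
  if (inherits(counts, "gene_record")) counts <- codon_counts(counts)
  stopifnot(inherits(counts, "codon_count_table"))
  if (counts$total_sense_codons == 0) stop("empty gene")
  chi2 <- 0; N <- 0
  for (aa in names(.DEGENERACY)) {
    fam <- .FAMILIES[[aa]]
    tot <- sum(counts$counts[fam])
    if (tot == 0) next
    e <- tot / length(fam)
    chi2 <- chi2 + sum((counts$counts[fam] - e)^2 / e)
    N <- N + tot
  }
  if (N == 0) stop("no codons in synonymous families")
  chi2 / N
}

#' Relative-adaptiveness weights from a reference gene set
#'
#' w_ij = RSCU_ij / max RSCU in family i (equivalently X_ij / X_i,max),
#' so the most-used codon of each family has weight 1.
#'
#' @param ref_counts a `codon_count_table` of the pooled reference set.
#' @param provenance free-text identifier of the reference set.
#' @return object of class `cai_weights`: named `w` over the 59 synonymous
#'   codons, all in (0, 1\], plus `provenance`.
#' @export
reference_weights <- function(ref_counts, provenance = "user reference") {
  stopifnot(inherits(ref_counts, "codon_count_table"))
  unobserved <- names(.DEGENERACY)[vapply(names(.DEGENERACY), function(aa)
    sum(ref_counts$counts[.FAMILIES[[aa]]]) == 0, logical(1))]
  if (length(unobserved) > 0)
    stop("reference set lacks codons for: ",
         paste(unobserved, collapse = ", "))
  w <- stats::setNames(rep(NA_real_, length(.SYN_CODONS)), .SYN_CODONS)
  for (aa in names(.DEGENERACY)) {
    fam <- .FAMILIES[[aa]]
    x <- ref_counts$counts[fam]
    w[fam] <- x / max(x)
  }
  structure(list(w = w, provenance = provenance), class = "cai_weights")
}

#' Bundled human-like CAI reference weights
#'
#' Weights derived from the packaged synthetic human-like codon-usage
#' frequency table (see
#' `system.file("extdata", "human_codon_reference_synthetic.tsv",
#' package = "codonpanel")`). The table is a constructed stand-in that
#' mirrors widely reported aggregate human codon preferences; it is not a
#' download of any specific database release, and CAI values computed with
#' it are comparative, not reproductions of any published CAI.
#'
#' @return a `cai_weights` object.
#' @export
human_reference_weights <- function() {
  if (is.null(.cache$human_w)) {
    tab <- utils::read.delim(.extdata("human_codon_reference_synthetic.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    counts <- stats::setNames(numeric(64), .CODONS)
    counts[tab$codon] <- tab$per_thousand * 1000  # pseudo-counts
    ref <- structure(list(gene_id = "human_ref", counts = counts,
                          total_sense_codons = sum(counts[.SENSE_CODONS])),
                     class = "codon_count_table")
    .cache$human_w <- reference_weights(
      ref, provenance = "human-like synthetic reference v1")
  }
  .cache$human_w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative-adaptiveness weights over the gene's
#' codons, excluding Met, Trp and stop codons. 1 means every codon is the
#' reference set's favourite.
#'
#' @param record a [gene_record()].
#' @param weights a `cai_weights` object (default: bundled human-like
#'   reference).
#' @return scalar in (0, 1\].
#' @export
cai <- function(record, weights = human_reference_weights()) {
  stopifnot(inherits(record, "gene_record"), inherits(weights, "cai_weights"))
  codons <- record$codons[record$codons %in% .SYN_CODONS]
  if (length(codons) == 0) stop("no synonymous codons in gene")
  w <- weights$w[codons]
  if (any(is.na(w) | w <= 0))
    stop("zero or missing weight for codon(s): ",
         paste(unique(codons[is.na(w) | w <= 0]), collapse = ", "))
  exp(mean(log(w)))
}

# the four codon classes of the P2 index: first two bases both weak (A/T)
# or both strong (C/G), third base C or T
.p2_classes <- local({
  b1 <- substr(.CODONS, 1, 1); b2 <- substr(.CODONS, 2, 2)
  b3 <- substr(.CODONS, 3, 3)
  ww <- b1 %in% c("A", "T") & b2 %in% c("A", "T")
  ss <- b1 %in% c("C", "G") & b2 %in% c("C", "G")
  list(WWC = .CODONS[ww & b3 == "C"], WWU = .CODONS[ww & b3 == "T"],
       SSC = .CODONS[ss & b3 == "C"], SSU = .CODONS[ss & b3 == "T"])
})

#' Translational-selection index P2
#'
#' P2 = (WWC + SSU) / (WWY + SSY), where each term sums the supplied
#' per-codon values (conventionally panel-mean RSCU) over the codon class:
#' W = A/U, S = C/G, Y = C/U, classes keyed by the first two bases and the
#' third base. Values above 0.5 indicate a bias favouring
#' codon-anticodon interaction strength (translational selection).
#'
#' @param values named numeric vector covering the 16 codons of classes
#'   WWC, WWU, SSC, SSU; typically mean RSCU across a panel.
#' @return scalar P2.
#' @export
p2 <- function(values) {
  need <- unlist(.p2_classes, use.names = FALSE)
  miss <- need[!(need %in% names(values)) | is.na(values[need])]
  if (length(miss) > 0)
    stop("missing value(s) for codon(s): ", paste(miss, collapse = ", "))
  s <- vapply(.p2_classes, function(cls) sum(values[cls]), numeric(1))
  unname((s["WWC"] + s["SSU"]) /
           (s["WWC"] + s["WWU"] + s["SSC"] + s["SSU"]))
}

#' P2 computed from raw codon counts
#'
#' Counts-based variant of [p2()]: class sums are codon counts rather than
#' RSCU. Agrees with the RSCU form when the classes' families are balanced
#' (e.g. all 2-fold).
#'
#' @param counts a `codon_count_table`.
#' @return scalar P2.
#' @export
p2_from_counts <- function(counts) {
  stopifnot(inherits(counts, "codon_count_table"))
  p2(counts$counts[unlist(.p2_classes, use.names = FALSE)])
}
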