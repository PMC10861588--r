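# Codon-pair counting and context analysis: a 64 x 64 contingency table of
# adjacent in-frame codon pairs with adjusted-residual significance calls.

#' Count adjacent codon pairs across a panel
#'
#' Every in-frame pair (codon k, codon k+1) within each gene is counted,
#' stop codons included; pairs never cross gene boundaries.
#'
#' @param records list of [gene_record()]s (or a single record).
#' @return object of class `codon_pair_matrix`: integer `count` (64 x 64,
#'   5' codon in rows), `total_pairs`, and `distinct_pairs` (pairs with
#'   count >= 1).
#' @export
codon_pair_counts <- function(records) {
  if (inherits(records, "gene_record")) records <- list(records)
  m <- matrix(0L, 64, 64, dimnames = list(.CODONS, .CODONS))
  for (rec in records) {
    codons <- rec$codons
    n <- length(codons)
    if (n < 2) next
    t2 <- table(factor(codons[-n], levels = .CODONS),
                factor(codons[-1], levels = .CODONS))
    m <- m + matrix(as.integer(t2), 64, 64)
  }
  structure(list(count = m, total_pairs = sum(m),
                 distinct_pairs = sum(m >= 1L)),
            class = "codon_pair_matrix")
}

#' @export
print.codon_pair_matrix <- function(x, ...) {
  cat("<codon_pair_matrix> ", x$total_pairs, " pairs, ",
      x$distinct_pairs, " distinct", sep = "")
  if (!is.null(x$adjusted_residual))
    cat("; ", sum(x$significant == "preferred"), " preferred / ",
        sum(x$significant == "rejected"), " rejected at |d| >= ",
        x$threshold, sep = "")
  cat("\n")
  invisible(x)
}

#' Adjusted residuals and significance calls for codon pairs
#'
#' Under independence of 5' and 3' codon, the expected count of cell (i, j)
#' is e_ij = r_i c_j / N (row total, column total, grand total). The
#' adjusted residual is
#' d_ij = (o_ij - e_ij) / sqrt(e_ij (1 - r_i/N) (1 - c_j/N)),
#' approximately standard normal under independence. Cells with
#' d >= +threshold are called `preferred`, d <= -threshold `rejected`,
#' others `ns`; cells in an empty row or column are `absent`.
#'
#' @param matrix a `codon_pair_matrix` from [codon_pair_counts()].
#' @param threshold significance cutoff on |d| (default 3.29, two-sided
#'   p ~ 0.001).
#' @return the input with `expected`, `adjusted_residual`, `significant`
#'   and `threshold` filled in.
#' @export
context_residuals <- function(matrix, threshold = 3.29) {
  stopifnot(inherits(matrix, "codon_pair_matrix"))
  o <- matrix$count
  N <- sum(o)
  if (N == 0) stop("empty pair matrix")
  r <- rowSums(o); cc <- colSums(o)
  if (sum(r > 0) < 2 || sum(cc > 0) < 2)
    stop("degenerate pair matrix: need at least two non-empty rows and columns")
  e <- outer(r, cc) / N
  denom <- sqrt(e * outer(1 - r / N, 1 - cc / N))
  d <- ifelse(denom > 0, (o - e) / denom, NA_real_)
  sig <- matrix("ns", 64, 64, dimnames = dimnames(o))
  sig[!is.na(d) & d >= threshold] <- "preferred"
  sig[!is.na(d) & d <= -threshold] <- "rejected"
  sig[r == 0, ] <- "absent"
  sig[, cc == 0] <- "absent"
  matrix$expected <- e
  matrix$adjusted_residual <- d
  matrix$significant <- sig
  matrix$threshold <- threshold
  matrix
}

#' Top codon pairs by count
#'
#' Pairs sorted by count descending, ties broken lexicographically by 5'
#' then 3' codon. Reported in the RNA alphabet with the encoded amino-acid
#' pair.
#'
#' @param matrix a `codon_pair_matrix`.
#' @param k number of pairs (all distinct pairs if larger).
#' @return data.frame with `pair`, `codon5`, `codon3`, `count`, `aa_pair`.
#' @export
top_pairs <- function(matrix, k = 15) {
  stopifnot(inherits(matrix, "codon_pair_matrix"), k >= 0)
  o <- matrix$count
  idx <- which(o >= 1L, arr.ind = TRUE)
  if (nrow(idx) == 0 || k == 0)
    return(data.frame(pair = character(0), codon5 = character(0),
                      codon3 = character(0), count = integer(0),
                      aa_pair = character(0)))
  c5 <- .CODONS[idx[, 1]]; c3 <- .CODONS[idx[, 2]]
  cnt <- o[idx]
  ord <- order(-cnt, c5, c3)
  take <- ord[seq_len(min(k, length(ord)))]
  aa <- function(cod) ifelse(.GC[cod] == "*", "stop", .GC[cod])
  data.frame(
    pair = paste0(as_rna(c5[take]), "-", as_rna(c3[take])),
    codon5 = c5[take], codon3 = c3[take], count = as.integer(cnt[take]),
    aa_pair = paste0(aa(c5[take]), aa(c3[take])),
    stringsAsFactors = FALSE)
}

#' Rare codon pairs grouped by the 5' amino acid
#'
#' Among pairs observed at least once but at most `max_count` times (absent
#' pairs excluded), counts how many distinct pairs start with a codon of
#' each amino acid; stop-initiated pairs are grouped under `"stop"`.
#'
#' @param matrix a `codon_pair_matrix`.
#' @param max_count rarity cutoff (pairs with count in 1..max_count).
#' @return named integer vector, amino acid -> number of rare pairs.
#' @export
rare_pairs_by_initial <- function(matrix, max_count = 2) {
  stopifnot(inherits(matrix, "codon_pair_matrix"), max_count >= 0)
  o <- matrix$count
  idx <- which(o >= 1L & o <= max_count, arr.ind = TRUE)
  if (nrow(idx) == 0) return(stats::setNames(integer(0), character(0)))
  aa5 <- .GC[.CODONS[idx[, 1]]]
  aa5[aa5 == "*"] <- "stop"
  tab <- table(aa5)
  stats::setNames(as.integer(tab), names(tab))
}

#' Margin-preserving random pair matrices
#'
#' Draws random 64 x 64 tables with the same row and column totals as the
#' observed pair matrix (Patefield's algorithm via [stats::r2dtable()]),
#' the permutation null used to calibrate the adjusted-residual cutoff.
#'
#' @param matrix a `codon_pair_matrix`.
#' @param n number of tables.
#' @param seed integer seed.
#' @return list of `codon_pair_matrix` objects (counts only).
#' @export
shuffle_pair_matrix <- function(matrix, n, seed = NULL) {
  stopifnot(inherits(matrix, "codon_pair_matrix"))
  r <- rowSums(matrix$count); cc <- colSums(matrix$count)
  .with_seed(seed, {
    tabs <- stats::r2dtable(n, r, cc)
    lapply(tabs, function(t) {
      dimnames(t) <- dimnames(matrix$count)
      structure(list(count = t, total_pairs = sum(t),
                     distinct_pairs = sum(t >= 1L)),
                class = "codon_pair_matrix")
    })
  })
}
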