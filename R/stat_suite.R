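# Cross-gene statistics: neutrality regression, PR2 parity, nucleotide
# third-position regressions, correlation matrices, bootstrap RSCU t-test,
# and ordination of RSCU tables.

.simple_regression <- function(x, y, xlab = "x", ylab = "y") {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("zero variance in ", xlab)
  fit <- stats::lm(y ~ x)
  if (stats::var(y) == 0) {
    # flat response: slope 0 is exact, correlation undefined
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = r,
    r_squared = r^2,
    p_value = p,
    n = n, xlab = xlab, ylab = ylab
  ), class = "cub_regression")
}

#' @export
print.cub_regression <- function(x, ...) {
  cat("<cub_regression> ", x$ylab, " ~ ", x$xlab, ": slope ",
      signif(x$slope, 4), ", r = ", signif(x$r, 3), ", r2 = ",
      signif(x$r_squared, 4), ", p = ", format.pval(x$p_value),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Neutrality (GC12 on GC3) regression
#'
#' Ordinary least squares of GC12 on GC3 across genes. The slope estimates
#' the fraction of directional mutation pressure ("relative neutrality");
#' 1 - slope is the selectional constraint. Units of GC12/GC3 (percent or
#' fraction) only need to agree.
#'
#' @param panel data.frame with numeric columns `gc12` and `gc3` (one row
#'   per gene), e.g. from [panel_features()].
#' @return `cub_regression` with extra fields `relative_neutrality` (slope)
#'   and `relative_constraint` (1 - slope).
#' @export
neutrality_regression <- function(panel) {
  stopifnot(all(c("gc12", "gc3") %in% names(panel)))
  out <- .simple_regression(panel$gc3, panel$gc12, "GC3", "GC12")
  out$relative_neutrality <- out$slope
  out$relative_constraint <- 1 - out$slope
  out
}

#' PR2 parity coordinates of a gene
#'
#' GC bias = G3/(G3+C3) (abscissa) and AT bias = A3/(A3+T3) (ordinate),
#' computed on third positions of sense codons. (0.5, 0.5) is the
#' parity-rule-2 neutral point (A3 = T3, G3 = C3). A zero denominator gives
#' NA for that coordinate.
#'
#' @param profile a `composition_profile` (or `gene_record`).
#' @return named vector `c(gc_bias=, at_bias=)`.
#' @export
parity_point <- function(profile) {
  if (inherits(profile, "gene_record")) profile <- nucleotide_composition(profile)
  stopifnot(inherits(profile, "composition_profile"))
  gc_d <- profile$G3 + profile$C3
  at_d <- profile$A3 + profile$T3
  c(gc_bias = if (gc_d > 0) profile$G3 / gc_d else NA_real_,
    at_bias = if (at_d > 0) profile$A3 / at_d else NA_real_)
}

#' Overall vs third-position nucleotide regression
#'
#' Regresses the overall percent of one base on its third-codon-position
#' percent across genes; r-squared is read as the percent of compositional
#' variation attributable to (third-position) mutation pressure.
#'
#' @param panel data.frame with columns `pct_<base>` and `pct_<base>3`
#'   (as produced by [panel_features()]).
#' @param base one of "A", "T", "C", "G".
#' @return a `cub_regression`.
#' @export
nt3_regression <- function(panel, base = c("A", "T", "C", "G")) {
  base <- match.arg(base)
  xcol <- paste0("pct_", base, "3"); ycol <- paste0("pct_", base)
  stopifnot(all(c(xcol, ycol) %in% names(panel)))
  .simple_regression(panel[[xcol]], panel[[ycol]], xcol, ycol)
}

.p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "NS"))))
}

#' Pairwise correlation matrix with significance
#'
#' Pearson or Spearman correlations of all column pairs (pairwise-complete
#' observations), two-sided p-values, optional Bonferroni correction
#' (p multiplied by the number of tested pairs, capped at 1), and
#' significance stars (*, **, *** at 0.05/0.01/0.001, NS otherwise).
#'
#' @param table data.frame or matrix of numeric columns.
#' @param method "pearson" or "spearman".
#' @param correction "none" or "bonferroni".
#' @return object of class `cub_correlations`: matrices `r`, `p`,
#'   `p_adjusted`, `stars`, plus `method` and `correction`.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman"),
                               correction = c("none", "bonferroni")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  m <- as.matrix(table)
  stopifnot(is.numeric(m), ncol(m) >= 2)
  k <- ncol(m)
  vars <- colnames(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    keep <- stats::complete.cases(m[, i], m[, j])
    if (sum(keep) < 3) next
    if (stats::sd(m[keep, i]) == 0 || stats::sd(m[keep, j]) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(m[keep, i], m[keep, j], method = method))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  n_pairs <- k * (k - 1) / 2
  p_adj <- if (correction == "bonferroni") pmin(p * n_pairs, 1) else p
  diag(p_adj) <- 0
  structure(list(r = r, p = p, p_adjusted = p_adj,
                 stars = .p_stars(p_adj), method = method,
                 correction = correction),
            class = "cub_correlations")
}

#' @export
print.cub_correlations <- function(x, digits = 3, ...) {
  k <- ncol(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  out[lower.tri(out)] <- format(round(x$r[lower.tri(x$r)], digits))
  stars <- matrix(x$stars, k, k)
  out[upper.tri(out)] <- stars[upper.tri(stars)]
  cat("<cub_correlations> ", x$method,
      if (x$correction != "none") paste0(", ", x$correction, "-corrected"),
      " (lower triangle r, upper triangle significance)\n", sep = "")
  print(out, quote = FALSE)
  invisible(x)
}

#' Bootstrap t-test of RSCU between two gene panels
#'
#' Per codon, the Welch t statistic between the two observed groups of RSCU
#' values; significance by a null-enforcing bootstrap: both groups are
#' redrawn (rows with replacement) from the pooled rows, and
#' p = (1 + #\{|t*| >= |t_obs|\}) / (reps + 1). Resampling whole gene rows
#' preserves the within-gene correlation between codons. Deterministic for
#' fixed seed.
#'
#' @param group_a,group_b numeric matrices (genes x codons) of RSCU values
#'   with matching columns; e.g. from [rscu_matrix()] or
#'   [simulate_rscu_rows()].
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return data.frame with `codon`, `t`, `p` (NA for codons with zero
#'   variance in both groups or missing values).
#' @export
bootstrap_t_test <- function(group_a, group_b, reps = 1000, seed = NULL) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  stopifnot(ncol(group_a) == ncol(group_b), reps >= 100)
  if (nrow(group_a) < 2 || nrow(group_b) < 2)
    stop("each group needs at least 2 genes")
  na <- nrow(group_a); nb <- nrow(group_b)
  welch_t <- function(a, b) {
    ma <- colMeans(a); mb <- colMeans(b)
    va <- (colMeans(a^2) - ma^2) * nrow(a) / (nrow(a) - 1)
    vb <- (colMeans(b^2) - mb^2) * nrow(b) / (nrow(b) - 1)
    se2 <- va / nrow(a) + vb / nrow(b)
    ifelse(se2 > 0, (ma - mb) / sqrt(se2), NA_real_)
  }
  t_obs <- welch_t(group_a, group_b)
  pooled <- rbind(group_a, group_b)
  np <- nrow(pooled)
  .with_seed(seed, {
    exceed <- numeric(ncol(pooled))
    valid <- !is.na(t_obs)
    for (r in seq_len(reps)) {
      a_star <- pooled[sample.int(np, na, replace = TRUE), , drop = FALSE]
      b_star <- pooled[sample.int(np, nb, replace = TRUE), , drop = FALSE]
      t_star <- welch_t(a_star, b_star)
      exceed <- exceed + as.numeric(!is.na(t_star) &
                                      abs(t_star) >= abs(t_obs))
    }
    p <- (1 + exceed) / (reps + 1)
    p[!valid] <- NA_real_
    data.frame(codon = colnames(pooled), t = unname(t_obs), p = unname(p),
               stringsAsFactors = FALSE)
  })
}

#' RSCU matrix of a panel
#'
#' Convenience: one row per gene, 59 synonymous-codon columns.
#'
#' @param records list of [gene_record()]s.
#' @return numeric matrix genes x 59.
#' @export
rscu_matrix <- function(records) {
  rows <- t(vapply(records, function(r) rscu(r)$rscu,
                   numeric(length(.SYN_CODONS))))
  rownames(rows) <- vapply(records, `[[`, character(1), "gene_id")
  rows
}

#' Ordination of an RSCU table
#'
#' Three conventions over a genes x codons RSCU matrix:
#' * `"covariance"` (default): column-centered, unscaled PCA via SVD —
#'   appropriate since RSCU columns share a common scale;
#' * `"correlation"`: PCA of standardised columns;
#' * `"ca"`: correspondence analysis of the table read as a contingency
#'   table (chi-square-standardised residual SVD), the convention of the
#'   classic palaeontological-statistics ordination tools; its axis
#'   percentages decompose total inertia rather than variance.
#'
#' @param rscu_matrix numeric matrix, genes in rows, codons in columns;
#'   no missing values.
#' @param method ordination convention.
#' @return object of class `rscu_ordination`: `variance_percent` (descending,
#'   summing to 100), `scores` (genes x axes), `loadings` (codons x axes)
#'   and `method`.
#' @export
pca_rscu <- function(rscu_matrix,
                     method = c("covariance", "correlation", "ca")) {
  method <- match.arg(method)
  x <- as.matrix(rscu_matrix)
  if (anyNA(x)) stop("RSCU matrix contains missing values")
  if (nrow(x) < 3) stop("need at least 3 genes")
  if (method %in% c("covariance", "correlation")) {
    pc <- stats::prcomp(x, center = TRUE, scale. = (method == "correlation"))
    ev <- pc$sdev^2
    vp <- 100 * ev / sum(ev)
    scores <- pc$x
    loadings <- pc$rotation
  } else {
    P <- x / sum(x)
    r <- rowSums(P); cc <- colSums(P)
    S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
    sv <- svd(S)
    ev <- sv$d^2
    vp <- 100 * ev / sum(ev)
    # row principal coordinates; column standard coordinates
    scores <- diag(1 / sqrt(r)) %*% sv$u %*% diag(sv$d)
    loadings <- diag(1 / sqrt(cc)) %*% sv$v
    rownames(scores) <- rownames(x); rownames(loadings) <- colnames(x)
    colnames(scores) <- colnames(loadings) <- paste0("Axis", seq_along(sv$d))
  }
  structure(list(variance_percent = vp, scores = scores,
                 loadings = loadings, method = method),
            class = "rscu_ordination")
}

#' @export
print.rscu_ordination <- function(x, ...) {
  cat("<rscu_ordination> method = ", x$method, "; axis percents: ",
      paste(round(x$variance_percent[seq_len(min(
        4, length(x$variance_percent)))], 2), collapse = ", "),
      " ...\n", sep = "")
  invisible(x)
}
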