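# Orchestration: per-gene feature table, full pipeline run with file
# outputs, and loaders for the bundled published-table fixtures.

#' Per-gene feature table for a panel
#'
#' One row per gene: length, overall and third-position base percents,
#' GC1/GC2/GC3/GC12, ENc, SCS, CAI, the six skews, parity coordinates and
#' the protein indices of the translated product. This is the table the
#' cross-gene statistics (neutrality, parity, regressions, correlations)
#' operate on.
#'
#' @param records list of [gene_record()]s.
#' @param weights `cai_weights` for the CAI column.
#' @return data.frame, one row per gene. `gc12`/`gc3` are percents;
#'   `gc3_frac` the fraction used by [expected_enc()]; `normalized_length`
#'   is length/100 (comparable in magnitude to percent GC).
#' @export
panel_features <- function(records, weights = human_reference_weights()) {
  stopifnot(length(records) > 0)
  rows <- lapply(records, function(rec) {
    comp <- nucleotide_composition(rec)
    sk <- skews(comp)
    par <- parity_point(comp)
    cnt <- codon_counts(rec)
    pp <- protein_indices(translate_cds(rec))
    data.frame(
      gene_id = rec$gene_id,
      length_nt = rec$length_nt,
      normalized_length = rec$length_nt / 100,
      pct_A = comp$base_percent[["A"]], pct_C = comp$base_percent[["C"]],
      pct_G = comp$base_percent[["G"]], pct_T = comp$base_percent[["T"]],
      pct_A3 = comp$pos_percent["A", 3], pct_C3 = comp$pos_percent["C", 3],
      pct_G3 = comp$pos_percent["G", 3], pct_T3 = comp$pos_percent["T", 3],
      gc1 = comp$GC1, gc2 = comp$GC2, gc3 = comp$GC3, gc12 = comp$GC12,
      gc3_frac = comp$GC3 / 100,
      enc = enc(cnt)$enc,
      scs = scaled_chi_square(cnt),
      cai = cai(rec, weights),
      at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]],
      purine_skew = sk[["purine_skew"]],
      pyrimidine_skew = sk[["pyrimidine_skew"]],
      keto_skew = sk[["keto_skew"]], amino_skew = sk[["amino_skew"]],
      gc_bias = par[["gc_bias"]], at_bias = par[["at_bias"]],
      gravy = pp$gravy, aroma = pp$aroma, pi = pp$pi,
      instability_index = pp$instability_index,
      aliphatic_index = pp$aliphatic_index,
      hydrophobic_fraction = pp$hydrophobic_fraction,
      acidic_frac = pp$acidic_frac, basic_frac = pp$basic_frac,
      neutral_frac = pp$neutral_frac,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_tsv <- function(x, path, rn = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rn, col.names = !is.null(colnames(x)) || !rn)
  path
}

#' Run the full codon-pattern analysis
#'
#' Executes the whole pipeline over a panel: validation, composition and
#' skews, dinucleotide odds ratios, RSCU/ENc/SCS/CAI/P2, pooled codon-pair
#' context with adjusted residuals, protein indices, neutrality and parity,
#' skew correlations and RSCU ordination; optionally a bootstrap RSCU
#' t-test against a comparison panel. With `out_dir` set, writes one
#' TSV/JSON per analysis plus a `manifest.json`; outputs are deterministic
#' for identical inputs and configuration (reruns are byte-identical).
#'
#' @param panel list of [gene_record()]s (or a FASTA path).
#' @param compare optional comparison panel (records or FASTA path) for the
#'   bootstrap RSCU t-test.
#' @param weights `cai_weights` for CAI.
#' @param out_dir output directory (created); NULL computes in memory only.
#' @param seed integer seed for the bootstrap stage.
#' @param strict reject genes with internal stop codons.
#' @param bootstrap_reps bootstrap replicates (>= 100).
#' @param pca_method ordination convention, see [pca_rscu()].
#' @param residual_threshold adjusted-residual cutoff, see
#'   [context_residuals()].
#' @return object of class `codon_panel_analysis`: all stage results plus a
#'   `manifest` echoing the configuration.
#' @export
run_codon_analysis <- function(panel, compare = NULL,
                               weights = human_reference_weights(),
                               out_dir = NULL, seed = 1, strict = FALSE,
                               bootstrap_reps = 1000,
                               pca_method = c("covariance", "correlation",
                                              "ca"),
                               residual_threshold = 3.29) {
  pca_method <- match.arg(pca_method)
  stopifnot(bootstrap_reps >= 100)
  if (is.character(panel)) panel <- read_cds_fasta(panel)
  if (is.character(compare)) compare <- read_cds_fasta(compare)

  stage <- "validation"
  res <- tryCatch({
    reports <- lapply(panel, validate_cds)
    if (strict) {
      bad <- Filter(function(v) length(v$internal_stop_positions) > 0, reports)
      if (length(bad) > 0)
        stop("internal stop codon(s) in gene(s): ",
             paste(vapply(bad, `[[`, character(1), "gene_id"),
                   collapse = ", "))
    }

    stage <- "composition"
    comps <- lapply(panel, nucleotide_composition)
    dinuc <- lapply(panel, dinucleotide_odds)

    stage <- "codon_usage"
    feats <- panel_features(panel, weights)
    rscu_m <- rscu_matrix(panel)
    p2_panel <- p2(colMeans(rscu_m, na.rm = TRUE))

    stage <- "codon_context"
    pairs <- context_residuals(codon_pair_counts(panel),
                               threshold = residual_threshold)

    stage <- "stat_suite"
    neutral <- neutrality_regression(feats)
    skew_cor <- correlation_matrix(
      feats[, c("at_skew", "gc_skew", "purine_skew", "pyrimidine_skew",
                "amino_skew", "keto_skew")])
    ord <- pca_rscu(rscu_m[, colSums(is.na(rscu_m)) == 0, drop = FALSE],
                    method = pca_method)
    ttest <- NULL
    if (!is.null(compare)) {
      stage <- "bootstrap_t_test"
      rscu_b <- rscu_matrix(compare)
      keep <- colSums(is.na(rscu_m)) == 0 & colSums(is.na(rscu_b)) == 0
      ttest <- bootstrap_t_test(rscu_m[, keep, drop = FALSE],
                                rscu_b[, keep, drop = FALSE],
                                reps = bootstrap_reps, seed = seed)
    }

    list(validation = reports, composition = comps, dinucleotide = dinuc,
         features = feats, rscu = rscu_m, p2 = p2_panel, pairs = pairs,
         neutrality = neutral, skew_correlations = skew_cor,
         ordination = ord, rscu_ttest = ttest)
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package = "codonpanel",
    version = as.character(utils::packageVersion("codonpanel")),
    n_genes = length(panel),
    genes = vapply(panel, `[[`, character(1), "gene_id"),
    n_compare = if (is.null(compare)) 0L else length(compare),
    seed = seed, strict = strict, bootstrap_reps = bootstrap_reps,
    pca_method = pca_method, residual_threshold = residual_threshold,
    cai_reference = weights$provenance,
    validation = lapply(res$validation, function(v)
      list(gene_id = v$gene_id, length_ok = v$length_ok,
           internal_stops = length(v$internal_stop_positions),
           ambiguous_dropped = v$ambiguous_codons_dropped)))
  res$manifest <- manifest
  class(res) <- "codon_panel_analysis"

  if (!is.null(out_dir)) .write_analysis(res, out_dir)
  res
}

# write every stage's table; remove partial outputs on failure
.write_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on.exit(if (!is.null(attr(written, "failed"))) unlink(written))
  wr <- function(x, file, rn = FALSE) {
    p <- file.path(out_dir, file)
    .write_tsv(x, p, rn)
    written <<- c(written, p)
  }
  tryCatch({
    comp_tab <- do.call(rbind, lapply(res$composition, function(cp)
      data.frame(gene_id = cp$gene_id, length_nt = cp$length_nt,
                 pct_A = cp$base_percent[["A"]], pct_C = cp$base_percent[["C"]],
                 pct_G = cp$base_percent[["G"]], pct_T = cp$base_percent[["T"]],
                 gc1 = cp$GC1, gc2 = cp$GC2, gc3 = cp$GC3, gc12 = cp$GC12)))
    wr(comp_tab, "composition.tsv")
    dn <- do.call(rbind, Map(function(g, d)
      cbind(gene_id = g, d), names(res$dinucleotide), res$dinucleotide))
    wr(dn, "dinucleotide_odds.tsv")
    wr(round(res$rscu, 2), "rscu.tsv", rn = TRUE)
    wr(res$rscu, "rscu_full.tsv", rn = TRUE)
    wr(res$features, "panel_features.tsv")
    cub <- res$features[, c("gene_id", "length_nt", "enc", "scs", "cai")]
    wr(cub, "cub_indices.tsv")
    m <- res$pairs
    idx <- which(m$count > 0, arr.ind = TRUE)
    pair_tab <- data.frame(
      codon5 = as_rna(.CODONS[idx[, 1]]), codon3 = as_rna(.CODONS[idx[, 2]]),
      count = m$count[idx], expected = m$expected[idx],
      adjusted_residual = m$adjusted_residual[idx],
      call = m$significant[idx])
    pair_tab <- pair_tab[order(-pair_tab$count, pair_tab$codon5,
                               pair_tab$codon3), ]
    wr(pair_tab, "codon_pairs.tsv")
    resid <- m$adjusted_residual
    dimnames(resid) <- list(as_rna(.CODONS), as_rna(.CODONS))
    wr(resid, "context_matrix.tsv", rn = TRUE)
    rare <- rare_pairs_by_initial(m)
    wr(data.frame(amino_acid = names(rare), rare_pairs = as.integer(rare)),
       "rare_pairs_by_aa.tsv")
    wr(res$features[, c("gene_id", "gravy", "aroma", "pi",
                        "instability_index", "aliphatic_index",
                        "hydrophobic_fraction", "acidic_frac", "basic_frac",
                        "neutral_frac")], "protein_indices.tsv")
    wr(res$features[, c("gene_id", "gc_bias", "at_bias")], "parity.tsv")
    jsonlite::write_json(
      res$neutrality[c("slope", "intercept", "r", "r_squared", "p_value",
                       "n", "relative_neutrality", "relative_constraint")],
      file.path(out_dir, "neutrality.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(out_dir, "neutrality.json"))
    wr(res$skew_correlations$r, "correlations_skews.tsv", rn = TRUE)
    wr(data.frame(axis = seq_along(res$ordination$variance_percent),
                  variance_percent = res$ordination$variance_percent),
       "pca_variance.tsv")
    wr(res$ordination$scores, "pca_scores.tsv", rn = TRUE)
    wr(res$ordination$loadings, "pca_loadings.tsv", rn = TRUE)
    if (!is.null(res$rscu_ttest)) wr(res$rscu_ttest, "rscu_ttest.tsv")
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    attr(written, "failed") <- TRUE
    stop(e)
  })
  invisible(out_dir)
}

#' @export
print.codon_panel_analysis <- function(x, ...) {
  cat("<codon_panel_analysis> ", x$manifest$n_genes, " genes\n", sep = "")
  cat("  neutrality slope ", signif(x$neutrality$slope, 4),
      " (constraint ", signif(x$neutrality$relative_constraint, 4), ")\n",
      sep = "")
  cat("  panel P2 ", signif(x$p2, 4), "; ", x$pairs$total_pairs,
      " codon pairs (", x$pairs$distinct_pairs, " distinct)\n", sep = "")
  cat("  ordination (", x$ordination$method, ") axis 1: ",
      round(x$ordination$variance_percent[1], 2), "%\n", sep = "")
  invisible(x)
}

#' Load a bundled published-table fixture
#'
#' Two machine-readable tables from a published analysis of the 18-gene
#' depression-associated panel ship with the package and are used by the
#' statistics stages as fixture inputs:
#' * `"rscu"`: the per-gene RSCU table (59 codons x 18 genes, 2-decimal
#'   published values) — returned as a genes x 59 matrix;
#' * `"skews"`: the six nucleotide skews per gene (18 x 6) — returned as a
#'   data.frame with a `gene` column.
#'
#' @param which `"rscu"` or `"skews"`.
#' @param path override the bundled file with another of the same schema.
#' @return matrix or data.frame as described.
#' @export
load_table_fixture <- function(which = c("rscu", "skews"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path))
    path <- .extdata(switch(which, rscu = "rscu_18genes.tsv",
                            skews = "skews_18genes.tsv"))
  if (!file.exists(path) || file.size(path) == 0)
    stop("fixture file missing or empty: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (which == "rscu") {
    if (names(tab)[1] != "codon")
      stop("schema mismatch: expected first column 'codon', got '",
           names(tab)[1], "'")
    missing <- setdiff(.SYN_CODONS, tab$codon)
    extra <- setdiff(tab$codon, .SYN_CODONS)
    if (length(missing) > 0 || length(extra) > 0)
      stop("schema mismatch: ",
           if (length(missing)) paste("missing codons:",
                                      paste(missing, collapse = ", ")),
           if (length(extra)) paste(" unexpected rows:",
                                    paste(extra, collapse = ", ")))
    m <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(m) <- tab$codon
    m
  } else {
    need <- c("gene", "at_skew", "gc_skew", "purine_skew",
              "pyrimidine_skew", "amino_skew", "keto_skew")
    if (!identical(sort(names(tab)), sort(need)))
      stop("schema mismatch: unexpected columns: ",
           paste(setdiff(names(tab), need), collapse = ", "))
    tab[, need]
  }
}
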