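# Seeded synthetic-CDS generator with controllable codon usage, GC3 and
# dinucleotide structure. Panels stand in for downloaded gene sets so every
# downstream stage is testable offline.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  code
}

# expand a (possibly partial) named weight vector to all 64 codons
.full_weights <- function(codon_weights) {
  w <- stats::setNames(numeric(64), .CODONS)
  if (is.null(codon_weights)) {
    w[.SENSE_CODONS] <- 1
  } else {
    if (is.null(names(codon_weights)))
      stop("codon_weights must be a named vector")
    bad <- setdiff(names(codon_weights), .CODONS)
    if (length(bad) > 0) stop("unknown codon(s): ", paste(bad, collapse = ", "))
    if (any(codon_weights < 0)) stop("codon weights must be non-negative")
    w[names(codon_weights)] <- codon_weights
  }
  w
}

# RSCU implied by a weight vector (per family, weight / family mean weight)
.weights_to_rscu <- function(w) {
  out <- stats::setNames(rep(NA_real_, length(.SYN_CODONS)), .SYN_CODONS)
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    if (length(fam) < 2) next
    wf <- w[fam]
    if (sum(wf) > 0) out[fam] <- wf / mean(wf)
  }
  out
}

# Tilt third-position G/C weights multiplicatively so that the expected GC3
# (uniform amino-acid usage, Met/Trp included) equals `gc3_target`.
.tilt_weights_gc3 <- function(w, gc3_target) {
  third_gc <- substr(.CODONS, 3, 3) %in% c("G", "C")
  names(third_gc) <- .CODONS
  exp_gc3 <- function(logt) {
    wt <- w * ifelse(third_gc, exp(logt), 1)
    pr <- vapply(.FAMILIES, function(fam) {
      s <- sum(wt[fam])
      if (s == 0) return(NA_real_)
      sum(wt[fam][third_gc[fam]]) / s
    }, numeric(1))
    mean(pr, na.rm = TRUE)
  }
  lo <- exp_gc3(-30); hi <- exp_gc3(30)
  if (is.na(lo) || is.na(hi) || gc3_target < lo || gc3_target > hi)
    stop(sprintf("GC3 target %.3f infeasible with these weights (range %.3f-%.3f)",
                 gc3_target, lo, hi))
  logt <- stats::uniroot(function(x) exp_gc3(x) - gc3_target,
                         c(-30, 30), tol = 1e-9)$root
  w * ifelse(third_gc, exp(logt), 1)
}

#' Generate one synthetic coding sequence
#'
#' Draws an amino-acid sequence uniformly over the 20 standard residues (or
#' uses a supplied one), then draws each codon within its synonymous family
#' with probability proportional to `codon_weights`. The sequence starts with
#' ATG and ends with a stop codon. Deterministic for a fixed seed.
#'
#' Optional structure: `dinucleotide_bias` multiplies the acceptance
#' probability of a candidate codon by a factor attached to the codon-boundary
#' dinucleotide (accept/reject resampling), emulating e.g. CpG depletion
#' across codon junctions; since rejection can only steer synonymous choice,
#' it bites where the first codon base is free (Leu/Ser/Arg families) and
#' leaves fixed-start families untouched. `pair_rule = list(codon5=, codon3=, prob=)` plants
#' a codon-pair preference: wherever adjacent amino acids match the pair's
#' amino acids, both codons are forced to the pair with probability `prob`.
#'
#' @param length_nt total length in nucleotides (multiple of 3, >= 9).
#' @param codon_weights named non-negative weights per codon (defaults to
#'   uniform over the 61 sense codons); codons not named get weight 0.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param aa_seq optional interior amino-acid string of length
#'   `length_nt/3 - 2`.
#' @param dinucleotide_bias optional named multipliers per dinucleotide.
#' @param pair_rule optional list(codon5, codon3, prob).
#' @param gene_id label for the generated record.
#' @return a [gene_record()] with attribute `target_rscu` (the RSCU implied
#'   by the weights) and `codon_weights`.
#' @export
generate_cds <- function(length_nt, codon_weights = NULL, seed = NULL,
                         aa_seq = NULL, dinucleotide_bias = NULL,
                         pair_rule = NULL, gene_id = "synth") {
  stopifnot(length_nt %% 3 == 0, length_nt >= 9)
  w <- .full_weights(codon_weights)
  n_codons <- length_nt / 3L
  n_interior <- n_codons - 2L
  .with_seed(seed, {
    if (is.null(aa_seq)) {
      aa <- sample(.AA_LETTERS, n_interior, replace = TRUE)
    } else {
      aa <- strsplit(toupper(aa_seq), "")[[1]]
      if (length(aa) != n_interior)
        stop("aa_seq must have ", n_interior, " residues")
      if (!all(aa %in% .AA_LETTERS)) stop("nonstandard residue in aa_seq")
    }
    for (a in unique(aa)) {
      if (sum(w[.FAMILIES[[a]]]) <= 0)
        stop("all-zero codon weights for amino acid ", a)
    }
    if (is.null(dinucleotide_bias)) {
      codons <- character(n_interior)
      for (a in unique(aa)) {
        fam <- .FAMILIES[[a]]
        idx <- which(aa == a)
        codons[idx] <- sample(fam, length(idx), replace = TRUE, prob = w[fam])
      }
    } else {
      max_mult <- max(unlist(dinucleotide_bias), 1)
      codons <- character(n_interior)
      prev <- "ATG"
      for (i in seq_len(n_interior)) {
        fam <- .FAMILIES[[aa[i]]]
        for (try in 1:100) {
          cand <- if (length(fam) == 1) fam else
            sample(fam, 1, prob = w[fam])
          dn <- paste0(substr(prev, 3, 3), substr(cand, 1, 1))
          m <- if (dn %in% names(dinucleotide_bias))
            dinucleotide_bias[[dn]] else 1
          if (stats::runif(1) < m / max_mult) break
        }
        codons[i] <- cand
        prev <- codons[i]
      }
    }
    if (!is.null(pair_rule)) {
      aa5 <- .GC[[pair_rule$codon5]]; aa3 <- .GC[[pair_rule$codon3]]
      hit <- which(aa[-n_interior] == aa5 & aa[-1] == aa3)
      hit <- hit[stats::runif(length(hit)) < pair_rule$prob]
      codons[hit] <- pair_rule$codon5
      codons[hit + 1L] <- pair_rule$codon3
    }
    stop_w <- w[.STOP_CODONS]
    stop_codon <- if (sum(stop_w) > 0)
      sample(.STOP_CODONS, 1, prob = stop_w) else sample(.STOP_CODONS, 1)
    rec <- gene_record(gene_id, paste(c("ATG", codons, stop_codon),
                                      collapse = ""))
    attr(rec, "target_rscu") <- .weights_to_rscu(w)
    attr(rec, "codon_weights") <- w
    rec
  })
}

#' Generate a synthetic CDS panel
#'
#' Emulates a panel of protein-coding genes: lengths drawn uniformly over
#' multiples of 3 in `length_range`, per-gene GC3 targets drawn uniformly in
#' `gc3_range` and realised by tilting third-position G/C codon weights.
#' Defaults mirror the 18-gene depression-associated reference panel: 18
#' genes of 1350-1650 bp with GC3 spanning 41.8-83.8%.
#'
#' @param n_genes number of genes.
#' @param length_range nucleotide length bounds (rounded to codons).
#' @param gc3_range bounds for the per-gene GC3 target, fractions in (0,1).
#' @param rscu_targets optional named codon->RSCU targets shaping the base
#'   weights before the GC3 tilt.
#' @param dinucleotide_bias,pair_rule passed to [generate_cds()].
#' @param seed integer seed; the panel is fully reproducible from its
#'   arguments plus the seed.
#' @param gene_prefix prefix for generated gene ids.
#' @return list of `gene_record`s; each carries attributes `target_rscu` and
#'   `target_gc3`, and the list carries attribute `panel_spec`.
#' @export
generate_panel <- function(n_genes = 18, length_range = c(1350, 1650),
                           gc3_range = c(0.418, 0.8382),
                           rscu_targets = NULL, dinucleotide_bias = NULL,
                           pair_rule = NULL, seed = NULL,
                           gene_prefix = "gene") {
  stopifnot(n_genes >= 0, length(length_range) == 2, length(gc3_range) == 2,
            all(gc3_range >= 0 & gc3_range <= 1))
  if (n_genes == 0) return(structure(list(), panel_spec = list(n_genes = 0)))
  base_w <- .full_weights(
    if (is.null(rscu_targets)) NULL else rscu_targets)
  .with_seed(seed, {
    len_choices <- seq(ceiling(length_range[1] / 3),
                       floor(length_range[2] / 3))
    lens <- 3L * len_choices[sample.int(length(len_choices), n_genes,
                                        replace = TRUE)]
    gc3s <- stats::runif(n_genes, gc3_range[1], gc3_range[2])
    recs <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      w <- .tilt_weights_gc3(base_w, gc3s[i])
      recs[[i]] <- generate_cds(lens[i], codon_weights = w,
                                dinucleotide_bias = dinucleotide_bias,
                                pair_rule = pair_rule,
                                gene_id = sprintf("%s%02d", gene_prefix, i))
      attr(recs[[i]], "target_gc3") <- gc3s[i]
    }
    names(recs) <- vapply(recs, `[[`, character(1), "gene_id")
    attr(recs, "panel_spec") <- list(
      n_genes = n_genes, length_range = length_range, gc3_range = gc3_range,
      rscu_targets = rscu_targets, dinucleotide_bias = dinucleotide_bias,
      seed = seed)
    recs
  })
}

#' Generate a synthetic housekeeping comparison panel
#'
#' Same machinery as [generate_panel()] but with an independent default
#' codon-usage profile (lower, narrower GC3) so that differences between the
#' study panel and the comparison panel exist by construction. Used as the
#' second group of the bootstrap RSCU t-test; the default size matches the
#' 62-gene housekeeping comparison set.
#'
#' @inheritParams generate_panel
#' @export
generate_housekeeping_panel <- function(n_genes = 62, seed = NULL,
                                        length_range = c(1350, 1650),
                                        gc3_range = c(0.35, 0.65),
                                        rscu_targets = NULL, ...) {
  generate_panel(n_genes = n_genes, length_range = length_range,
                 gc3_range = gc3_range, rscu_targets = rscu_targets,
                 seed = seed, gene_prefix = "hk", ...)
}

#' Simulate per-gene RSCU rows from the generator's count model
#'
#' Draws, for each gene, amino-acid counts from a uniform multinomial and
#' codon counts within each family proportional to `codon_weights`, then
#' computes RSCU. This is the count-level marginal of [generate_cds()]
#' (codon choice is i.i.d. per amino acid), used for calibration and power
#' simulations where sequence assembly is unnecessary.
#'
#' @param n_genes number of rows.
#' @param n_codons sense codons per gene.
#' @param codon_weights as in [generate_cds()].
#' @param seed integer seed.
#' @return numeric matrix `n_genes` x 59 of RSCU values (NA for unobserved
#'   families).
#' @export
simulate_rscu_rows <- function(n_genes, n_codons, codon_weights = NULL,
                               seed = NULL) {
  w <- .full_weights(codon_weights)
  .with_seed(seed, {
    out <- matrix(NA_real_, n_genes, length(.SYN_CODONS),
                  dimnames = list(NULL, .SYN_CODONS))
    for (g in seq_len(n_genes)) {
      aa_counts <- stats::rmultinom(1, n_codons,
                                    rep(1 / 20, 20))[, 1]
      names(aa_counts) <- .AA_LETTERS
      counts <- stats::setNames(numeric(64), .CODONS)
      for (a in .AA_LETTERS) {
        fam <- .FAMILIES[[a]]
        if (aa_counts[[a]] == 0) next
        if (length(fam) == 1) {
          counts[fam] <- aa_counts[[a]]
        } else {
          counts[fam] <- stats::rmultinom(1, aa_counts[[a]],
                                          w[fam] / sum(w[fam]))[, 1]
        }
      }
      out[g, ] <- .rscu_of_counts(counts)
    }
    out
  })
}
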