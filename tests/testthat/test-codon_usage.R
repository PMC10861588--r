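test_that("codon counts separate sense totals from the 64-wide table", {
  cc <- codon_counts(rec_of(c("TTT", "TTT", "TTC", "TAA")))
  expect_equal(unname(cc$counts[c("TTT", "TTC", "TAA")]), c(2L, 1L, 1L))
  expect_equal(cc$total_sense_codons, 3L)
  pooled <- pool_codon_counts(list(cc, cc))
  expect_equal(unname(pooled$counts[["TTT"]]), 4L)
  expect_equal(pooled$total_sense_codons, 6L)
})

test_that("RSCU matches the defining ratio and conserves family sums", {
  rs <- rscu(rec_of(c("TTT", "TTT", "TTC", "TAA")))
  expect_equal(unname(rs$rscu[["TTT"]]), 4 / 3, tolerance = 1e-12)
  expect_equal(unname(rs$rscu[["TTC"]]), 2 / 3, tolerance = 1e-12)
  # equal counts in a family -> all 1
  rs2 <- rscu(rec_of(c("GTT", "GTC", "GTA", "GTG")))
  expect_equal(unname(rs2$rscu[c("GTT", "GTC", "GTA", "GTG")]), rep(1, 4))
  # unobserved families are missing, not zero
  expect_true(is.na(rs$rscu[["GGG"]]))
  # family sums equal family sizes on a random gene
  g <- generate_cds(9003, seed = 41)
  vals <- rscu(g)$rscu
  fams <- split(names(vals), codon_aa(names(vals)))
  for (f in fams) {
    if (!anyNA(vals[f])) expect_equal(sum(vals[f]), length(f),
                                      tolerance = 1e-9)
  }
})

test_that("RSCU classification thresholds are 0.6 and 1.6", {
  rs <- rscu(rec_of(c(rep("TTT", 9), "TTC", "TAA")))
  expect_equal(unname(rs$classification[["TTT"]]), "over")   # 1.8
  expect_equal(unname(rs$classification[["TTC"]]), "under")  # 0.2
})

test_that("ENc hits its analytic limits", {
  g_biased <- generate_cds(3003, codon_weights = one_codon_weights(),
                           seed = 2)
  expect_equal(enc(g_biased)$enc, 20)
  # uniform generator output: near-maximal effective number
  g_unif <- generate_cds(300003, seed = 3)
  expect_gte(enc(g_unif)$enc, 59)
  expect_lte(enc(g_unif)$enc, 61)
  # exact uniform counts hit the 61 ceiling
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc)[gc != "*"], gc[gc != "*"])
  expect_equal(enc(rec_of(unlist(lapply(fams, rep, times = 4))))$enc, 61)
})

test_that("family homozygosity follows Wright's formula", {
  # Phe {TTT:3, TTC:1}: F = (4 * 0.625 - 1) / 3 = 0.5
  e <- enc(rec_of(c(rep("TTT", 3), "TTC")))
  expect_equal(e$F2, 0.5)
  expect_gt(e$families_missing, 0)  # other degeneracy classes substituted
})

test_that("the expected ENc-GC3 curve has its known values and shape", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0.001), 31.03, tolerance = 1e-3)
  # peaks at GC3 ~ 0.5, approaches 31 at both composition extremes
  s <- seq(0.05, 0.95, by = 0.05)
  expect_equal(which.max(expected_enc(s)), which(s == 0.5))
  expect_lt(abs(expected_enc(0.999) - 32.06), 0.01)
  expect_error(expected_enc(0))
})

test_that("scaled chi-square matches hand values and scale invariance", {
  expect_equal(scaled_chi_square(rec_of(c("GTT", "GTC", "GTA", "GTG"))), 0)
  expect_equal(scaled_chi_square(rec_of(rep("TTT", 4))), 1)
  g <- generate_cds(3003, seed = 44)
  cc <- codon_counts(g)
  doubled <- cc
  doubled$counts <- cc$counts * 2L
  doubled$total_sense_codons <- cc$total_sense_codons * 2L
  expect_equal(scaled_chi_square(doubled), scaled_chi_square(cc),
               tolerance = 1e-12)
  expect_gte(scaled_chi_square(g), 0)
})

test_that("SCS of a uniform generator is near zero at large counts", {
  g <- generate_cds(30003, seed = 45)
  expect_lte(scaled_chi_square(g), 0.02)
})

test_that("reference weights are family-normalised and scale-free", {
  ref <- codon_counts(rec_of(c(rep("TTT", 10), rep("TTC", 30))))
  # other families unobserved -> error listing them
  expect_error(reference_weights(ref), "lacks codons")
  g <- generate_cds(60003, seed = 46)
  ref2 <- codon_counts(g)
  w <- reference_weights(ref2, "test")
  expect_true(all(w$w > 0 & w$w <= 1))
  fams <- split(names(w$w), codon_aa(names(w$w)))
  for (f in fams) expect_equal(max(w$w[f]), 1)
  scaled <- ref2
  scaled$counts <- ref2$counts * 10L
  expect_equal(reference_weights(scaled, "x")$w, w$w)
})

test_that("CAI is the geometric mean of weights with known cases", {
  g <- generate_cds(60003, seed = 47)
  w <- reference_weights(codon_counts(g), "test")
  # gene made only of family-maximal codons -> CAI 1
  best <- names(w$w)[vapply(names(w$w), function(cd) {
    fam <- names(w$w)[codon_aa(names(w$w)) == codon_aa(cd)]
    w$w[[cd]] == max(w$w[fam])
  }, logical(1))]
  gene_best <- rec_of(best)
  expect_equal(cai(gene_best, w), 1)
  # two-codon gene: sqrt(w1 * w2)
  wman <- structure(list(w = stats::setNames(rep(1, length(syn_codons())),
                                             syn_codons()),
                         provenance = "manual"), class = "cai_weights")
  wman$w[["TTT"]] <- 0.5
  expect_equal(cai(rec_of(c("TTT", "TTC")), wman), sqrt(0.5))
  # order invariance
  g2 <- rec_of(sample(g$codons))
  expect_equal(cai(g2, w), cai(g, w))
})

test_that("CAI strictly decreases when a codon is swapped to a lower weight", {
  g <- generate_cds(3003, seed = 48)
  w <- human_reference_weights()
  base <- cai(g, w)
  set.seed(49)
  for (i in 1:10) {
    codons <- g$codons
    # find a codon whose family has a lower-weight synonym
    cand <- which(vapply(codons, function(cd) {
      cd %in% names(w$w) &&
        any(w$w[intersect(fam_of(cd), names(w$w))] < w$w[[cd]])
    }, logical(1)))
    pos <- sample(cand, 1)
    fam <- intersect(fam_of(codons[pos]), names(w$w))
    lower <- fam[w$w[fam] < w$w[[codons[pos]]]]
    codons[pos] <- lower[1]
    expect_lt(cai(rec_of(codons), w), base)
  }
})

test_that("P2 equals 0.5 at equal usage and responds to WWC enrichment", {
  vals <- stats::setNames(rep(1, length(syn_codons())), syn_codons())
  expect_equal(p2(vals), 0.5)
  wwc <- c("AAC", "ATC", "TAC", "TTC")
  vals2 <- vals
  vals2[wwc] <- 2
  expect_equal(p2(vals2), 12 / 20)
  expect_error(p2(vals[-1]), "missing")
})

test_that("count-based P2 agrees when family totals scale with family size", {
  counts <- stats::setNames(numeric(64), names(Biostrings::GENETIC_CODE))
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc)[gc != "*"], gc[gc != "*"])
  set.seed(50)
  for (f in fams) {
    n <- length(f)
    if (n == 1) { counts[f] <- 2; next }
    # family total = 2 * family size -> RSCU = counts / 2 everywhere
    x <- as.vector(stats::rmultinom(1, 2 * n, rep(1, n)))
    counts[f] <- x
  }
  cc <- structure(list(gene_id = "c", counts = counts,
                       total_sense_codons = sum(counts)),
                  class = "codon_count_table")
  expect_equal(p2_from_counts(cc), p2(rscu(cc)$rscu))
})
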