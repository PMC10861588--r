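test_that("pair counting stays within genes and tracks totals", {
  m <- codon_pair_counts(list(rec_of(c("GTG", "GTG", "GTG"))))
  expect_equal(m$count["GTG", "GTG"], 2L)
  expect_equal(m$total_pairs, 2L)
  expect_equal(m$distinct_pairs, 1L)
  m2 <- codon_pair_counts(list(rec_of(c("AAA", "TTT"), "a"),
                               rec_of(c("TTT", "AAA"), "b")))
  expect_equal(m2$count["AAA", "TTT"], 1L)
  expect_equal(m2$count["TTT", "AAA"], 1L)
  expect_equal(m2$total_pairs, 2L)  # no cross-gene TTT-TTT pair
  m0 <- codon_pair_counts(list())
  expect_equal(m0$total_pairs, 0L)
})

test_that("total pairs equals sum of per-gene codon counts minus one", {
  panel <- generate_panel(7, length_range = c(300, 600), seed = 51)
  m <- codon_pair_counts(panel)
  expect_equal(m$total_pairs,
               sum(vapply(panel, function(r) length(r$codons) - 1L,
                          integer(1))))
})

test_that("adjusted residuals match a hand-computed 2x2 oracle", {
  # counts [[9,1],[1,9]] placed in an otherwise empty matrix
  m <- codon_pair_counts(list())
  m$count["AAA", "AAA"] <- 9L; m$count["AAA", "TTT"] <- 1L
  m$count["TTT", "AAA"] <- 1L; m$count["TTT", "TTT"] <- 9L
  m$total_pairs <- 20L
  f <- context_residuals(m)
  # independent oracle: e = r*c/N, d = (o-e)/sqrt(e(1-r/N)(1-c/N))
  e11 <- 10 * 10 / 20
  d11 <- (9 - e11) / sqrt(e11 * (1 - 0.5) * (1 - 0.5))
  expect_equal(f$adjusted_residual["AAA", "AAA"], d11)
  expect_equal(sign(f$adjusted_residual["AAA", "AAA"]), 1)
  expect_equal(sign(f$adjusted_residual["AAA", "TTT"]), -1)
  expect_equal(sign(f$adjusted_residual["TTT", "AAA"]), -1)
  expect_equal(sign(f$adjusted_residual["TTT", "TTT"]), 1)
  # expected margins reproduce observed margins
  keep <- rowSums(f$count) > 0
  expect_equal(rowSums(f$expected)[keep], rowSums(f$count)[keep])
})

test_that("exact independence yields zero residuals and ns calls", {
  m <- codon_pair_counts(list())
  for (a in c("AAA", "TTT")) for (b in c("AAA", "TTT"))
    m$count[a, b] <- 5L
  m$total_pairs <- 20L
  f <- context_residuals(m)
  expect_equal(f$adjusted_residual["AAA", "AAA"], 0)
  expect_true(all(f$significant[c("AAA", "TTT"), c("AAA", "TTT")] == "ns"))
  expect_equal(f$significant["GGG", "GGG"], "absent")
})

test_that("degenerate one-row matrices are rejected", {
  m <- codon_pair_counts(list(rec_of(c("GTG", "GTG", "GTG"))))
  expect_error(context_residuals(m), "degenerate")
})

test_that("top pairs rank by count with lexicographic ties, RNA naming", {
  genes <- list(rec_of(rep("GTG", 6), "a"),          # GTG-GTG x5
                rec_of(c("AAA", "TTT", "AAA"), "b"),
                rec_of(c("CCC", "GGG"), "c"))
  m <- codon_pair_counts(genes)
  tp <- top_pairs(m, 3)
  expect_equal(tp$pair[1], "GUG-GUG")
  expect_equal(tp$aa_pair[1], "VV")
  expect_equal(tp$count[1], 5L)
  # ties at count 1 resolved lexicographically by 5' then 3'
  expect_equal(tp$pair[2:3], c("AAA-UUU", "CCC-GGG"))
  expect_equal(nrow(top_pairs(m, 0)), 0)
  expect_equal(nrow(top_pairs(m, 100)), m$distinct_pairs)
})

test_that("ranking is invariant under gene order permutation", {
  panel <- generate_panel(5, length_range = c(300, 450), seed = 52)
  t1 <- top_pairs(codon_pair_counts(panel), 10)
  t2 <- top_pairs(codon_pair_counts(rev(panel)), 10)
  expect_equal(t1, t2)
})

test_that("rare pairs group by the 5' amino acid", {
  m <- codon_pair_counts(list())
  m$count["CGT", "AAA"] <- 1L
  m$count["CGC", "AAA"] <- 1L
  m$total_pairs <- 2L
  rp <- rare_pairs_by_initial(m, max_count = 2)
  expect_equal(unname(rp[["R"]]), 2L)
  expect_length(rare_pairs_by_initial(m, max_count = 0), 0)
  # partition property: counts sum to the number of rare pairs
  panel <- generate_panel(6, length_range = c(300, 600), seed = 53)
  mm <- codon_pair_counts(panel)
  rp2 <- rare_pairs_by_initial(mm, max_count = 2)
  expect_equal(sum(rp2), sum(mm$count >= 1 & mm$count <= 2))
})

test_that("stop-initiated rare pairs are grouped under 'stop'", {
  m <- codon_pair_counts(list())
  m$count["TGA", "AAA"] <- 1L
  m$total_pairs <- 1L
  expect_equal(unname(rare_pairs_by_initial(m, 2)[["stop"]]), 1L)
})

test_that("i.i.d. panels produce few significant context calls", {
  panel <- generate_panel(100, length_range = c(1350, 1650), seed = 54)
  f <- context_residuals(codon_pair_counts(panel))
  ok <- f$significant != "absent"
  rate <- sum(f$significant %in% c("preferred", "rejected")) / sum(ok)
  expect_lte(rate, 0.005)
})
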