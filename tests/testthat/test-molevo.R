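test_that("backtranslation maps residues to codons and gaps to triplets", {
  out <- backtranslate_alignment(c(x = "M-K", y = "MSK"),
                                 c(x = "ATGAAA", y = "ATGTCTAAG"))
  expect_equal(unname(out["x"]), "ATG---AAA")
  expect_equal(unname(out["y"]), "ATGTCTAAG")
  # trailing stop is dropped
  out3 <- backtranslate_alignment(c(x = "MK", y = "MK"),
                                  c(x = "ATGAAATAA", y = "ATGAAG"))
  expect_equal(unname(out3["x"]), "ATGAAA")
  expect_error(backtranslate_alignment(c(x = "MK", y = "MK"),
                                       c(x = "ATGTAAAAA", y = "ATGAAG")),
               "internal stop")
  expect_error(backtranslate_alignment(c(x = "MK", y = "MK"),
                                       c(x = "ATGAA", y = "ATGAAG")),
               "not divisible by 3")
  expect_error(backtranslate_alignment(c(x = "MV", y = "MK"),
                                       c(x = "ATGAAA", y = "ATGAAG")),
               "mismatch at residue 2")
})

test_that("NG86 gives zero rates for identical sequences", {
  caln <- codon_alignment(c(a = "ATGAAACCC", b = "ATGAAACCC"))
  r <- ng86_kaks(caln)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$ratio)) # undefined, never infinite
})

test_that("NG86 matches the hand-enumerated toy oracle", {
  # expected values frozen from a manual site/pathway enumeration of the
  # 12-codon pair (S = 26/3, N = 82/3, Sd = 1, Nd = 1), independently
  # confirmed by a second implementation.
  r <- ng86_kaks(codon_alignment(toy_codon_pair()))
  expect_equal(r$syn_sites, 26 / 3, tolerance = 1e-12)
  expect_equal(r$nonsyn_sites, 82 / 3, tolerance = 1e-12)
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$nonsyn_diffs, 1)
  expect_equal(r$ks, -0.75 * log(1 - 4 / 3 * (3 / 26)), tolerance = 1e-12)
  expect_equal(r$ka, -0.75 * log(1 - 4 / 3 * (3 / 82)), tolerance = 1e-12)
  expect_equal(r$n_codons, 12L)
})

test_that("NG86 is symmetric and sites sum to 3 x compared codons", {
  pair <- toy_codon_pair()
  r1 <- ng86_kaks(codon_alignment(pair))
  r2 <- ng86_kaks(codon_alignment(pair[c(2, 1)]))
  expect_equal(r1$ka, r2$ka)
  expect_equal(r1$ks, r2$ks)
  set.seed(31)
  for (i in 1:5) {
    fam <- simulate_family(sim_config(seed = i, n_codons = 60,
                                      duplication_mya = 10))
    r <- ng86_kaks(codon_alignment(fam$cds))
    expect_equal(r$syn_sites + r$nonsyn_sites, 3 * r$n_codons,
                 tolerance = 1e-9)
  }
})

test_that("NG86 averages every minimal pathway on multi-hit codons", {
  # TTT (Phe) vs GAT (Asp) differ at positions 1 and 2; the two
  # pathways give (0 syn, 2 nonsyn) and (0, 2): hand enumeration
  # TTT->GTT(V)->GAT(D) and TTT->TAT(Y)->GAT(D), all nonsynonymous.
  r <- ng86_kaks(codon_alignment(c(a = "TTT", b = "GAT")))
  expect_equal(r$syn_diffs, 0)
  expect_equal(r$nonsyn_diffs, 2)
  # gapped-only pair is an error
  expect_error(ng86_kaks(codon_alignment(c(a = "---", b = "ATG"))),
               "no comparable codons")
})

test_that("Jukes-Cantor correction is flagged invalid at saturation", {
  # force ps >= 3/4 with a fully synonymous 4-fold scramble
  caln <- codon_alignment(c(a = paste(rep("GGA", 8), collapse = ""),
                            b = paste(rep(c("GGC", "GGG", "GGT"),
                                          length.out = 8), collapse = "")))
  r <- ng86_kaks(caln)
  expect_false(r$jc_valid[["ks"]])
  expect_true(is.na(r$ks))
})

test_that("the dating formula reproduces printed dates and is linear", {
  expect_equal(date_duplication(0.1177), 9.65)
  expect_equal(date_duplication(0.0909), 7.45)
  expect_equal(date_duplication(0), 0)
  expect_error(date_duplication(-0.1), "non-negative")
  ks <- c(0.05, 0.1, 0.2)
  t1 <- date_duplication(ks, digits = NULL)
  expect_equal(t1[3] / t1[1], 4) # linear in ks
  half_lam <- kaks_config(lam = SOYBEAN_LAMBDA / 2)
  expect_equal(date_duplication(ks, half_lam, digits = NULL), 2 * t1)
})

test_that("pair summaries reproduce the published table arithmetic", {
  pairs <- load_table2_fixture()
  s <- summarize_pairs(pairs, ratio_threshold = 0.3)
  expect_equal(round(s$ks_mean, 4), 0.1682)
  expect_equal(round(s$date_mean, 2), 13.78)
  expect_equal(s$segmental_ratio_below, 8L)
  expect_equal(s$segmental_ratio_at_or_above, 9L)
  expect_equal(s$tandem_ratio_at_or_above, 1L)
  # ratio column equals ka/ks at the printed rounding, every row
  expect_equal(round(pairs$ka / pairs$ks, 4), pairs$ratio)
  empty <- summarize_pairs(pairs[0, ])
  expect_equal(empty$n_pairs, 0L)
  expect_true(is.na(empty$ks_mean))
})

test_that("simulated pairs are recovered near their target Ks", {
  target <- 0.15
  est <- vapply(1:8, function(i) {
    fam <- simulate_family(sim_config(
      seed = 100 + i, n_codons = 500,
      duplication_mya = target / (2 * 6.1e-9) / 1e6))
    ng86_kaks(codon_alignment(fam$cds))$ks
  }, numeric(1))
  expect_lt(abs(mean(est) - target) / target, 0.15)
})
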