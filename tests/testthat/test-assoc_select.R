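# Hardy-Weinberg, ANOVA association, TagSNPs and marker-assisted selection.

test_that("HWE chi-square behaves at equilibrium and reports frequencies", {
  r <- hwe_test(c(25, 50, 25))
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$maf, 0.5)
  expect_equal(r$he, 0.5)
  expect_equal(r$ho, 0.5)
  expect_true(r$in_hwe)
  expect_equal(r$hom_minor + r$het + r$hom_major, r$n)

  # carrier frequencies are distinct from allele frequencies
  r2 <- hwe_test(c(15, 50, 45))
  expect_equal(r2$carrier_minor, 65 / 110, tolerance = 1e-12)
  expect_equal(r2$carrier_major, 95 / 110, tolerance = 1e-12)
  expect_equal(r2$maf, 80 / 220, tolerance = 1e-12)

  rm_ <- hwe_test(c(0, 0, 50))
  expect_true(is.na(rm_$chi2))
})

test_that("hwe_scan tests every locus of a genotype matrix", {
  dos <- rbind(c(2, 0), c(1, 1), c(0, 2), c(1, 1), c(0, 0))
  gm <- gm_from_dosage(dos, majors = c("G", "T"), minors = c("C", "A"))
  cat2 <- catalog_from_alleles(majors = c("G", "T"), minors = c("C", "A"))
  sc <- hwe_scan(gm, cat2)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$het, c(2, 2))
  expect_equal(sc$chi2[1],
               hwe_test(c(1, 2, 2))$chi2)
})

test_that("ANOVA association decomposes variance and handles edge cases", {
  # saturated case: within-class variance 0 -> R2 = 100
  g <- rep(c("AA", "Aa", "aa"), each = 2)
  y <- rep(c(1, 2, 3), each = 2)
  a <- suppressWarnings(anova_association(g, y))  # perfect fit: F unreliable
  expect_equal(a$r2_contribution, 100)

  # SS decomposition exact on random inputs
  set.seed(61)
  for (rep in 1:10) {
    g <- sample(c("CC", "CG", "GG"), 60, replace = TRUE)
    y <- rnorm(60)
    a <- anova_association(g, y)
    fit <- stats::lm(y ~ factor(g))
    expect_equal(a$r2_contribution, 100 * summary(fit)$r.squared, tolerance = 1e-10)
    expect_equal(a$f_stat, summary(fit)$fstatistic[["value"]], tolerance = 1e-10)
  }

  expect_warning(anova_association(c("AA", "AA", "AA", "Aa", "Aa", "aa"),
                                   c(1, 2, 3, 4, 5, 6)),
                 "size floor")
  # dropping leaves too few classes: warning then error
  expect_error(suppressWarnings(anova_association(c("AA", "AA", "AA", "Aa"),
                                                  c(1, 2, 3, 4))),
               "two usable")
  expect_error(anova_association(rep("AA", 6), rnorm(6)), "two usable")
  expect_error(suppressWarnings(anova_association(rep(c("AA", "Aa"), 3), rep(1, 6))),
               "zero total")
})

test_that("TagSNP selection orders by contribution rate and applies thresholds", {
  res <- data.frame(locus = c("CG615", "AT641", "AG3859"),
                    trait = "alpha_pinene_pct",
                    f_stat = c(10, 6, 7),
                    p_value = c(1e-4, 3e-3, 1e-3),
                    r2_contribution = c(15.548, 10.271, 11.445),
                    r2_adjusted = c(14, 9, 10), n = 110, n_classes = 3)
  sel <- select_tag_snps(res)
  expect_equal(sel$locus, c("CG615", "AG3859", "AT641"))

  res$r2_contribution <- c(9, 8, 7)
  expect_equal(nrow(select_tag_snps(res)), 0)

  # BH mode thresholds the adjusted p-values
  res2 <- data.frame(locus = letters[1:4], p_value = c(0.001, 0.04, 0.04, 0.04),
                     r2_contribution = c(20, 20, 20, 20))
  sel2 <- select_tag_snps(res2, multiple_testing = "bh")
  expect_true("p_adjusted" %in% names(sel2))
  expect_equal(sel2$p_adjusted[sel2$locus == "a"], 0.004)
})

test_that("combined genotype codes follow the AaBbCc convention", {
  dos <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 1, 0), c(NA, 0, 0))
  gm <- gm_from_dosage(dos, majors = c("G", "T", "G"), minors = c("C", "A", "A"),
                       positions = c(615, 641, 3859))
  cat3 <- catalog_from_alleles(majors = c("G", "T", "G"), minors = c("C", "A", "A"),
                               positions = c(615, 641, 3859))
  cc <- combine_genotypes(gm, cat3, tag_loci = c("AG3859", "CG615", "AT641"))
  expect_equal(attr(cc, "possible_combinations"), 27L)   # 3^3
  expect_equal(cc$code[1], "AABBCC")                     # hom-major everywhere
  expect_equal(cc$code[2], "AaBbCc")                     # het everywhere
  expect_equal(cc$code[3], "aaBbCC")
  expect_true(is.na(cc$code[4]))                         # missing tag call

  cc1 <- combine_genotypes(gm, cat3, tag_loci = "CG615")
  expect_equal(attr(cc1, "possible_combinations"), 3L)
})

test_that("MAS selection computes ratio, differential and realized gain", {
  # 110 trees; 2 carry the elite code
  codes <- data.frame(id = sprintf("t%03d", 1:110),
                      code = c(rep("AABBCC", 2), rep("AaBbCc", 108)))
  y <- c(44, 46, rnorm(108, 20, 4))
  traits <- data.frame(id = codes$id, alpha_pinene_pct = y)
  sel <- mas_select(codes, traits, "alpha_pinene_pct", scheme = "AABBCC")
  expect_equal(round(sel$selection_ratio, 2), 1.82)
  expect_equal(sel$n_selected, 2)
  expect_equal(sel$selection_differential, mean(y[1:2]) - mean(y), tolerance = 1e-12)
  expect_equal(sel$realized_gain_pct,
               100 * (mean(y[1:2]) - mean(y)) / mean(y), tolerance = 1e-12)

  # 12 of 110 -> 10.91%
  codes$code[3:12] <- "AABBCc"
  sel12 <- mas_select(codes, traits, "alpha_pinene_pct",
                      scheme = c("AABBCC", "AABBCc"))
  expect_equal(round(sel12$selection_ratio, 2), 10.91)

  # selecting everyone: differential and gain are exactly 0
  all_sel <- mas_select(codes, traits, "alpha_pinene_pct",
                        scheme = unique(codes$code))
  expect_equal(all_sel$selection_differential, 0, tolerance = 1e-12)
  expect_equal(all_sel$realized_gain_pct, 0, tolerance = 1e-12)

  # gain is invariant under trait rescaling; differential scales
  traits2 <- traits; traits2$alpha_pinene_pct <- y * 3.7
  sel_b <- mas_select(codes, traits2, "alpha_pinene_pct", scheme = "AABBCC")
  expect_equal(sel_b$realized_gain_pct, sel$realized_gain_pct, tolerance = 1e-10)
  expect_equal(sel_b$selection_differential, 3.7 * sel$selection_differential,
               tolerance = 1e-10)

  expect_error(mas_select(codes, traits, "alpha_pinene_pct", scheme = "aabbcc"),
               "empty selection")

  # trait_mean_threshold scheme selects high-mean classes
  sel_thr <- mas_select(codes, traits, "alpha_pinene_pct",
                        scheme = list(type = "trait_mean_threshold", min_mean = 40))
  expect_equal(sort(sel_thr$selected_ids)[1:2], c("t001", "t002"))
})

test_that("genotype summaries sort by mean and flag singletons", {
  codes <- data.frame(id = sprintf("t%02d", 1:9),
                      code = c(rep("AABBCC", 1), rep("AaBbCc", 5), rep("aabbcc", 3)))
  traits <- data.frame(id = codes$id,
                       alpha_pinene_pct = c(45, 21, 22, 20, 19, 23, 10, 11, 12))
  gs <- genotype_summary(codes, traits, "alpha_pinene_pct")
  expect_equal(gs$code, c("AABBCC", "AaBbCc", "aabbcc"))
  expect_true(gs$single_obs[1])
  expect_equal(gs$n, c(1L, 5L, 3L))

  one <- genotype_summary(data.frame(id = "a", code = "AA"),
                          data.frame(id = "a", alpha_pinene_pct = 5), "alpha_pinene_pct")
  expect_equal(nrow(one), 1)
  expect_error(genotype_summary(codes, data.frame(id = codes$id, alpha_pinene_pct = NA),
                                "alpha_pinene_pct"), "no usable")
})

test_that("null association keeps the type-I error near the nominal level", {
  set.seed(67)
  reps <- 300
  pvals <- replicate(reps, {
    g <- sample(c("CC", "CG", "GG"), 110, replace = TRUE, prob = c(0.36, 0.48, 0.16))
    suppressWarnings(anova_association(g, rnorm(110))$p_value)
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
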