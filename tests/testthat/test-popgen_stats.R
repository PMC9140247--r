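# Diversity and neutrality statistics against hand computations and
# brute-force oracles.

test_that("nucleotide diversity matches hand-computed and degenerate cases", {
  aln <- make_aln(c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT", "AAAAAAAATT"))
  # all 6 pairs: d = 1,2,2,1,1,0 -> mean 7/6; per site /10
  expect_equal(nucleotide_diversity(aln), (7 / 6) / 10, tolerance = 1e-12)
  expect_equal(mean_pairwise_differences(aln), 7 / 6, tolerance = 1e-12)

  expect_equal(nucleotide_diversity(make_aln(c("ACGT", "ACGT", "ACGT"))), 0)
  expect_equal(nucleotide_diversity(make_aln(c(strrep("A", 100),
                                               paste0(strrep("A", 99), "T")))), 0.01)
  expect_error(nucleotide_diversity(make_aln("ACGT")), "at least 2")
})

test_that("pi equals the brute-force pairwise oracle on random alignments", {
  set.seed(11)
  for (rep in 1:6) {
    aln <- random_aln(20, 50)
    expect_equal(nucleotide_diversity(aln), brute_pi(aln), tolerance = 1e-12)
  }
  # and with missing data, pairwise deletion with per-pair L
  mat <- random_aln(6, 20)$mat
  mat[cbind(c(1, 3, 5), c(2, 7, 19))] <- "N"
  alnN <- alignment_set(letters[1:6], mat)
  n <- 6; tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "N" & mat[j, ] != "N"
    tot <- tot + sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    np <- np + 1
  }
  expect_equal(nucleotide_diversity(alnN), tot / np, tolerance = 1e-12)
})

test_that("Watterson's theta follows S/(a1 L)", {
  expect_equal(watterson_theta(2, 4, 10), 2 / ((1 + 1/2 + 1/3) * 10), tolerance = 1e-12)
  expect_equal(round(watterson_theta(2, 4, 10), 5), 0.10909)
  expect_equal(watterson_theta(0, 4, 10), 0)
  expect_equal(watterson_theta(3, 2, 10), 3 / 10)  # n = 2: a1 = 1
})

test_that("haplotype diversity covers the closed-form and boundary cases", {
  expect_equal(haplotype_diversity(1, n = 4), 0)
  expect_equal(haplotype_diversity(c(0.5, 0.5), n = 4), (4 / 3) * 0.5, tolerance = 1e-12)
  expect_equal(haplotype_diversity(rep(1 / 7, 7), n = 7), 1, tolerance = 1e-12)
  expect_error(haplotype_diversity(c(0.6, 0.6), n = 4), "sum to 1")
  f <- haplotype_frequencies(make_aln(c("AT", "AT", "AA", "GG")))
  expect_equal(unname(f), c(0.5, 0.25, 0.25))
})

test_that("Tajima's D is zero at equality, signed like pi - S/a1, and matches the oracle", {
  n <- 4; S <- 2
  a1 <- 1 + 1/2 + 1/3
  expect_equal(tajimas_d(S, S / a1, n), 0, tolerance = 1e-12)
  d <- tajimas_d(S, 7 / 6, n)
  expect_gt(d, 0)  # 7/6 > 2/a1
  expect_equal(d, oracle_tajima_d(S, 7 / 6, n), tolerance = 1e-12)
  expect_true(is.na(tajimas_d(0, 0, 10)))

  set.seed(21)
  for (rep in 1:20) {
    n_r <- sample(4:150, 1); S_r <- sample(1:80, 1)
    k_r <- runif(1, 0, 2 * S_r)
    expect_equal(tajimas_d(S_r, k_r, n_r), oracle_tajima_d(S_r, k_r, n_r),
                 tolerance = 1e-10)
    expect_equal(sign(tajimas_d(S_r, k_r, n_r)), sign(k_r - S_r / sum(1 / (1:(n_r - 1)))))
  }

  # an excess of rare variants drives D negative: 50 haplotypes, all
  # mutations singletons
  seqs <- rep(strrep("A", 30), 50)
  for (i in 1:20) substr(seqs[i], i, i) <- "T"
  ns <- neutrality_summary(make_aln(seqs))
  expect_lt(ns$tajima_d, 0)
})

test_that("Fu & Li's D*/F* have the expected signs and match a literal transcription", {
  # no singletons but many mutations -> D* > 0
  seqs <- c(rep(strrep("A", 20), 5), rep(paste0(strrep("T", 10), strrep("A", 10)), 5))
  ns <- neutrality_summary(make_aln(seqs))
  expect_equal(ns$eta_s, 0)
  expect_gt(ns$fu_li_d_star, 0)

  # all singletons on n = 50 -> D* < 0
  seqs <- rep(strrep("A", 30), 50)
  for (i in 1:20) substr(seqs[i], i, i) <- "T"
  ns2 <- neutrality_summary(make_aln(seqs))
  expect_equal(ns2$eta_s, 20)
  expect_lt(ns2$fu_li_d_star, 0)

  for (n in c(5, 10, 25, 50, 110, 220)) {
    o <- oracle_fu_li_star(n, eta = 12, eta_s = 3, k_hat = 4.2)
    got <- fu_li_star(n, eta = 12, eta_s = 3, pi_total = 4.2)
    expect_equal(got$d_star, o$d_star, tolerance = 1e-12)
    expect_equal(got$f_star, o$f_star, tolerance = 1e-12)
  }
  expect_true(is.na(fu_li_star(10, 0, 0, 0)$d_star))
})

test_that("Fay & Wu's H evaluates the theta_pi - theta_H contrast", {
  # n = 4, two singleton derived sites: theta_pi = 1, theta_H = 1/3
  expect_equal(fay_wu_h(c(2, 0, 0), n = 4), 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(fay_wu_h(c(0, 0, 0), n = 4), 0)
  # low-frequency derived excess gives H > 0; high-frequency excess H < 0
  expect_gt(fay_wu_h(c(5, 0, 0), n = 4), 0)
  expect_lt(fay_wu_h(c(0, 0, 5), n = 4), 0)
  expect_error(fay_wu_h(c(1, 1), n = 4), "length")
})

test_that("the polarized spectrum uses the outgroup and sums to S", {
  seqs <- c("AATT", "AATA", "AACA", "AACA", "GATA")  # last row outgroup
  sp <- site_frequency_spectrum(make_aln(seqs), outgroup_row = 5)
  expect_true(sp$polarized)
  expect_equal(sum(sp$sfs), 2)  # col 1 unpolarizable? no: outgroup G not among {A}, monomorphic anyway
  ns <- neutrality_summary(make_aln(seqs), outgroup_row = 5)
  expect_equal(ns$n, 4)
  expect_false(is.na(ns$fay_wu_h))
  # fallback polarization warns
  expect_warning(neutrality_summary(make_aln(seqs[1:4]), ancestral_fallback = TRUE),
                 "ancestral")
})

test_that("Nei-Gojobori Ka/Ks behaves on planted coding differences", {
  m <- gene_model("cds", 90, data.frame(start = 1, end = 90))  # 30 codons
  base <- strrep("GGAACCATT", 10)  # Gly Thr Ile repeated, 30 codons
  aln_id <- make_aln(c(base, base))
  kk0 <- nei_gojobori_ka_ks(aln_id, m)
  expect_equal(kk0$ka, 0)
  expect_equal(kk0$ks, 0)
  expect_true(is.na(kk0$ka_ks))

  # one synonymous third-position change: GGA -> GGG
  alt <- base
  substr(alt, 3, 3) <- "G"
  kk1 <- nei_gojobori_ka_ks(make_aln(c(base, alt)), m)
  expect_gt(kk1$ks, 0)
  expect_equal(kk1$ka, 0)

  # add one nonsynonymous change: ACC -> GCC (Thr -> Ala) at codon 2
  alt2 <- alt
  substr(alt2, 4, 4) <- "G"
  kk2 <- nei_gojobori_ka_ks(make_aln(c(base, alt2)), m)
  # oracle: p_s = 1 / S_sites, p_n = 1 / N_sites with NG86 fractional sites,
  # then Jukes-Cantor; sites averaged over the pair
  syn_sites_of <- function(seq) {
    codons <- substring(seq, seq(1, 88, 3), seq(3, 90, 3))
    code <- Biostrings::GENETIC_CODE
    sum(vapply(codons, function(cd) {
      s <- 0
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        alt_cd <- cd; substr(alt_cd, p, p) <- b
        if (code[[alt_cd]] == code[[cd]]) s <- s + 1 / 3
      }
      s
    }, numeric(1)))
  }
  Ss <- (syn_sites_of(base) + syn_sites_of(alt2)) / 2
  Ns <- 90 - Ss
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  expect_equal(kk2$ks, jc(1 / Ss), tolerance = 1e-12)
  expect_equal(kk2$ka, jc(1 / Ns), tolerance = 1e-12)
  expect_equal(kk2$ka_ks, jc(1 / Ns) / jc(1 / Ss), tolerance = 1e-12)

  # pairwise averaging is symmetric in sequence order
  kk3 <- nei_gojobori_ka_ks(make_aln(c(alt2, base)), m)
  expect_equal(kk3$ka, kk2$ka, tolerance = 1e-14)
  expect_equal(kk3$ks, kk2$ks, tolerance = 1e-14)
})

test_that("Rm reproduces canonical four-gamete cases and the exhaustive oracle", {
  # the canonical four-gamete configuration over two sites
  aln4 <- make_aln(c("AA", "AT", "TA", "TT"))
  rs <- rm_four_gamete(aln4)
  expect_equal(rs$rm, 1L)
  expect_equal(nrow(rs$incompatible_pairs), 1)

  # no incompatible pair
  expect_equal(rm_four_gamete(make_aln(c("AA", "AT", "TT")))$rm, 0L)

  set.seed(31)
  for (rep in 1:12) {
    B <- matrix(sample(0:1, 8 * 12, replace = TRUE), 8, 12)
    seqs <- apply(B, 1, function(r) paste0(c("A", "T")[r + 1], collapse = ""))
    # keep only biallelic (polymorphic) columns for the oracle comparison
    poly <- apply(B, 2, function(x) length(unique(x)) == 2)
    got <- rm_four_gamete(make_aln(seqs, ids = sprintf("h%02d", 1:8)))$rm
    expect_equal(got, oracle_rm(B[, poly, drop = FALSE]))
  }

  # rm_per_snp uses the supplied informative-SNP denominator
  expect_equal(rm_four_gamete(aln4, n_snps = 59)$rm_per_snp, 1 / 59)
})
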