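# EM haplotype frequencies, pairwise LD, decay and blocks.

test_that("EM equals direct gamete counting when phase is unambiguous", {
  # {AABB x2, aabb x2}: no double heterozygote, phase known
  dos <- rbind(c(2, 2), c(2, 2), c(0, 0), c(0, 0))
  f <- em_haplotype_frequencies(dos)
  expect_equal(unname(f[c("11", "00")]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(f[c("01", "10")]), c(0, 0), tolerance = 1e-9)

  # any mix with <= 1 heterozygous locus per individual: EM = counting
  set.seed(5)
  for (rep in 1:5) {
    d <- cbind(sample(0:2, 40, replace = TRUE), 0L)
    d[, 2] <- ifelse(d[, 1] == 1, sample(c(0L, 2L), 40, replace = TRUE),
                     sample(0:2, 40, replace = TRUE))
    f2 <- em_haplotype_frequencies(d)
    # direct gamete counts: each individual contributes two resolvable gametes
    g <- matrix(0, 1, 4, dimnames = list(NULL, c("00", "01", "10", "11")))
    for (i in seq_len(nrow(d))) {
      x <- d[i, ]
      het <- which(x == 1)
      if (length(het) == 0) {
        h <- paste0(as.integer(x == 2), collapse = "")
        g[1, h] <- g[1, h] + 2
      } else {
        x1 <- x; x1[het] <- 0; x2 <- x; x2[het] <- 2
        g[1, paste0(as.integer(x1 == 2), collapse = "")] <-
          g[1, paste0(as.integer(x1 == 2), collapse = "")] + 1
        g[1, paste0(as.integer(x2 == 2), collapse = "")] <-
          g[1, paste0(as.integer(x2 == 2), collapse = "")] + 1
      }
    }
    expect_equal(as.numeric(f2[colnames(g)]), as.numeric(g / sum(g)), tolerance = 1e-7)
  }
})

test_that("EM handles a monomorphic locus and recovers planted pools", {
  dos <- cbind(c(0, 1, 2, 1, 0, 2), 0L)
  f <- em_haplotype_frequencies(dos)
  p_minor <- mean(dos[, 1]) / 2
  expect_equal(unname(f["10"]), p_minor, tolerance = 1e-9)
  expect_equal(unname(f["00"]), 1 - p_minor, tolerance = 1e-9)
  expect_equal(unname(f["01"] + f["11"]), 0, tolerance = 1e-9)

  # planted pool {11:0.4, 01:0.3, 10:0.2, 00:0.1}; mean estimate over
  # replicates approaches the truth
  set.seed(17)
  pool <- c("00" = 0.1, "01" = 0.3, "10" = 0.2, "11" = 0.4)
  est <- replicate(30, {
    d <- sample_pool_dosage(50, pool)
    em_haplotype_frequencies(d)[names(pool)]
  })
  expect_lt(max(abs(rowMeans(est) - pool)), 0.04)
})

test_that("EM log-likelihood is non-decreasing on random genotype inputs", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    d <- matrix(sample(0:2, 30 * k, replace = TRUE), 30, k)
    f <- em_haplotype_frequencies(d)
    ll <- attr(f, "loglik")
    expect_true(all(diff(ll) >= -1e-9))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
  expect_error(em_haplotype_frequencies(matrix(NA_integer_, 3, 2)), "complete cases")
  expect_error(em_haplotype_frequencies(matrix(0L, 3, 15)), "between 1 and 14")
})

test_that("pairwise LD reproduces complete-LD and hand-computed cases", {
  cat2 <- catalog_from_alleles(majors = c("A", "G"), minors = c("C", "T"))
  # perfectly correlated loci: individuals all AABB or aabb
  dos <- rbind(matrix(2, 5, 2), matrix(0, 5, 2))
  gm <- gm_from_dosage(dos, majors = c("A", "G"), minors = c("C", "T"))
  p <- pairwise_ld(gm, cat2, gm$loci[1], gm$loci[2])
  expect_equal(p$r2, 1, tolerance = 1e-6)
  expect_equal(p$d_prime, 1, tolerance = 1e-6)
  expect_equal(p$distance_bp, 100)
  # f(AB) = f(ab) = 0.5 with p = q = 0.5 -> d = 0.25, r2 = 1
  expect_equal(p$d, 0.25, tolerance = 1e-6)

  # independent loci in a large panel: r2 near 0
  set.seed(41)
  dosi <- cbind(rbinom(800, 2, 0.4), rbinom(800, 2, 0.3))
  gmi <- gm_from_dosage(dosi, majors = c("A", "G"), minors = c("C", "T"))
  pi_ld <- pairwise_ld(gmi, cat2, gmi$loci[1], gmi$loci[2])
  expect_lt(pi_ld$r2, 0.01)

  # monomorphic locus -> NA statistics
  dosm <- cbind(c(0, 1, 2, 1), c(0, 0, 0, 0))
  gmm <- gm_from_dosage(dosm, majors = c("A", "G"), minors = c("C", "T"))
  pm <- pairwise_ld(gmm, cat2, gmm$loci[1], gmm$loci[2])
  expect_true(is.na(pm$r2))
})

test_that("the LD matrix is symmetric, label-consistent and matches pairwise calls", {
  set.seed(43)
  dos <- matrix(rbinom(60 * 3, 2, 0.4), 60, 3)
  gm <- gm_from_dosage(dos, majors = c("A", "G", "T"), minors = c("C", "T", "A"))
  cat3 <- catalog_from_alleles(majors = c("A", "G", "T"), minors = c("C", "T", "A"))
  lm <- ld_matrix(gm, cat3)
  expect_equal(lm$r2, t(lm$r2))
  expect_equal(unname(diag(lm$r2)), rep(1, 3))
  for (r in seq_len(nrow(lm$pairs))) {
    pr <- lm$pairs[r, ]
    expect_equal(lm$r2[pr$locus_i, pr$locus_j],
                 pairwise_ld(gm, cat3, pr$locus_i, pr$locus_j)$r2)
  }
})

test_that("LD decay finds threshold crossings from binned means", {
  # two internally uniform blocks 1500 bp apart: within-block r2 high,
  # between-block low
  set.seed(47)
  hap_block <- rbinom(400, 1, 0.4)
  other <- rbinom(400, 1, 0.35)
  B <- cbind(hap_block, hap_block, hap_block, other, other, other)
  dos <- B[seq(1, 399, 2), ] + B[seq(2, 400, 2), ]
  pos6 <- c(100, 150, 200, 1600, 1650, 1700)
  gm <- gm_from_dosage(dos, majors = rep("A", 6), minors = rep("C", 6),
                       positions = pos6)
  cat6 <- catalog_from_alleles(majors = rep("A", 6), minors = rep("C", 6),
                               positions = pos6)
  lm <- ld_matrix(gm, cat6, loci = cat6$label)
  within <- lm$pairs$r2[lm$pairs$distance_bp < 500]
  between <- lm$pairs$r2[lm$pairs$distance_bp > 1000]
  expect_gt(mean(within), 0.9)
  expect_lt(mean(between), 0.1)
  dec <- ld_decay(lm$pairs, thresholds = c(0.2))
  expect_true(is.finite(dec$distance_bp))
  expect_gt(dec$distance_bp, 100)
  expect_lt(dec$distance_bp, 1600)

  # all pairs at r2 = 1: no crossing, reported beyond range (NA)
  flat <- data.frame(distance_bp = c(100, 500, 900), r2 = 1)
  expect_true(all(is.na(ld_decay(flat)$distance_bp)))
  # single bin: crossing undefined
  one <- data.frame(distance_bp = c(10, 20), r2 = c(0.9, 0.05))
  expect_true(is.na(ld_decay(one, thresholds = 0.2)$distance_bp))
  expect_error(ld_decay(flat, thresholds = 1.2), "inside")
})

test_that("block partitioning covers explicit, feature and r2-driven methods", {
  # explicit boundaries reproducing six blocks of 11,9,10,10,12,7 loci
  sizes <- c(11, 9, 10, 10, 12, 7)
  n_loci <- sum(sizes)
  cat59 <- snp_catalog(data.frame(position = seq_len(n_loci) * 10, major = "G",
                                  minor = "C", maf = 0.3))
  bounds <- split(cat59$label, rep(seq_along(sizes), sizes))
  blocks <- partition_blocks(cat59, method = "explicit", boundaries = bounds)
  expect_equal(vapply(blocks, function(b) length(b$loci), integer(1)), sizes)
  expect_error(partition_blocks(cat59, method = "explicit",
                                boundaries = bounds[-1]), "cover")

  # r2_contiguous splits two uncorrelated clusters
  set.seed(53)
  h1 <- rbinom(300, 1, 0.5); h2 <- rbinom(300, 1, 0.5)
  B <- cbind(h1, h1, h2, h2)
  dos <- B[seq(1, 299, 2), ] + B[seq(2, 300, 2), ]
  gm <- gm_from_dosage(dos, majors = rep("A", 4), minors = rep("C", 4))
  cat4 <- catalog_from_alleles(majors = rep("A", 4), minors = rep("C", 4))
  blk <- partition_blocks(cat4, gm, method = "r2_contiguous", r2_min = 0.5)
  expect_equal(length(blk), 2)
  expect_equal(blk[[1]]$loci, cat4$label[1:2])

  # single locus under the feature method
  m <- gene_model("g", 300, data.frame(start = 101, end = 103))
  cat1 <- snp_catalog(data.frame(position = 102, major = "G", minor = "C", maf = 0.3))
  blk1 <- partition_blocks(cat1, method = "feature", model = m)
  expect_equal(length(blk1), 1)
  expect_equal(blk1[[1]]$loci, cat1$label)
})

test_that("block haplotypes report frequencies and dominant calls", {
  cat2 <- catalog_from_alleles(majors = c("A", "G"), minors = c("C", "T"))
  # everyone homozygous for one haplotype
  gm_hom <- gm_from_dosage(matrix(2, 6, 2), majors = c("A", "G"), minors = c("C", "T"))
  blk <- list(name = "b1", region_label = NA, loci = gm_hom$loci)
  hb <- block_haplotypes(blk, gm_hom, cat2)
  expect_equal(nrow(hb$haplotypes), 1)
  expect_equal(hb$haplotypes$frequency, 1)
  expect_true(hb$haplotypes$dominant)
  expect_equal(hb$haplotypes$haplotype, "CT")

  # planted pool 0.40/0.35/0.25 -> all three dominant; a 0.15 haplotype is
  # listed but not dominant
  set.seed(59)
  pool <- c("00" = 0.40, "11" = 0.35, "10" = 0.25)
  d <- sample_pool_dosage(300, pool)
  gm3 <- gm_from_dosage(d, majors = c("A", "G"), minors = c("C", "T"))
  hb3 <- block_haplotypes(list(name = "b", region_label = NA, loci = gm3$loci),
                          gm3, cat2)
  dom <- hb3$haplotypes$haplotype[hb3$haplotypes$dominant]
  expect_setequal(dom, c("AG", "CT", "CG"))

  pool2 <- c("00" = 0.85, "11" = 0.15)
  d2 <- sample_pool_dosage(400, pool2)
  gm4 <- gm_from_dosage(d2, majors = c("A", "G"), minors = c("C", "T"))
  hb4 <- block_haplotypes(list(name = "b", region_label = NA, loci = gm4$loci),
                          gm4, cat2)
  row15 <- hb4$haplotypes[hb4$haplotypes$haplotype == "CT", ]
  expect_equal(nrow(row15), 1)
  expect_false(row15$dominant)
})
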