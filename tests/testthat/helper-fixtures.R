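# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately naive (brute force / literal formula transcriptions) and
# never share code with the implementation they check.

make_aln <- function(seqs, ids = sprintf("s%02d", seq_along(seqs)),
                     is_haplotype = TRUE) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  alignment_set(ids, mat, is_haplotype = is_haplotype)
}

random_aln <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  mat <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  alignment_set(sprintf("r%03d", seq_len(n)), mat)
}

# brute-force mean pairwise difference per site over all pairs
brute_pi <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat); L <- ncol(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / (n * (n - 1) / 2) / L
}

# exhaustive minimum number of inter-site breakpoints hitting every
# four-gamete-incompatible interval of a 0/1 haplotype matrix
oracle_rm <- function(B) {
  S <- ncol(B)
  ints <- list()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    if (length(unique(B[, i] * 2 + B[, j])) == 4) ints <- c(ints, list(c(i, j)))
  }
  if (!length(ints)) return(0L)
  gaps <- seq_len(S - 1)  # breakpoint g sits between sites g and g+1
  hits <- function(set) all(vapply(ints, function(iv)
    any(set >= iv[1] & set <= iv[2] - 1), logical(1)))
  for (k in seq_along(gaps)) {
    combs <- utils::combn(gaps, k, simplify = FALSE)
    if (any(vapply(combs, hits, logical(1)))) return(k)
  }
  length(gaps)
}

# literal transcription of the Tajima (1989) test, kept independent of the
# package internals
oracle_tajima_d <- function(S, k_hat, n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# literal transcription of Fu & Li's starred statistics (corrected
# variance constants), written from the published formulas
oracle_fu_li_star <- function(n, eta, eta_s, k_hat) {
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 + 2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn - 2 * (n * an * (an + 1)) / (n - 1)^2) /
    (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  Ds <- (n / (n - 1) * eta - an * eta_s) / sqrt(uDs * eta + vDs * eta^2)
  vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
            2 / (n - 1) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vFs
  Fs <- (k_hat - (n - 1) / n * eta_s) / sqrt(uFs * eta + vFs * eta^2)
  list(d_star = Ds, f_star = Fs)
}

# diploid dosage panel sampled from a known two-locus haplotype pool
sample_pool_dosage <- function(n, pool_freq) {
  # pool_freq named by bit strings "00","01","10","11" (locus1, locus2)
  haps <- names(pool_freq)
  draw <- function() {
    h <- sample(haps, 2, replace = TRUE, prob = pool_freq)
    b <- do.call(rbind, strsplit(h, ""))
    as.integer(b[1, ]) + as.integer(b[2, ])
  }
  t(vapply(seq_len(n), function(i) draw(), integer(2)))
}

# tiny genotype-matrix builder from dosage + allele pair per locus
gm_from_dosage <- function(dos, majors, minors,
                           positions = seq_len(ncol(dos)) * 100,
                           ids = sprintf("t%03d", seq_len(nrow(dos)))) {
  k <- ncol(dos)
  a1 <- matrix(NA_character_, nrow(dos), k)
  a2 <- a1
  for (j in seq_len(k)) {
    a1[, j] <- ifelse(is.na(dos[, j]), NA,
                      ifelse(dos[, j] >= 1, minors[j], majors[j]))
    a2[, j] <- ifelse(is.na(dos[, j]), NA,
                      ifelse(dos[, j] == 2, minors[j], majors[j]))
  }
  genotype_matrix(ids, paste0(minors, majors, positions), a1, a2)
}

catalog_from_alleles <- function(majors, minors, positions = seq_along(majors) * 100,
                                 maf = rep(0.3, length(majors))) {
  snp_catalog(data.frame(position = positions, major = majors, minor = minors,
                         maf = maf))
}
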