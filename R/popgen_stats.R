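# Sequence-based diversity, neutrality and recombination statistics.
# All public diversities are reported per site; internal computations that
# need totals (Tajima's D, Fu & Li) use mean pairwise differences per
# alignment.

check_haplotypes <- function(aln, min_n = 2) {
  if (!aln$is_haplotype) stop("haplotype alignment required (is_haplotype = TRUE)")
  if (any(aln$mat %in% IUPAC_HET)) stop("ambiguity codes not allowed in haplotype alignments")
  if (n_seq(aln) < min_n) stop("need at least ", min_n, " haplotypes")
  invisible(aln)
}

# Per-column allele counts over A/C/G/T (N = missing, gaps forbidden).
column_counts <- function(mat) {
  sapply(NUC, function(b) colSums(mat == b))  # L x 4
}

# Sum over unordered pairs of per-column mismatches, plus per-column called n.
column_pair_stats <- function(mat) {
  cc <- column_counts(mat)
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1, dimnames = list(NULL, NUC))
  n_called <- rowSums(cc)
  contrib <- (n_called^2 - rowSums(cc^2)) / 2   # sum_{a<b} n_a n_b
  list(contrib = contrib, n_called = n_called, counts = cc)
}

#' Nucleotide diversity (pi) per site
#'
#' Average proportion of differing sites over all haplotype pairs. With
#' missing data (`N`) each pair is compared over its shared called sites
#' (pairwise deletion with per-pair length).
#'
#' @param aln haplotype [alignment_set()] without gaps.
#' @param site_mask optional logical or integer vector selecting alignment
#'   columns to analyze.
#' @return pi per site (numeric scalar).
#' @export
nucleotide_diversity <- function(aln, site_mask = NULL) {
  pi_stats(aln, site_mask)$pi_per_site
}

#' Mean number of pairwise differences (total, not per site)
#'
#' @inheritParams nucleotide_diversity
#' @return mean pairwise difference count k (the quantity entering Tajima's
#'   D and Fu & Li's F*).
#' @export
mean_pairwise_differences <- function(aln, site_mask = NULL) {
  pi_stats(aln, site_mask)$pi_total
}

pi_stats <- function(aln, site_mask = NULL) {
  check_haplotypes(aln)
  mat <- aln$mat
  if (!is.null(site_mask)) mat <- mat[, site_mask, drop = FALSE]
  if (any(mat == "-")) stop("strip indel columns before computing diversity")
  n <- nrow(mat); L <- ncol(mat)
  if (!any(mat == "N")) {
    st <- column_pair_stats(mat)
    npairs <- n * (n - 1) / 2
    tot <- sum(st$contrib)
    return(list(pi_per_site = tot / (npairs * L), pi_total = tot / npairs, L = L))
  }
  # exact pairwise route under missing data
  d <- 0; dps <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "N" & mat[j, ] != "N"
    Lij <- sum(ok)
    if (Lij == 0) next
    dij <- sum(mat[i, ok] != mat[j, ok])
    d <- d + dij
    dps <- dps + dij / Lij
    npairs <- npairs + 1
  }
  if (npairs == 0) stop("no comparable pairs")
  list(pi_per_site = dps / npairs, pi_total = d / npairs, L = L)
}

#' Watterson's theta per site
#'
#' `theta_w = S / (a1 * L)` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes.
#' @param L number of analyzed sites.
#' @return theta per site.
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(n >= 2, L >= 1)
  S / (harmonic(n - 1) * L)
}

harmonic <- function(m) if (m < 1) 0 else sum(1 / seq_len(m))
harmonic2 <- function(m) if (m < 1) 0 else sum(1 / seq_len(m)^2)

#' Haplotype (gene) diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` from haplotype frequencies.
#'
#' @param freqs haplotype relative frequencies (must sum to 1).
#' @param n number of haplotypes sampled.
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(freqs, n) {
  if (n < 2) stop("need n >= 2")
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  (n / (n - 1)) * (1 - sum(freqs^2))
}

#' Haplotype frequencies of an alignment
#'
#' Collapses identical rows; rows containing `N` are dropped.
#'
#' @param aln haplotype [alignment_set()].
#' @return named numeric vector of relative frequencies (descending).
#' @export
haplotype_frequencies <- function(aln) {
  check_haplotypes(aln)
  seqs <- apply(aln$mat, 1, paste0, collapse = "")
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  tab <- sort(table(seqs), decreasing = TRUE)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

# ---------------------------------------------------------------------------
# Neutrality tests

tajima_constants <- function(n) {
  a1 <- harmonic(n - 1)
  a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between the mean-pairwise-difference and
#' segregating-site estimators of theta; zero in expectation under the
#' standard neutral model.
#'
#' @param S segregating sites (must be >= 1; `NA` returned for S = 0).
#' @param pi_total mean pairwise differences per alignment (not per site),
#'   see [mean_pairwise_differences()].
#' @param n number of haplotypes.
#' @return D, or `NA_real_` when undefined (S = 0).
#' @export
tajimas_d <- function(S, pi_total, n) {
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

fu_li_constants <- function(n) {
  a_n <- harmonic(n - 1)
  b_n <- harmonic2(n - 1)
  a_n1 <- harmonic(n)
  c_n <- if (n == 2) 1 else 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  d_n <- c_n + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * a_n1 - 3) / (n - 2) - 1 / n)
  v_ds <- ((n / (n - 1))^2 * b_n + a_n^2 * d_n -
             2 * n * a_n * (a_n + 1) / (n - 1)^2) / (a_n^2 + b_n)
  u_ds <- (n / (n - 1)) * (a_n - n / (n - 1)) - v_ds
  v_fs <- (d_n + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
             (2 / (n - 1)) * (4 * b_n - 6 + 8 / n)) / (a_n^2 + b_n)
  u_fs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
             2 * (n + 1) / (n - 1)^2 * (a_n1 - 2 * n / (n + 1))) / a_n - v_fs
  list(a_n = a_n, b_n = b_n, c_n = c_n, d_n = d_n,
       u_ds = u_ds, v_ds = v_ds, u_fs = u_fs, v_fs = v_fs)
}

#' Fu & Li's D* and F* (no outgroup)
#'
#' Contrast singleton mutations (present in exactly one haplotype) with the
#' total mutation count, using the within-sample forms that do not require
#' ancestral-state polarization.
#'
#' @param n number of haplotypes (> 2).
#' @param eta total number of mutations.
#' @param eta_s number of singleton mutations.
#' @param pi_total mean pairwise differences (used by F*).
#' @return list with `d_star` and `f_star` (`NA` when eta = 0).
#' @export
fu_li_star <- function(n, eta, eta_s, pi_total) {
  if (eta == 0) return(list(d_star = NA_real_, f_star = NA_real_))
  if (n <= 2) stop("Fu & Li's starred statistics need n > 2")
  k <- fu_li_constants(n)
  d_star <- ((n / (n - 1)) * eta - k$a_n * eta_s) /
    sqrt(k$u_ds * eta + k$v_ds * eta^2)
  f_star <- (pi_total - ((n - 1) / n) * eta_s) /
    sqrt(k$u_fs * eta + k$v_fs * eta^2)
  list(d_star = d_star, f_star = f_star)
}

#' Fay & Wu's H
#'
#' `H = theta_pi - theta_H` computed from a polarized (derived-allele) site
#' frequency spectrum; sensitive to an excess of high-frequency derived
#' alleles.
#'
#' @param sfs numeric vector of length `n - 1`; `sfs[i]` = number of sites
#'   with derived-allele count i.
#' @param n number of haplotypes.
#' @return H (0 when no segregating sites).
#' @export
fay_wu_h <- function(sfs, n) {
  if (length(sfs) != n - 1) stop("sfs must have length n - 1")
  i <- seq_len(n - 1)
  theta_pi <- sum(2 * sfs * i * (n - i)) / (n * (n - 1))
  theta_h <- sum(2 * sfs * i^2) / (n * (n - 1))
  theta_pi - theta_h
}

#' Site frequency spectrum of a haplotype alignment
#'
#' Restricted to biallelic sites. With an outgroup row the spectrum is
#' polarized (derived-allele counts, the outgroup excluded from the counts
#' and sites where the outgroup carries neither allele skipped); without
#' one the folded (minor-allele) spectrum is returned.
#'
#' @param aln haplotype [alignment_set()].
#' @param outgroup_row row index or id of an outgroup sequence, or `NULL`.
#' @return list with `sfs` (length n-1 counts), `polarized`, `n`,
#'   `n_skipped` (sites unpolarizable by the outgroup).
#' @export
site_frequency_spectrum <- function(aln, outgroup_row = NULL) {
  check_haplotypes(aln)
  if (is.character(outgroup_row)) outgroup_row <- match(outgroup_row, aln$ids)
  mat <- aln$mat
  og <- NULL
  if (!is.null(outgroup_row)) {
    og <- mat[outgroup_row, ]
    mat <- mat[-outgroup_row, , drop = FALSE]
  }
  n <- nrow(mat)
  sfs <- numeric(n - 1)
  n_skipped <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]; col <- col[col != "N"]
    cnt <- table(col)
    cnt <- cnt[cnt > 0]
    if (length(cnt) != 2) next
    if (is.null(og)) {
      i <- min(cnt)
    } else {
      anc <- og[j]
      if (!anc %in% names(cnt)) { n_skipped <- n_skipped + 1L; next }
      i <- sum(cnt[names(cnt) != anc])
    }
    if (i >= 1 && i <= n - 1) sfs[i] <- sfs[i] + 1
  }
  list(sfs = sfs, polarized = !is.null(og), n = n, n_skipped = n_skipped)
}

#' Neutrality-test summary for a haplotype alignment
#'
#' Computes segregating sites, total and singleton mutation counts, mean
#' pairwise differences, Tajima's D, Fu & Li's D*/F* and (when ancestral
#' states are available) Fay & Wu's H. Multiallelic columns are excluded
#' throughout. Without an outgroup, H is only computed when
#' `ancestral_fallback = TRUE`, which treats the major allele as ancestral
#' and emits a prominent warning.
#'
#' @param aln haplotype [alignment_set()].
#' @param outgroup_row optional outgroup row (index or id) used to polarize
#'   the spectrum; the outgroup is excluded from all statistics.
#' @param ancestral_fallback use major-allele-as-ancestral polarization for
#'   Fay & Wu's H when no outgroup is given.
#' @return list of class `neutrality_summary`.
#' @export
neutrality_summary <- function(aln, outgroup_row = NULL, ancestral_fallback = FALSE) {
  check_haplotypes(aln, min_n = 3)
  sp <- site_frequency_spectrum(aln, outgroup_row)
  ingroup <- if (is.null(outgroup_row)) aln else {
    r <- if (is.character(outgroup_row)) match(outgroup_row, aln$ids) else outgroup_row
    alignment_set(aln$ids[-r], aln$mat[-r, , drop = FALSE], TRUE, aln$ref_positions)
  }
  n <- sp$n
  sfs <- sp$sfs
  S <- sum(sfs)
  eta <- S                      # biallelic sites contribute one mutation each
  eta_s <- if (sp$polarized) sfs[1] else sfs[1]  # count-1 mutations
  pi_total <- mean_pairwise_differences(ingroup)
  d <- tajimas_d(S, pi_total, n)
  fl <- if (S > 0) fu_li_star(n, eta, eta_s, pi_total)
        else list(d_star = NA_real_, f_star = NA_real_)
  h <- NA_real_
  polarized <- sp$polarized
  if (polarized) {
    h <- fay_wu_h(sfs, n)
  } else if (ancestral_fallback) {
    warning("Fay & Wu's H polarized by major-allele-as-ancestral fallback; ",
            "supply an outgroup for a defensible H")
    h <- fay_wu_h(sfs, n)
    polarized <- FALSE
  }
  structure(list(n = n, S = S, eta = eta, eta_s = eta_s,
                 pi_total = pi_total, tajima_d = d,
                 fu_li_d_star = fl$d_star, fu_li_f_star = fl$f_star,
                 fay_wu_h = h, sfs = sfs, polarized = polarized),
            class = "neutrality_summary")
}

# ---------------------------------------------------------------------------
# Nei-Gojobori Ka/Ks

codon_table_cache <- new.env(parent = emptyenv())

translate1 <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# fraction of synonymous sites per codon (NG86: each position contributes
# the fraction of its three possible changes that are synonymous)
codon_syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  if (!is.null(codon_table_cache[[key]])) return(codon_table_cache[[key]])
  aa <- translate1(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(NUC, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (identical(translate1(alt), aa)) s <- s + 1 / 3
    }
  }
  codon_table_cache[[key]] <- s
  s
}

# average synonymous/nonsynonymous difference counts between two codons over
# all mutational pathways (stop codons treated as a distinct residue, so
# steps to or from a stop count as nonsynonymous)
codon_path_diffs <- function(c1, c2) {
  key <- paste0("d_", c1, "_", c2)
  if (!is.null(codon_table_cache[[key]])) return(codon_table_cache[[key]])
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- if (length(pos) == 0) c(sd = 0, nd = 0) else {
    perms <- if (length(pos) == 1) list(pos) else
      apply(permutations(length(pos)), 1, function(o) pos[o], simplify = FALSE)
    acc <- c(0, 0)
    for (ord in perms) {
      cur <- c1; sdv <- 0; ndv <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (identical(translate1(cur), translate1(nxt))) sdv <- sdv + 1 else ndv <- ndv + 1
        cur <- nxt
      }
      acc <- acc + c(sdv, ndv)
    }
    acc <- acc / length(perms)
    c(sd = acc[1], nd = acc[2])
  }
  codon_table_cache[[key]] <- res
  res
}

permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' `d = -(3/4) log(1 - (4/3) p)`; undefined (`NA`) for `p >= 3/4`.
#'
#' @param p proportion of differing sites.
#' @return corrected distance.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori Ka and Ks for a coding haplotype alignment
#'
#' Synonymous and nonsynonymous sites are counted per sequence with the
#' NG86 fractional-site rule and averaged per pair; differences are
#' apportioned by averaging over all mutational pathways per codon.
#' Proportions are averaged over all sequence pairs and Jukes-Cantor
#' corrected. `ka_ks` is `NA` when `ks` is 0 or a correction is undefined.
#'
#' @param aln haplotype [alignment_set()] covering the gene; the CDS is
#'   extracted through `model`. Codons with alignment columns removed as
#'   indels are dropped with a warning.
#' @param model a [gene_model()].
#' @return list with `ka`, `ks`, `ka_ks`, mean proportions `p_n`, `p_s`,
#'   and the mean site counts `n_sites`, `s_sites`, `n_codons`.
#' @export
nei_gojobori_ka_ks <- function(aln, model) {
  check_haplotypes(aln)
  cpos <- cds_positions(model)
  cols <- match(cpos, aln$ref_positions)
  codon_ids <- rep(seq_len(length(cpos) / 3), each = 3)
  bad_codons <- unique(codon_ids[is.na(cols)])
  if (length(bad_codons)) {
    warning(length(bad_codons), " codon(s) dropped: columns removed from alignment")
    keep <- !(codon_ids %in% bad_codons)
    cols <- cols[keep]
  }
  M <- aln$mat[, cols, drop = FALSE]
  if (any(M == "N")) stop("missing bases (N) in CDS not supported")
  n <- nrow(M); Lc <- ncol(M); nc <- Lc / 3
  i1 <- seq(1, Lc, 3)
  codons <- matrix(paste0(M[, i1], M[, i1 + 1], M[, i1 + 2]), nrow = n)
  if (nc > 1 && any(codons[1, -nc] %in% c("TAA", "TAG", "TGA")))
    warning("premature stop codon in reference sequence")
  s_per_seq <- apply(codons, 1, function(row) sum(vapply(row, codon_syn_sites, numeric(1))))
  n_per_seq <- 3 * nc - s_per_seq
  poly <- which(apply(codons, 2, function(x) length(unique(x)) > 1))
  sum_ps <- 0; sum_pn <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    Ssites <- (s_per_seq[i] + s_per_seq[j]) / 2
    Nsites <- (n_per_seq[i] + n_per_seq[j]) / 2
    sd <- 0; nd <- 0
    for (k in poly) {
      if (codons[i, k] != codons[j, k]) {
        dd <- codon_path_diffs(codons[i, k], codons[j, k])
        sd <- sd + dd[["sd"]]; nd <- nd + dd[["nd"]]
      }
    }
    sum_ps <- sum_ps + sd / Ssites
    sum_pn <- sum_pn + nd / Nsites
    npairs <- npairs + 1
  }
  p_s <- sum_ps / npairs; p_n <- sum_pn / npairs
  ks <- jukes_cantor(p_s); ka <- jukes_cantor(p_n)
  ka_ks <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ka_ks = ka_ks, p_n = p_n, p_s = p_s,
       n_sites = mean(n_per_seq), s_sites = mean(s_per_seq), n_codons = nc)
}

# ---------------------------------------------------------------------------
# Minimum recombination (Hudson-Kaplan)

#' Minimum number of recombination events (four-gamete test)
#'
#' A site pair is incompatible when all four gametes are observed among
#' haplotypes called at both sites. Rm is the Hudson-Kaplan bound: the
#' minimum number of inter-site breakpoints needed to hit every
#' incompatible interval, obtained by the greedy leftmost-right-endpoint
#' scan.
#'
#' @param aln haplotype [alignment_set()]; only biallelic sites are used.
#' @param n_snps denominator for `rm_per_snp` (defaults to the number of
#'   biallelic sites analyzed); pass the informative-SNP count to mirror
#'   Rm-per-informative-SNP reporting.
#' @return list of class `recombination_summary` with `rm`, `rm_per_snp`
#'   and `incompatible_pairs` (data.frame of site positions).
#' @export
rm_four_gamete <- function(aln, n_snps = NULL) {
  check_haplotypes(aln)
  cat <- call_snps(aln)
  S <- nrow(cat)
  if (is.null(n_snps)) n_snps <- S
  if (S < 2) {
    return(structure(list(rm = 0L, rm_per_snp = 0,
                          incompatible_pairs = data.frame(pos_i = integer(), pos_j = integer())),
                     class = "recombination_summary"))
  }
  cols <- match(cat$position, aln$ref_positions)
  B <- matrix(NA_integer_, n_seq(aln), S)
  for (s in seq_len(S)) {
    col <- aln$mat[, cols[s]]
    B[, s] <- ifelse(col == "N", NA_integer_, as.integer(col == cat$minor[s]))
  }
  inc_i <- integer(); inc_j <- integer()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    ok <- !is.na(B[, i]) & !is.na(B[, j])
    g <- unique(B[ok, i] * 2L + B[ok, j])
    if (length(g) == 4) { inc_i <- c(inc_i, i); inc_j <- c(inc_j, j) }
  }
  rm <- rm_from_intervals(inc_i, inc_j)
  structure(list(rm = rm, rm_per_snp = rm / n_snps,
                 incompatible_pairs = data.frame(pos_i = cat$position[inc_i],
                                                 pos_j = cat$position[inc_j])),
            class = "recombination_summary")
}

# greedy minimum stabbing of open intervals (i, j): sort by right end; a new
# breakpoint is needed whenever the next interval starts at or after the
# last stabbed right end
rm_from_intervals <- function(i, j) {
  if (!length(i)) return(0L)
  ord <- order(j, i)
  i <- i[ord]; j <- j[ord]
  count <- 0L; last <- -Inf
  for (k in seq_along(i)) {
    if (i[k] >= last) { count <- count + 1L; last <- j[k] }
  }
  count
}

# ---------------------------------------------------------------------------
# Assembled diversity summary

#' Diversity summary for a haplotype alignment
#'
#' Computes n, analyzed length, segregating sites, pi, Watterson's theta and
#' haplotype diversity; with a gene model (and a functionally classified
#' catalog) also per-site diversities over silent / synonymous /
#' nonsynonymous site classes and Nei-Gojobori Ka/Ks. Site-class
#' denominators use the NG86 fractional site counts of the reference
#' sequence for coding classes and the noncoding length for silent sites.
#'
#' @param aln haplotype [alignment_set()] (gap-free).
#' @param model optional [gene_model()].
#' @param catalog optional classified [snp_catalog()] (see
#'   [classify_functional()]); required for site-class diversities.
#' @param reference_row sequence supplying the reference CDS.
#' @return list of class `diversity_summary`.
#' @export
diversity_summary <- function(aln, model = NULL, catalog = NULL, reference_row = 1) {
  check_haplotypes(aln)
  st <- column_pair_stats(aln$mat)
  n <- n_seq(aln); L <- n_col(aln)
  nal <- rowSums(st$counts > 0)
  S <- sum(nal >= 2)
  ps <- pi_stats(aln)
  hf <- haplotype_frequencies(aln)
  out <- list(n = n, L = L, S = S,
              pi = ps$pi_per_site,
              theta_w = watterson_theta(S, n, L),
              hd = haplotype_diversity(hf, n))
  if (!is.null(model) && !is.null(catalog)) {
    if (any(is.na(catalog$functional_class))) stop("catalog must be functionally classified")
    percol <- st$contrib / (st$n_called * (st$n_called - 1) / 2)
    col_of <- match(catalog$position, aln$ref_positions)
    cpos <- cds_positions(model)
    coding_cols <- !is.na(match(aln$ref_positions, cpos))
    refrow <- if (is.character(reference_row)) match(reference_row, aln$ids) else reference_row
    ref_cds_cols <- match(cpos, aln$ref_positions)
    ref_cds_cols <- ref_cds_cols[!is.na(ref_cds_cols)]
    ref_cds <- aln$mat[refrow, ref_cds_cols]
    nc_full <- length(ref_cds) %/% 3
    codons <- paste0(ref_cds[seq(1, 3 * nc_full, 3)],
                     ref_cds[seq(2, 3 * nc_full, 3)],
                     ref_cds[seq(3, 3 * nc_full, 3)])
    L_syn <- sum(vapply(codons, codon_syn_sites, numeric(1)))
    L_nonsyn <- 3 * nc_full - L_syn
    L_noncoding <- sum(!coding_cols)
    syn_cols <- col_of[catalog$functional_class == "synonymous"]
    nonsyn_cols <- col_of[catalog$functional_class == "nonsynonymous"]
    sum_syn <- sum(percol[syn_cols])
    sum_nonsyn <- sum(percol[nonsyn_cols])
    sum_noncoding <- sum(percol[!coding_cols])
    out$pi_synonymous <- if (L_syn > 0) sum_syn / L_syn else NA_real_
    out$pi_nonsynonymous <- if (L_nonsyn > 0) sum_nonsyn / L_nonsyn else NA_real_
    out$pi_silent <- if (L_syn + L_noncoding > 0)
      (sum_syn + sum_noncoding) / (L_syn + L_noncoding) else NA_real_
    kk <- nei_gojobori_ka_ks(aln, model)
    out$ka <- kk$ka; out$ks <- kk$ks; out$ka_ks <- kk$ka_ks
  }
  structure(out, class = "diversity_summary")
}
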