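# Hardy-Weinberg tests, single-marker ANOVA association with contribution
# R2, TagSNP selection and genotype-combination marker-assisted selection.

#' Hardy-Weinberg equilibrium chi-square test for one locus
#'
#' Allele frequencies are taken from the genotype counts; expected counts
#' are `n p^2, 2 n p q, n q^2`; the Pearson statistic is computed with no
#' continuity correction and referred to chi-square with one degree of
#' freedom. Expected heterozygosity is `He = 2pq`, observed `Ho = het / n`.
#' Carrier frequencies (fraction of individuals carrying each allele) are
#' reported alongside true allele frequencies.
#'
#' @param counts numeric vector `c(hom_minor, het, hom_major)`.
#' @param locus optional locus label for the result row.
#' @return one-row data.frame of class `hwe_result`: counts, `n`, `maf`,
#'   `he`, `ho`, `carrier_minor`, `carrier_major`, `chi2`, `p_value`,
#'   `in_hwe`. All statistics are `NA` for a monomorphic locus.
#' @export
hwe_test <- function(counts, locus = NA_character_) {
  if (length(counts) != 3) stop("counts must be (hom_minor, het, hom_major)")
  n <- sum(counts)
  if (n < 1) stop("no individuals")
  hom_minor <- counts[1]; het <- counts[2]; hom_major <- counts[3]
  p <- (2 * hom_minor + het) / (2 * n)  # minor-allele frequency
  q <- 1 - p
  res <- data.frame(locus = locus, hom_minor = hom_minor, het = het,
                    hom_major = hom_major, n = n, maf = p,
                    he = 2 * p * q, ho = het / n,
                    carrier_minor = (hom_minor + het) / n,
                    carrier_major = (hom_major + het) / n,
                    chi2 = NA_real_, p_value = NA_real_, in_hwe = NA)
  class(res) <- c("hwe_result", "data.frame")
  if (p == 0 || p == 1) return(res)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  res$chi2 <- chi2
  res$p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  res$in_hwe <- res$p_value > 0.05
  res
}

#' Hardy-Weinberg scan over a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()].
#' @param loci labels to test (default all loci of `gm` found in the
#'   catalog).
#' @return data.frame of [hwe_test()] rows.
#' @export
hwe_scan <- function(gm, catalog, loci = NULL) {
  dos <- genotype_dosage(gm, catalog)
  if (is.null(loci)) loci <- colnames(dos)
  do.call(rbind, lapply(loci, function(lab) {
    x <- dos[, lab]
    x <- x[!is.na(x)]
    hwe_test(c(sum(x == 2), sum(x == 1), sum(x == 0)), locus = lab)
  }))
}

#' One-way ANOVA association of a locus with a quantitative trait
#'
#' Fixed-effects one-way ANOVA of the trait across genotype classes. The
#' contribution rate is `R2 = 100 * SS_between / SS_total`; the
#' small-sample adjusted value `R2_adj = 100 * (1 - MS_within / MS_total)`
#' is reported alongside. Classes with fewer than `min_class` non-missing
#' values are dropped with a warning.
#'
#' @param genotype factor-like vector of genotype classes (e.g. `"CC"`,
#'   `"CG"`, `"GG"`, or dosages).
#' @param trait numeric trait values aligned with `genotype`.
#' @param locus,trait_name labels for the result row.
#' @param min_class minimum class size (default 2).
#' @return one-row data.frame of class `assoc_result` with `f_stat`,
#'   `p_value`, `r2_contribution`, `r2_adjusted` (both in %), `n`,
#'   `n_classes`, and the per-class means as attribute `group_means`.
#' @export
anova_association <- function(genotype, trait, locus = NA_character_,
                              trait_name = NA_character_, min_class = 2) {
  ok <- !is.na(genotype) & !is.na(trait)
  g <- factor(as.character(genotype[ok]))
  y <- trait[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < min_class]
  if (length(small)) {
    warning("dropping genotype class(es) below size floor: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(g) %in% small)
    g <- droplevels(g[keep]); y <- y[keep]
  }
  if (nlevels(g) < 2) stop("fewer than two usable genotype classes")
  if (var(y) == 0) stop("zero total trait variance")
  fit <- aov(y ~ g)
  an <- anova(fit)
  ssb <- an[["Sum Sq"]][1]; ssw <- an[["Sum Sq"]][2]
  sst <- ssb + ssw
  n <- length(y); k <- nlevels(g)
  msw <- ssw / (n - k); mst <- sst / (n - 1)
  res <- data.frame(locus = locus, trait = trait_name,
                    f_stat = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                    r2_contribution = 100 * ssb / sst,
                    r2_adjusted = 100 * (1 - msw / mst),
                    n = n, n_classes = k)
  class(res) <- c("assoc_result", "data.frame")
  attr(res, "group_means") <- tapply(y, g, mean)
  res
}

#' Association scan of all loci against one trait
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()]; only informative loci are scanned when
#'   the flag is set.
#' @param traits a trait table (see [read_trait_table()]).
#' @param trait trait column name.
#' @return data.frame of [anova_association()] rows (one per testable
#'   locus; untestable loci are skipped).
#' @export
assoc_scan <- function(gm, catalog, traits, trait) {
  if (!trait %in% names(traits)) stop("unknown trait: ", trait)
  loci <- if (all(is.na(catalog$informative))) catalog$label
          else catalog$label[catalog$informative %in% TRUE]
  loci <- loci[loci %in% gm$loci]
  y <- traits[[trait]][match(gm$individual_ids, traits$id)]
  calls <- matrix(paste0(gm$a1, gm$a2), nrow = length(gm$individual_ids),
                  dimnames = list(NULL, gm$loci))
  calls[is.na(gm$a1)] <- NA
  rows <- lapply(loci, function(lab) {
    tryCatch(anova_association(calls[, lab], y, locus = lab, trait_name = trait),
             error = function(e) NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable loci")
  out
}

#' Select TagSNPs from association results
#'
#' Loci passing both the contribution-rate and the p-value thresholds,
#' ordered by decreasing contribution R2. With `multiple_testing = "bh"`
#' the Benjamini-Hochberg adjusted p-values are thresholded instead.
#'
#' @param results data.frame of [anova_association()] rows.
#' @param r2_min contribution-rate threshold in percent (default 10).
#' @param p_max p-value threshold (default 0.05).
#' @param multiple_testing `"none"` (default) or `"bh"`.
#' @return the selected subset, ordered by `r2_contribution` descending,
#'   with a `p_adjusted` column when BH is used.
#' @export
select_tag_snps <- function(results, r2_min = 10, p_max = 0.05,
                            multiple_testing = c("none", "bh")) {
  multiple_testing <- match.arg(multiple_testing)
  if (!nrow(results)) stop("empty association results")
  p <- results$p_value
  if (multiple_testing == "bh") {
    results$p_adjusted <- p.adjust(p, method = "BH")
    p <- results$p_adjusted
  }
  sel <- results[!is.na(p) & p <= p_max & results$r2_contribution >= r2_min, , drop = FALSE]
  sel[order(-sel$r2_contribution), , drop = FALSE]
}

#' Combined genotype codes at tag loci
#'
#' Each tag locus is assigned a letter (A, B, C, ... in genomic order);
#' homozygous-major is the uppercase pair (`AA`), heterozygous mixed case
#' (`Aa`), homozygous-minor lowercase (`aa`). The combined code is the
#' concatenation over loci; individuals missing any tag call get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()].
#' @param tag_loci labels of the tag loci, in any order (sorted to genomic
#'   order internally).
#' @return data.frame (`id`, `code`) with attribute
#'   `possible_combinations` (`3^k`) and `letters` mapping.
#' @export
combine_genotypes <- function(gm, catalog, tag_loci) {
  pos <- catalog$position[match(tag_loci, catalog$label)]
  if (any(is.na(pos))) stop("tag locus not in catalog")
  tag_loci <- tag_loci[order(pos)]
  k <- length(tag_loci)
  dos <- genotype_dosage(gm, catalog)[, tag_loci, drop = FALSE]
  codes <- vapply(seq_along(gm$individual_ids), function(i) {
    x <- dos[i, ]
    if (anyNA(x)) return(NA_character_)
    paste0(vapply(seq_len(k), function(j) {
      up <- LETTERS[j]; lo <- tolower(up)
      c(paste0(up, up), paste0(up, lo), paste0(lo, lo))[x[j] + 1]
    }, character(1)), collapse = "")
  }, character(1))
  structure(data.frame(id = gm$individual_ids, code = codes),
            possible_combinations = 3L^k,
            letters = setNames(LETTERS[seq_len(k)], tag_loci))
}

#' Marker-assisted selection by combined genotype
#'
#' Selects individuals whose combined genotype code is in an explicit set,
#' or (scheme `trait_mean_threshold`) individuals whose genotype class mean
#' meets a trait threshold. Reports the selection ratio
#' (`100 * n_selected / N`), the selection differential (selected mean
#' minus population mean) and the realized gain
#' (`100 * differential / population mean`).
#'
#' @param codes data.frame from [combine_genotypes()].
#' @param traits trait table.
#' @param trait trait column name.
#' @param scheme character vector of codes to select, or
#'   `list(type = "trait_mean_threshold", min_mean = <value>)`.
#' @return list of class `selection_result`.
#' @export
mas_select <- function(codes, traits, trait, scheme) {
  if (!trait %in% names(traits)) stop("unknown trait: ", trait)
  y <- traits[[trait]][match(codes$id, traits$id)]
  ok <- !is.na(codes$code) & !is.na(y)
  pop_ids <- codes$id[ok]; pop_y <- y[ok]; pop_codes <- codes$code[ok]
  N <- length(pop_ids)
  if (N == 0) stop("no individuals with both genotype code and trait")
  if (is.list(scheme) && identical(scheme$type, "trait_mean_threshold")) {
    cls_mean <- tapply(pop_y, pop_codes, mean)
    scheme_codes <- names(cls_mean)[cls_mean >= scheme$min_mean]
  } else {
    scheme_codes <- as.character(scheme)
  }
  sel <- pop_codes %in% scheme_codes
  if (!any(sel)) stop("empty selection: no individual carries the scheme genotypes")
  pop_mean <- mean(pop_y)
  sel_mean <- mean(pop_y[sel])
  diff <- sel_mean - pop_mean
  gain <- if (pop_mean <= 0) NA_real_ else 100 * diff / pop_mean
  structure(list(scheme = scheme_codes, selected_ids = pop_ids[sel],
                 n_selected = sum(sel), n_population = N,
                 selection_ratio = 100 * sum(sel) / N,
                 population_mean = pop_mean, selected_mean = sel_mean,
                 selection_differential = diff,
                 realized_gain_pct = gain),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$n_selected, "of", x$n_population,
      sprintf("selected (%.2f%%); differential %.2f; realized gain %.1f%%\n",
              x$selection_ratio, x$selection_differential, x$realized_gain_pct))
  invisible(x)
}

#' Per-combination genotype summary
#'
#' Trait mean, spread and count per observed combined genotype, sorted by
#' mean descending; single-observation combinations are flagged.
#'
#' @param codes data.frame from [combine_genotypes()].
#' @param traits trait table.
#' @param trait trait column name.
#' @return data.frame (`code`, `n`, `mean`, `sd`, `min`, `max`,
#'   `single_obs`).
#' @export
genotype_summary <- function(codes, traits, trait) {
  if (!trait %in% names(traits)) stop("unknown trait: ", trait)
  y <- traits[[trait]][match(codes$id, traits$id)]
  ok <- !is.na(codes$code) & !is.na(y)
  if (!any(ok)) stop("no usable trait values")
  sp <- split(y[ok], codes$code[ok])
  df <- data.frame(code = names(sp),
                   n = vapply(sp, length, integer(1)),
                   mean = vapply(sp, mean, numeric(1)),
                   sd = vapply(sp, function(v) if (length(v) > 1) sd(v) else NA_real_, numeric(1)),
                   min = vapply(sp, min, numeric(1)),
                   max = vapply(sp, max, numeric(1)))
  df$single_obs <- df$n == 1L
  df <- df[order(-df$mean, df$code), , drop = FALSE]
  rownames(df) <- NULL
  df
}
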