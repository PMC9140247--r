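# Linkage disequilibrium from unphased diploid genotypes via EM
# haplotype-frequency estimation, LD decay and haplotype blocks.

#' EM estimation of multilocus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies at k biallelic loci from
#' unphased diploid dosage genotypes, assuming random union of gametes.
#' Initialization is the deterministic product of single-locus allele
#' frequencies (no random restarts), so results are reproducible; the EM
#' log-likelihood is non-decreasing by construction and asserted in tests.
#'
#' @param dosage integer matrix (individuals x k loci) of minor-allele
#'   counts 0/1/2; rows with any `NA` are dropped (complete cases).
#' @param tol stop when the largest absolute frequency change drops below
#'   this (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return numeric vector of length `2^k`, named by haplotype bit strings
#'   (`"01"` = major at locus 1, minor at locus 2), with attributes
#'   `loglik` (trace), `n_iter` and `n_used`.
#' @export
em_haplotype_frequencies <- function(dosage, tol = 1e-8, max_iter = 1000) {
  dosage <- as.matrix(dosage)
  k <- ncol(dosage)
  if (k < 1 || k > 14) stop("k must be between 1 and 14 (2^k haplotype table)")
  cc <- complete.cases(dosage)
  if (!any(cc)) stop("no complete cases")
  d <- dosage[cc, , drop = FALSE]
  n <- nrow(d)
  nh <- 2L^k
  bits <- 2L^(seq_len(k) - 1L)
  hap_names <- vapply(0:(nh - 1), function(h)
    paste0(as.integer(bitwAnd(h, bits) > 0), collapse = ""), character(1))

  # group identical genotype rows; enumerate compatible haplotype pairs once
  key <- apply(d, 1, paste0, collapse = "")
  tab <- table(key)
  patterns <- names(tab)
  wts <- as.numeric(tab)
  pair_list <- lapply(patterns, function(p) {
    g <- as.integer(strsplit(p, "")[[1]])
    het <- which(g == 1L)
    hom <- sum(bits[g == 2L])
    if (!length(het)) return(cbind(h1 = hom, h2 = hom))
    subs <- 0:(2L^length(het) - 1L)
    hb <- 2L^(seq_along(het) - 1L)
    h1 <- vapply(subs, function(s) hom + sum(bits[het[bitwAnd(s, hb) > 0]]), numeric(1))
    full <- sum(bits[het])
    h2 <- hom + (full - (h1 - hom))
    keep <- h1 <= h2
    cbind(h1 = h1[keep], h2 = h2[keep])
  })

  p_minor <- colMeans(d) / 2
  f <- vapply(0:(nh - 1), function(h) {
    m <- as.integer(bitwAnd(h, bits) > 0)
    prod(ifelse(m == 1, p_minor, 1 - p_minor))
  }, numeric(1))
  f <- pmax(f, .Machine$double.xmin)
  f <- f / sum(f)

  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    newf <- numeric(nh)
    ll <- 0
    for (g in seq_along(patterns)) {
      pr <- pair_list[[g]]
      w <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L] * ifelse(pr[, 1] == pr[, 2], 1, 2)
      tot <- sum(w)
      ll <- ll + wts[g] * log(tot)
      w <- w / tot
      contrib <- wts[g] * w
      for (r in seq_len(nrow(pr))) {
        newf[pr[r, 1] + 1L] <- newf[pr[r, 1] + 1L] + contrib[r]
        newf[pr[r, 2] + 1L] <- newf[pr[r, 2] + 1L] + contrib[r]
      }
    }
    newf <- newf / (2 * n)
    ll_trace <- c(ll_trace, ll)
    delta <- max(abs(newf - f))
    f <- newf
    if (delta < tol) break
  }
  names(f) <- hap_names
  structure(f, loglik = ll_trace, n_iter = length(ll_trace), n_used = n)
}

#' Pairwise linkage disequilibrium between two loci
#'
#' Two-locus haplotype frequencies are estimated by
#' [em_haplotype_frequencies()]; D is expressed with respect to the minor
#' alleles, `D' = |D|/Dmax` and `r2 = D^2 / (pA(1-pA) pB(1-pB))`.
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()] covering the loci.
#' @param locus_i,locus_j locus labels.
#' @return one-row data.frame (class `ld_pair`): labels, `distance_bp`,
#'   `d`, `d_prime`, `r2`, `n_used`; statistics are `NA` for monomorphic
#'   input.
#' @export
pairwise_ld <- function(gm, catalog, locus_i, locus_j) {
  dos <- genotype_dosage(gm, catalog)
  if (!all(c(locus_i, locus_j) %in% colnames(dos)))
    stop("locus not present in genotype matrix")
  d2 <- dos[, c(locus_i, locus_j)]
  cc <- complete.cases(d2)
  pos <- catalog$position[match(c(locus_i, locus_j), catalog$label)]
  res <- data.frame(locus_i = locus_i, locus_j = locus_j,
                    distance_bp = abs(pos[2] - pos[1]),
                    d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                    n_used = sum(cc))
  class(res) <- c("ld_pair", "data.frame")
  x <- d2[cc, , drop = FALSE]
  pA <- mean(x[, 1]) / 2; pB <- mean(x[, 2]) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(res)
  f <- em_haplotype_frequencies(x)
  fAB <- f[["11"]]
  d <- fAB - pA * pB
  dmax <- if (d > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  res$d <- d
  res$d_prime <- if (dmax == 0) NA_real_ else abs(d) / dmax
  res$r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  res
}

#' LD matrix over a set of loci
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()].
#' @param loci labels to include; default = informative loci of the catalog
#'   (all loci when informativeness is unset).
#' @return list of class `ld_matrix` with symmetric `r2` and `d_prime`
#'   matrices (diagonal 1) and the long-form `pairs` data.frame.
#' @export
ld_matrix <- function(gm, catalog, loci = NULL) {
  if (is.null(loci)) {
    loci <- if (all(is.na(catalog$informative))) catalog$label
            else catalog$label[catalog$informative %in% TRUE]
  }
  loci <- loci[loci %in% gm$loci]
  k <- length(loci)
  if (k < 2) stop("need at least two loci")
  r2 <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  dp <- r2
  diag(r2) <- 1; diag(dp) <- 1
  pairs <- vector("list", k * (k - 1) / 2)
  idx <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- pairwise_ld(gm, catalog, loci[i], loci[j])
    idx <- idx + 1
    pairs[[idx]] <- p
    r2[i, j] <- r2[j, i] <- p$r2
    dp[i, j] <- dp[j, i] <- p$d_prime
  }
  structure(list(r2 = r2, d_prime = dp, pairs = do.call(rbind, pairs)),
            class = "ld_matrix")
}

#' LD decay with distance
#'
#' Pairs are binned by inter-locus distance (default 100-bp bins); the
#' distance at which the binned mean r2 first falls below each threshold is
#' found by linear interpolation between bin midpoints. No monotone
#' smoothing is applied.
#'
#' @param pairs data.frame with `distance_bp` and `r2` (e.g. the `pairs`
#'   element of [ld_matrix()]).
#' @param thresholds r2 thresholds, each in (0, 1).
#' @param bin_width bin width in bp.
#' @return data.frame (`threshold`, `distance_bp`); `distance_bp` is `NA`
#'   when the mean never crosses the threshold within range or when fewer
#'   than two bins exist. Binned means are attached as attribute `bins`.
#' @export
ld_decay <- function(pairs, thresholds = c(0.2, 0.1), bin_width = 100) {
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be inside (0, 1)")
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  if (nrow(pairs) < 1) stop("need at least one pair")
  bin <- floor((pairs$distance_bp - 1) / bin_width)
  agg <- aggregate(r2 ~ bin, data = data.frame(bin = bin, r2 = pairs$r2), FUN = mean)
  agg$mid <- (agg$bin + 0.5) * bin_width
  agg <- agg[order(agg$mid), ]
  cross <- function(thr) {
    if (nrow(agg) < 2) return(NA_real_)
    below <- which(agg$r2 < thr)
    if (!length(below)) return(NA_real_)
    b <- below[1]
    if (b == 1) return(agg$mid[1])
    x0 <- agg$mid[b - 1]; x1 <- agg$mid[b]
    y0 <- agg$r2[b - 1]; y1 <- agg$r2[b]
    x0 + (y0 - thr) / (y0 - y1) * (x1 - x0)
  }
  out <- data.frame(threshold = thresholds,
                    distance_bp = vapply(thresholds, cross, numeric(1)))
  attr(out, "bins") <- agg[, c("mid", "r2")]
  out
}

# ---------------------------------------------------------------------------
# Haplotype blocks

#' Partition loci into haplotype blocks
#'
#' Three methods: `explicit` takes user-supplied boundaries (a list of
#' locus-label vectors covering all loci, in position order); `feature`
#' groups contiguous loci sharing a gene-model region label (see
#' [region_of()]); `r2_contiguous` greedily extends a block while the mean
#' pairwise r2 of a candidate locus with current members stays at or above
#' `r2_min`.
#'
#' @param catalog a [snp_catalog()]; only informative loci are used when
#'   the flag is set.
#' @param gm a [genotype_matrix()] (needed for `r2_contiguous`).
#' @param method one of `"explicit"`, `"feature"`, `"r2_contiguous"`.
#' @param boundaries for `explicit`: list of character vectors of locus
#'   labels.
#' @param model for `feature`: a [gene_model()].
#' @param r2_min for `r2_contiguous` (default 0.5).
#' @param name_prefix block name prefix.
#' @return list of block skeletons: each a list with `name`,
#'   `region_label`, `loci`.
#' @export
partition_blocks <- function(catalog, gm = NULL,
                             method = c("r2_contiguous", "explicit", "feature"),
                             boundaries = NULL, model = NULL, r2_min = 0.5,
                             name_prefix = "block") {
  method <- match.arg(method)
  loci <- if (all(is.na(catalog$informative))) catalog$label
          else catalog$label[catalog$informative %in% TRUE]
  pos <- catalog$position[match(loci, catalog$label)]
  loci <- loci[order(pos)]
  groups <- switch(method,
    explicit = {
      if (is.null(boundaries)) stop("explicit method needs boundaries")
      covered <- unlist(boundaries)
      if (!setequal(covered, loci))
        stop("explicit boundaries must cover all loci exactly; missing: ",
             paste(setdiff(loci, covered), collapse = ", "))
      lapply(boundaries, function(b) loci[loci %in% b])
    },
    feature = {
      if (is.null(model)) stop("feature method needs a gene model")
      reg <- region_of(model, catalog$position[match(loci, catalog$label)])
      split(loci, cumsum(c(TRUE, reg[-1] != reg[-length(reg)])))
    },
    r2_contiguous = {
      if (is.null(gm)) stop("r2_contiguous method needs genotypes")
      if (length(loci) == 1) list(loci) else {
        lm <- ld_matrix(gm, catalog, loci)$r2
        out <- list(); cur <- loci[1]
        for (lab in loci[-1]) {
          m <- mean(lm[lab, cur], na.rm = TRUE)
          if (!is.na(m) && m >= r2_min) cur <- c(cur, lab)
          else { out <- c(out, list(cur)); cur <- lab }
        }
        c(out, list(cur))
      }
    })
  lapply(seq_along(groups), function(i) {
    b_loci <- groups[[i]]
    region <- if (!is.null(model))
      paste(unique(region_of(model, catalog$position[match(b_loci, catalog$label)])),
            collapse = ",") else NA_character_
    list(name = paste0(name_prefix, "-", i), region_label = region, loci = b_loci)
  })
}

#' Haplotypes and frequencies within a block
#'
#' Runs [em_haplotype_frequencies()] over the block loci, renders haplotype
#' bit patterns as nucleotide strings (major/minor alleles in locus order),
#' keeps haplotypes at or above the reporting floor and flags dominant
#' haplotypes (estimated frequency > `dominant_min`).
#'
#' @param block a block skeleton from [partition_blocks()].
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()].
#' @param floor reporting floor for estimated frequencies (default 0.01).
#' @param dominant_min dominance cutoff (default 0.2).
#' @return list of class `haplotype_block`: `name`, `region_label`, `loci`,
#'   `haplotypes` (data.frame `haplotype`, `frequency`, `dominant`,
#'   descending frequency), `n_used`.
#' @export
block_haplotypes <- function(block, gm, catalog, floor = 0.01, dominant_min = 0.2) {
  loci <- block$loci
  if (length(loci) > 14) stop("block has more than 14 loci; split it first")
  dos <- genotype_dosage(gm, catalog)[, loci, drop = FALSE]
  f <- em_haplotype_frequencies(dos)
  idx <- match(loci, catalog$label)
  render <- function(bitstr) {
    b <- strsplit(bitstr, "")[[1]] == "1"
    paste0(ifelse(b, catalog$minor[idx], catalog$major[idx]), collapse = "")
  }
  keep <- which(f >= floor)
  df <- data.frame(haplotype = vapply(names(f)[keep], render, character(1)),
                   frequency = as.numeric(f[keep]))
  df <- df[order(-df$frequency, df$haplotype), , drop = FALSE]
  rownames(df) <- NULL
  df$dominant <- df$frequency > dominant_min
  structure(list(name = block$name, region_label = block$region_label,
                 loci = loci, haplotypes = df,
                 n_used = attr(f, "n_used")),
            class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("<haplotype_block>", x$name, "-", length(x$loci), "loci,",
      nrow(x$haplotypes), "haplotypes reported\n")
  print(x$haplotypes)
  invisible(x)
}
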