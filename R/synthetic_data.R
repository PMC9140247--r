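# Coalescent-based synthetic data: haplotype alignments with realistic
# diversity and block-wise LD, Hardy-Weinberg diploid genotype panels and a
# quantitative trait with planted per-SNP effects.

#' Default gene model used by the simulator
#'
#' A 4638-bp gene with a 5'-UTR, ten coding exons totaling 1890 bp (630
#' codons: a 629-residue protein plus the stop), nine introns and a
#' 3'-UTR, emulating the exon/intron architecture of a conifer monoterpene
#' synthase gene.
#'
#' @return a [gene_model()].
#' @export
default_gene_model <- function() {
  ex_len <- c(200, 180, 200, 190, 200, 180, 190, 180, 180, 190)  # 1890 bp
  in_len <- c(150, rep(214, 8))
  start <- 587
  starts <- integer(10); ends <- integer(10)
  for (i in 1:10) {
    starts[i] <- start
    ends[i] <- start + ex_len[i] - 1
    start <- ends[i] + if (i < 10) in_len[i] else 0
  }
  gene_model("synthetic-apin", 4638, data.frame(start = starts, end = ends))
}

#' Simulation parameters
#'
#' Defaults describe the study conditions the generator emulates: 110
#' diploid individuals, a 4638-bp gene, per-site diversity theta = 0.003,
#' six independently coalescing segments (creating haplotype-block LD
#' structure), a trait baseline of 20.6 (alpha-pinene as % of turpentine)
#' and three causal SNPs with single-locus R2 targets of 0.155, 0.103 and
#' 0.114.
#'
#' @param n_individuals diploid sample size.
#' @param gene_length_bp gene length.
#' @param gene_model gene model (default [default_gene_model()]).
#' @param theta_per_site scaled mutation rate per site.
#' @param n_blocks number of independently coalescing segments.
#' @param causal list of lists `(position, a, d)` with additive and
#'   dominance effects in trait units, or `NULL` to use `target_r2`.
#' @param target_r2 per-causal-locus single-marker R2 (fractions); used by
#'   [simulate_trait()] to solve additive effects.
#' @param causal_positions preferred gene positions for causal SNPs when
#'   `target_r2` drives the effects.
#' @param trait_baseline population trait mean.
#' @param noise_sd residual standard deviation (trait units).
#' @param seed integer seed; every simulation is deterministic given it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 110, gene_length_bp = 4638,
                       gene_model = default_gene_model(),
                       theta_per_site = 0.003, n_blocks = 6,
                       causal = NULL,
                       target_r2 = c(0.155, 0.103, 0.114),
                       causal_positions = c(615, 641, 3859),
                       trait_baseline = 20.6, noise_sd = 8,
                       seed = 1L) {
  stopifnot(theta_per_site >= 0, n_blocks >= 1, gene_length_bp >= 1,
            noise_sd >= 0)
  if (!is.null(target_r2) && any(target_r2 <= 0 | target_r2 >= 1))
    stop("target_r2 values must lie in (0, 1)")
  structure(list(n_individuals = as.integer(n_individuals),
                 gene_length_bp = as.integer(gene_length_bp),
                 gene_model = gene_model, theta_per_site = theta_per_site,
                 n_blocks = as.integer(n_blocks), causal = causal,
                 target_r2 = target_r2, causal_positions = causal_positions,
                 trait_baseline = trait_baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Kingman coalescent for n tips: returns list of branches, each with the
# tip set below it and its length (time in units of 2N generations).
coalescent_branches <- function(n_tips) {
  lineages <- lapply(seq_len(n_tips), function(i) i)
  birth <- rep(0, n_tips)
  t <- 0
  branches_tips <- vector("list", 2 * (n_tips - 1))
  branch_len <- numeric(2 * (n_tips - 1))
  bi <- 0
  while (length(lineages) > 1) {
    k <- length(lineages)
    t <- t + rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2)
    for (p in pick) {
      bi <- bi + 1
      branches_tips[[bi]] <- lineages[[p]]
      branch_len[bi] <- t - birth[p]
    }
    merged <- c(lineages[[pick[1]]], lineages[[pick[2]]])
    lineages <- c(lineages[-pick], list(merged))
    birth <- c(birth[-pick], t)
  }
  list(tips = branches_tips[seq_len(bi)], len = branch_len[seq_len(bi)])
}

#' Simulate haplotypes under a block-wise neutral coalescent
#'
#' The gene is split into `n_blocks` contiguous segments; each segment gets
#' an independent Kingman genealogy for `2 * n_individuals` lineages.
#' Infinite-site mutations are placed on branches in proportion to branch
#' length, with `Poisson(theta * segment_length * T_total / 2)` mutations
#' per segment assigned to distinct positions, so every variable site is
#' biallelic. Independent segment genealogies create within-block LD and
#' between-block decay. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list with `aln` (haplotype [alignment_set()], `2n` rows),
#'   `truth` (data.frame `position`, `ancestral`, `derived`,
#'   `derived_count`) and `ancestral` (reference sequence).
#' @export
simulate_haplotypes <- function(params) {
  set.seed(params$seed)
  L <- params$gene_length_bp
  if (L < 1) stop("zero-length gene")
  n_hap <- 2L * params$n_individuals
  anc <- sample(NUC, L, replace = TRUE)
  # keep the ancestral CDS free of internal stop codons
  if (!is.null(params$gene_model) && params$gene_model$length_bp == L) {
    cpos <- cds_positions(params$gene_model)
    nc <- length(cpos) / 3
    for (k in seq_len(nc - 1)) {
      idx <- cpos[(3 * k - 2):(3 * k)]
      while (paste0(anc[idx], collapse = "") %in% c("TAA", "TAG", "TGA"))
        anc[idx] <- sample(NUC, 3, replace = TRUE)
    }
    anc[cpos[(3 * nc - 2):(3 * nc)]] <- c("T", "A", "A")  # terminal stop
  }
  mat <- matrix(rep(anc, each = n_hap), nrow = n_hap)
  bounds <- round(seq(0, L, length.out = params$n_blocks + 1))
  truth <- list(position = integer(), ancestral = character(),
                derived = character(), derived_count = integer())
  for (b in seq_len(params$n_blocks)) {
    seg <- (bounds[b] + 1):bounds[b + 1]
    seg_len <- length(seg)
    if (seg_len < 1) next
    cb <- coalescent_branches(n_hap)
    t_total <- sum(cb$len)
    n_mut <- rpois(1, params$theta_per_site * seg_len * t_total / 2)
    n_mut <- min(n_mut, seg_len)  # infinite sites on a finite segment
    if (n_mut == 0) next
    pos <- sort(sample(seg, n_mut))
    br <- sample.int(length(cb$len), n_mut, replace = TRUE, prob = cb$len)
    cpos_all <- if (!is.null(params$gene_model) && params$gene_model$length_bp == L)
      cds_positions(params$gene_model) else integer()
    for (m in seq_len(n_mut)) {
      carriers <- cb$tips[[br[m]]]
      choices <- setdiff(NUC, anc[pos[m]])
      k <- match(pos[m], cpos_all)
      if (!is.na(k)) {
        # avoid nonsense mutations so every haplotype encodes a full protein
        cs <- ((k - 1) %/% 3) * 3
        codon <- anc[cpos_all[cs + 1:3]]
        ok <- vapply(choices, function(b) {
          cd <- codon; cd[k - cs] <- b
          !(paste0(cd, collapse = "") %in% c("TAA", "TAG", "TGA"))
        }, logical(1))
        if (any(ok)) choices <- choices[ok]
      }
      der <- if (length(choices) == 1) choices else sample(choices, 1)
      mat[carriers, pos[m]] <- der
      truth$position <- c(truth$position, pos[m])
      truth$ancestral <- c(truth$ancestral, anc[pos[m]])
      truth$derived <- c(truth$derived, der)
      truth$derived_count <- c(truth$derived_count, length(carriers))
    }
  }
  ids <- sprintf("hap%03d", seq_len(n_hap))
  truth <- as.data.frame(truth)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  list(aln = alignment_set(ids, mat, is_haplotype = TRUE),
       truth = truth, ancestral = anc)
}

#' Pair haplotypes into diploid individuals
#'
#' Haplotypes are matched at random (a perfect matching under the seed) so
#' Hardy-Weinberg proportions hold by construction; genotypes at the
#' catalog loci are the unordered allele pairs. The true pairing and phased
#' alleles are retained as attribute `phase` for phase-aware tests.
#'
#' @param aln haplotype [alignment_set()] with an even number of rows.
#' @param catalog a [snp_catalog()] called from `aln`.
#' @param seed integer seed for the matching.
#' @return a [genotype_matrix()] with attribute `phase` (list `h1`, `h2`:
#'   row indices of `aln` per individual).
#' @export
pair_into_diploids <- function(aln, catalog, seed = 1L) {
  n_hap <- n_seq(aln)
  if (n_hap %% 2 != 0) stop("odd haplotype count; cannot pair into diploids")
  set.seed(seed)
  perm <- sample.int(n_hap)
  h1 <- perm[seq(1, n_hap, 2)]
  h2 <- perm[seq(2, n_hap, 2)]
  cols <- match(catalog$position, aln$ref_positions)
  a1 <- aln$mat[h1, cols, drop = FALSE]
  a2 <- aln$mat[h2, cols, drop = FALSE]
  a1[a1 == "N"] <- NA; a2[a2 == "N"] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  ids <- sprintf("tree%03d", seq_along(h1))
  gm <- genotype_matrix(ids, catalog, a1, a2)
  attr(gm, "phase") <- list(h1 = h1, h2 = h2)
  gm
}

#' Simulate a quantitative trait with planted SNP effects
#'
#' `trait = baseline + sum(a_c * x_c + d_c * h_c) + N(0, noise_sd^2)` with
#' `x_c` the minor-allele dosage and `h_c` the heterozygosity indicator at
#' causal locus c. When `params$target_r2` drives the effects, additive
#' coefficients are solved against the empirical dosage variance of the
#' supplied panel: `a_c = sqrt(r2_c / (1 - sum(r2)) * noise_sd^2 /
#' var(x_c))`, with `d_c = 0`, so each locus explains its target fraction
#' of the trait variance in this panel (up to LD among causal loci).
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()].
#' @param params a [sim_params()]; `params$causal` (explicit effects) takes
#'   precedence over `params$target_r2`.
#' @param causal_loci labels of the causal loci when `target_r2` is used;
#'   defaults to the loci nearest `params$causal_positions`.
#' @param seed seed for the residual noise (default `params$seed + 1`).
#' @return trait table (`id`, `alpha_pinene_pct`) with attribute `truth`
#'   recording the planted loci and effects.
#' @export
simulate_trait <- function(gm, catalog, params, causal_loci = NULL,
                           seed = params$seed + 1L) {
  set.seed(seed)
  n <- length(gm$individual_ids)
  dos <- genotype_dosage(gm, catalog)
  if (!is.null(params[["causal"]])) {
    labs <- vapply(params[["causal"]], function(cl)
      catalog$label[which.min(abs(catalog$position - cl$position))], character(1))
    a <- vapply(params[["causal"]], function(cl) cl$a, numeric(1))
    dd <- vapply(params[["causal"]], function(cl) if (is.null(cl$d)) 0 else cl$d, numeric(1))
  } else {
    r2 <- params[["target_r2"]]
    if (sum(r2) >= 1) stop("target_r2 infeasible: planted variances meet or exceed total")
    labs <- causal_loci
    if (is.null(labs)) {
      # prefer common loci near the requested positions that are only weakly
      # correlated with loci already chosen, so each planted effect stays a
      # (near-)independent source of variance
      max_link_r2 <- 0.2
      weak_ld <- function(lab) {
        if (!length(labs)) return(TRUE)
        r <- suppressWarnings(stats::cor(dos[, lab], dos[, labs, drop = FALSE],
                                         use = "pairwise.complete.obs"))
        all(is.na(r) | r^2 < max_link_r2)
      }
      labs <- character(0)
      for (p in params$causal_positions) {
        for (floor_maf in c(0.2, 0.1, 0)) {
          cand <- catalog[catalog$maf >= floor_maf & !(catalog$label %in% labs), , drop = FALSE]
          cand <- cand[vapply(cand$label, weak_ld, logical(1)), , drop = FALSE]
          if (nrow(cand)) break
        }
        if (!nrow(cand)) {
          # last resort: accept linkage rather than fail (the planted
          # single-locus R2 may then undershoot its target)
          warning("no weakly linked candidate near position ", p,
                  "; planting on a linked locus")
          cand <- catalog[!(catalog$label %in% labs), , drop = FALSE]
        }
        if (!nrow(cand)) stop("not enough SNPs for the requested causal loci")
        labs <- c(labs, cand$label[which.min(abs(cand$position - p))])
      }
    }
    if (anyDuplicated(labs)) stop("causal loci collapse onto fewer than ",
                                  length(r2), " distinct SNPs")
    vx <- apply(dos[, labs, drop = FALSE], 2, var, na.rm = TRUE)
    if (any(vx == 0)) stop("causal locus with zero dosage variance")
    a <- sqrt(r2 / (1 - sum(r2)) * params$noise_sd^2 / vx)
    dd <- rep(0, length(a))
  }
  x <- dos[, labs, drop = FALSE]
  x[is.na(x)] <- 0  # missing causal calls contribute no genetic effect
  h <- (x == 1) * 1
  g <- as.vector(x %*% a + h %*% dd)
  y <- params$trait_baseline + g - mean(g) + rnorm(n, 0, params$noise_sd)
  tt <- structure(data.frame(id = gm$individual_ids, alpha_pinene_pct = y),
                  class = c("trait_table", "data.frame"))
  attr(tt, "truth") <- data.frame(locus = labs, a = a, d = dd)
  tt
}

#' Generate a complete study-shaped fixture bundle
#'
#' One call simulates haplotypes, calls and classifies SNPs, pairs diploids
#' and plants a three-SNP trait, then writes the full input set: FASTA
#' alignment, genotype TSV, gene-model TSV, trait CSV and a truth JSON
#' recording every planted parameter for recovery tests.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing); `NULL` skips writing.
#' @param params a [sim_params()] (its seed is overridden by `seed`).
#' @return invisible list: `aln`, `catalog`, `gm`, `traits`, `truth`,
#'   `params`, `paths`.
#' @export
generate_fixture_study <- function(seed = 1L, dir = NULL, params = sim_params()) {
  params$seed <- as.integer(seed)
  sim <- simulate_haplotypes(params)
  cat <- call_snps(sim$aln)
  cat <- classify_informative(cat)
  cat <- classify_functional(cat, params$gene_model, sim$aln)
  gm <- pair_into_diploids(sim$aln, cat, seed = params$seed + 7L)
  traits <- simulate_trait(gm, cat, params)
  truth <- list(seed = params$seed,
                theta_per_site = params$theta_per_site,
                n_individuals = params$n_individuals,
                n_snps = nrow(cat),
                causal = attr(traits, "truth"),
                target_r2 = params$target_r2,
                trait_baseline = params$trait_baseline,
                noise_sd = params$noise_sd)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "haplotypes.fasta"),
                  genotypes = file.path(dir, "genotypes.tsv"),
                  gene_model = file.path(dir, "gene_model.tsv"),
                  traits = file.path(dir, "traits.csv"),
                  truth = file.path(dir, "truth.json"))
    write_fasta_alignment(sim$aln, paths$fasta)
    write_genotype_table(gm, paths$genotypes)
    write_gene_model(params$gene_model, paths$gene_model)
    write_trait_table(traits, paths$traits)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(aln = sim$aln, catalog = cat, gm = gm, traits = traits,
                 truth = truth, params = params, paths = paths))
}
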