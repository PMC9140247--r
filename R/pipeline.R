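# End-to-end pipeline: ingest or simulate -> SNP calling -> diversity /
# neutrality / recombination -> LD and blocks -> HWE -> association ->
# TagSNPs -> marker-assisted selection; deterministic report bundle.

default_config <- function() {
  list(trait = "alpha_pinene_pct", maf_min = 0.05, r2_min = 10, p_max = 0.05,
       dominant_min = 0.2, informative_policy = "maf_threshold",
       block_method = "r2_contiguous", block_r2_min = 0.5,
       multiple_testing = "none", selection_codes = NULL, seed = NULL)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Run the full candidate-gene SNP pipeline
#'
#' Stages: load inputs (or simulate them from `config$seed`); strip indel
#' columns; call and classify SNPs; diversity, neutrality and
#' recombination summaries; LD matrix and decay; haplotype blocks with
#' dominant-haplotype calling; per-locus HWE; one-way ANOVA association
#' for the configured trait; TagSNP selection; combined-genotype
#' marker-assisted selection. All stage outputs are written under
#' `out_dir` with a manifest; rerunning with the same configuration
#' reproduces identical files.
#'
#' Config keys (paper-convention defaults): `alignment`, `genotypes`,
#' `gene_model`, `traits` (file paths) or `seed` (simulate instead);
#' `out_dir`; `trait` (default `alpha_pinene_pct`); `maf_min` (0.05);
#' `informative_policy`; `r2_min` (10, percent); `p_max` (0.05);
#' `dominant_min` (0.2); `block_method` (`r2_contiguous`, or `explicit`
#' with `block_boundaries`, or `feature`); `block_r2_min` (0.5);
#' `multiple_testing` (`none`); `selection_codes` (explicit combined
#' genotype codes; default selects classes whose mean exceeds the
#' population mean by one standard deviation).
#'
#' @param config named list or path to a key=value file.
#' @return invisible list of all stage results (`catalog`, `diversity`,
#'   `neutrality`, `recombination`, `ld`, `decay`, `blocks`, `hwe`,
#'   `assoc`, `tags`, `genotype_summary`, `selection`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config must name out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  simulate <- is.null(cfg$alignment)
  if (simulate) {
    if (is.null(cfg$seed)) stop("missing inputs: supply alignment/... files or a seed")
    fx <- generate_fixture_study(seed = as.integer(cfg$seed))
    aln <- fx$aln; model <- fx$params$gene_model
    gm <- fx$gm; traits <- fx$traits
  } else {
    for (key in c("genotypes", "gene_model", "traits"))
      if (is.null(cfg[[key]])) stop("missing input: ", key)
    aln <- read_fasta_alignment(cfg$alignment, is_haplotype = TRUE)
    model <- read_gene_model(cfg$gene_model)
    gm <- read_genotype_table(cfg$genotypes, dialect = cfg$genotype_dialect %||% "tsv")
    traits <- read_trait_table(cfg$traits)
  }
  missing_ids <- setdiff(gm$individual_ids, traits$id)
  if (length(missing_ids))
    warning("trait table missing genotyped individual(s): ",
            paste(missing_ids, collapse = ", "), "; using complete cases")

  stripped <- strip_indel_columns(aln)
  aln2 <- stripped$aln
  catalog <- call_snps(aln2, removed_indel_columns = stripped$removed)
  catalog <- classify_informative(catalog, policy = cfg$informative_policy,
                                  maf_min = cfg$maf_min)
  catalog <- classify_functional(catalog, model, aln2)

  div <- diversity_summary(aln2, model = model, catalog = catalog)
  neut <- neutrality_summary(aln2)
  recomb <- rm_four_gamete(aln2, n_snps = attr(catalog, "n_informative"))

  ld <- ld_matrix(gm, catalog)
  decay <- ld_decay(ld$pairs)
  blocks <- partition_blocks(catalog, gm, method = cfg$block_method,
                             boundaries = cfg$block_boundaries, model = model,
                             r2_min = cfg$block_r2_min)
  blocks <- lapply(blocks, block_haplotypes, gm = gm, catalog = catalog,
                   dominant_min = cfg$dominant_min)
  hwe <- hwe_scan(gm, catalog,
                  loci = catalog$label[catalog$informative %in% TRUE])
  assoc <- assoc_scan(gm, catalog, traits, cfg$trait)
  tags <- select_tag_snps(assoc, r2_min = cfg$r2_min, p_max = cfg$p_max,
                          multiple_testing = cfg$multiple_testing)
  sel <- NULL; gsum <- NULL
  if (nrow(tags) >= 1) {
    codes <- combine_genotypes(gm, catalog, tags$locus)
    gsum <- genotype_summary(codes, traits, cfg$trait)
    scheme <- if (!is.null(cfg$selection_codes)) cfg$selection_codes else {
      y <- traits[[cfg$trait]][match(gm$individual_ids, traits$id)]
      list(type = "trait_mean_threshold",
           min_mean = mean(y, na.rm = TRUE) + sd(y, na.rm = TRUE))
    }
    sel <- tryCatch(mas_select(codes, traits, cfg$trait, scheme),
                    error = function(e) { warning(conditionMessage(e)); NULL })
  }

  # ---- report bundle (fixed precision: diversities 5 dp, chi2/p 4 dp,
  # percentages 2 dp)
  p <- function(f) file.path(out_dir, f)
  write_snp_catalog(catalog, p("snp_catalog.tsv"))
  write_report(div[!vapply(div, is.null, logical(1))], p("diversity.json"), digits = 5)
  write_report(list(n = neut$n, S = neut$S, eta = neut$eta, eta_s = neut$eta_s,
                    pi_total = round(neut$pi_total, 5),
                    tajima_d = round(neut$tajima_d, 5),
                    fu_li_d_star = round(neut$fu_li_d_star, 5),
                    fu_li_f_star = round(neut$fu_li_f_star, 5),
                    fay_wu_h = if (is.na(neut$fay_wu_h)) NULL else round(neut$fay_wu_h, 5),
                    polarized = neut$polarized),
               p("neutrality.json"), digits = 5)
  write_report(list(rm = recomb$rm, rm_per_snp = round(recomb$rm_per_snp, 3)),
               p("recombination.json"), digits = 3)
  r2m <- round(ld$r2, 4)
  write.table(data.frame(locus = rownames(r2m), r2m, check.names = FALSE),
              p("ld_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(decay, p("ld_decay.tsv"), format = "tsv", digits = 1)
  block_df <- do.call(rbind, lapply(blocks, function(b)
    data.frame(block = b$name, region = b$region_label,
               n_loci = length(b$loci), loci = paste(b$loci, collapse = ","),
               haplotype = b$haplotypes$haplotype,
               frequency = b$haplotypes$frequency,
               dominant = b$haplotypes$dominant)))
  write_report(block_df, p("blocks.tsv"), format = "tsv", digits = 3)
  write_report(hwe, p("hwe.tsv"), format = "tsv", digits = 4)
  write_report(assoc, p("association.tsv"), format = "tsv", digits = 4)
  write_report(tags, p("tag_snps.tsv"), format = "tsv", digits = 4)
  if (!is.null(gsum)) write_report(gsum, p("genotype_summary.tsv"), format = "tsv", digits = 2)
  if (!is.null(sel))
    write_report(list(scheme = paste(sel$scheme, collapse = ","),
                      n_selected = sel$n_selected, n_population = sel$n_population,
                      selection_ratio = round(sel$selection_ratio, 2),
                      population_mean = round(sel$population_mean, 2),
                      selected_mean = round(sel$selected_mean, 2),
                      selection_differential = round(sel$selection_differential, 2),
                      realized_gain_pct = round(sel$realized_gain_pct, 2)),
                 p("selection.json"), digits = 2)
  manifest <- list(package_version = as.character(utils::packageVersion("pinesnp")),
                   config = cfg[order(names(cfg))],
                   simulated = simulate,
                   n_individuals = length(gm$individual_ids),
                   n_snps = nrow(catalog),
                   n_informative = attr(catalog, "n_informative"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(list(catalog = catalog, diversity = div, neutrality = neut,
                 recombination = recomb, ld = ld, decay = decay,
                 blocks = blocks, hwe = hwe, assoc = assoc, tags = tags,
                 genotype_summary = gsum, selection = sel, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
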