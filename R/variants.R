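# SNP calling and site classification from a gapped alignment.

#' Remove insertion/deletion columns from an alignment
#'
#' Every column containing a gap character in any row is removed; contiguous
#' removed columns are merged into intervals. Reference positions of the
#' surviving columns are retained (`ref_positions`) so that SNP positions
#' keep referring to the pre-filter coordinate system.
#'
#' @param aln an [alignment_set()].
#' @return list with `aln` (gap-free [alignment_set()]) and `removed`
#'   (data.frame `start`, `end` of removed reference-column intervals).
#' @export
strip_indel_columns <- function(aln) {
  gap <- apply(aln$mat == "-", 2, any)
  if (all(gap)) stop("no sites remain after removing indel columns")
  removed_pos <- aln$ref_positions[gap]
  removed <- merge_intervals(removed_pos)
  out <- alignment_set(aln$ids, aln$mat[, !gap, drop = FALSE],
                       is_haplotype = aln$is_haplotype,
                       ref_positions = aln$ref_positions[!gap])
  list(aln = out, removed = removed)
}

merge_intervals <- function(pos) {
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  pos <- sort(unique(pos))
  brk <- c(0, which(diff(pos) > 1), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1], end = pos[brk[-1]])
}

#' Call biallelic SNPs from a haplotype alignment
#'
#' A column is a SNP iff exactly two nucleotides occur among the non-missing
#' rows; columns with three or more alleles are recorded as multiallelic and
#' excluded from the catalog. `N` is treated as missing. The major allele is
#' the more frequent one; frequency ties are broken alphabetically (the
#' alphabetically first allele is called minor).
#'
#' @param aln a gap-free haplotype [alignment_set()] (run
#'   [strip_indel_columns()] first if needed).
#' @param removed_indel_columns optional data.frame of removed intervals to
#'   carry into the catalog.
#' @return a [snp_catalog()] with positions on the original reference
#'   coordinates.
#' @export
call_snps <- function(aln, removed_indel_columns = NULL) {
  if (!aln$is_haplotype) stop("call_snps requires a haplotype alignment")
  if (any(aln$mat == "-")) stop("strip indel columns before calling SNPs")
  mat <- aln$mat
  cnt <- vapply(NUC, function(b) colSums(mat == b), numeric(ncol(mat)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, NUC))
  n_alleles <- rowSums(cnt > 0)
  multi <- aln$ref_positions[n_alleles > 2]
  bi <- which(n_alleles == 2)
  rows <- lapply(bi, function(j) {
    cj <- cnt[j, ]
    cj <- cj[cj > 0]
    ord <- order(cj, names(cj))  # ties: alphabetically first is minor
    data.frame(position = aln$ref_positions[j],
               major = names(cj)[ord[2]], minor = names(cj)[ord[1]],
               maf = cj[[ord[1]]] / sum(cj),
               n_called = as.integer(sum(cj)),
               minor_count = as.integer(cj[[ord[1]]]))
  })
  loci <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), major = character(), minor = character(),
               maf = numeric(), n_called = integer(), minor_count = integer())
  snp_catalog(loci, removed_indel_columns = removed_indel_columns,
              multiallelic_positions = multi)
}

#' Flag informative SNPs
#'
#' Two policies: `maf_threshold` keeps loci with MAF at or above `maf_min`
#' (the convention of dropping rare loci with MAF below 0.05);
#' `non_singleton` keeps loci whose minor allele is observed more than once.
#'
#' @param cat a [snp_catalog()] with `maf` (and `minor_count` for the
#'   `non_singleton` policy) populated.
#' @param policy `"maf_threshold"` or `"non_singleton"`.
#' @param maf_min MAF cutoff for the threshold policy.
#' @return the catalog with `informative` set; the counts of informative and
#'   rare loci are attached as attributes `n_informative` / `n_rare`.
#' @export
classify_informative <- function(cat, policy = c("maf_threshold", "non_singleton"),
                                 maf_min = 0.05) {
  policy <- match.arg(policy)
  if (any(is.na(cat$maf))) stop("maf must be populated")
  inf <- switch(policy,
    maf_threshold = cat$maf >= maf_min,
    non_singleton = {
      if (any(is.na(cat$minor_count))) stop("minor_count required for non_singleton policy")
      cat$minor_count > 1L
    })
  cat$informative <- inf
  attr(cat, "n_informative") <- sum(inf)
  attr(cat, "n_rare") <- sum(!inf)
  cat
}

#' Classify SNPs as synonymous, nonsynonymous or noncoding
#'
#' SNPs outside coding exons are `noncoding`. For coding SNPs the reference
#' codon (taken from `reference_row` of the alignment) is translated with
#' the standard genetic code against the codon carrying the alternate
#' allele; identical amino acids mean `synonymous`. A change creating a stop
#' codon is flagged in `creates_stop`, not treated as an error. The derived
#' convention "silent = synonymous + noncoding" is available via
#' [silent_sites()].
#'
#' @param cat a [snp_catalog()].
#' @param model a [gene_model()].
#' @param aln the alignment the catalog was called from (its
#'   `ref_positions` map columns to gene coordinates).
#' @param reference_row row index or id supplying codon context (default 1).
#' @return the catalog with `functional_class` and `creates_stop` filled.
#' @export
classify_functional <- function(cat, model, aln, reference_row = 1) {
  if (is.character(reference_row)) reference_row <- match(reference_row, aln$ids)
  refseq <- rep(NA_character_, model$length_bp)
  refseq[aln$ref_positions] <- aln$mat[reference_row, ]
  cpos <- cds_positions(model)
  rem <- attr(cat, "removed_indel_columns")
  in_removed <- function(p) nrow(rem) > 0 && any(p >= rem$start & p <= rem$end)
  code <- Biostrings::GENETIC_CODE
  fc <- character(nrow(cat)); cs <- logical(nrow(cat))
  for (i in seq_len(nrow(cat))) {
    p <- cat$position[i]
    if (in_removed(p)) stop("SNP position ", p, " lies in a removed indel interval")
    k <- match(p, cpos)
    if (is.na(k)) { fc[i] <- "noncoding"; cs[i] <- FALSE; next }
    codon_start <- ((k - 1L) %/% 3L) * 3L + 1L
    codon_pos <- cpos[codon_start:(codon_start + 2L)]
    ref_codon <- refseq[codon_pos]
    if (any(is.na(ref_codon)))
      stop("codon context for SNP at ", p, " falls in removed columns")
    ref_base <- refseq[p]
    if (!ref_base %in% c(cat$major[i], cat$minor[i])) {
      warning("reference base at ", p, " matches neither catalog allele; using major")
      ref_base <- cat$major[i]
      ref_codon[match(p, codon_pos)] <- ref_base
    }
    alt_base <- if (ref_base == cat$major[i]) cat$minor[i] else cat$major[i]
    alt_codon <- ref_codon
    alt_codon[match(p, codon_pos)] <- alt_base
    aa_ref <- code[[paste0(ref_codon, collapse = "")]]
    aa_alt <- code[[paste0(alt_codon, collapse = "")]]
    fc[i] <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
    cs[i] <- aa_alt == "*" && aa_ref != "*"
  }
  cat$functional_class <- fc
  cat$creates_stop <- cs
  cat
}

#' Silent SNPs (synonymous plus noncoding)
#'
#' @param cat a classified [snp_catalog()].
#' @return logical vector flagging silent loci.
#' @export
silent_sites <- function(cat) {
  if (any(is.na(cat$functional_class))) stop("run classify_functional first")
  cat$functional_class %in% c("synonymous", "noncoding")
}
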