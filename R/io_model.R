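#' @importFrom stats pchisq rnorm rexp rpois runif sd setNames var aov anova complete.cases p.adjust aggregate
#' @importFrom utils read.delim write.table read.csv write.csv head modifyList packageVersion
NULL

IUPAC_HET <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
NUC <- c("A", "C", "G", "T")

# ---------------------------------------------------------------------------
# GeneModel

#' Build a gene model
#'
#' Describes a single candidate gene on its own coordinate system: total
#' genomic length, exon intervals (1-based, inclusive), which exons carry
#' coding sequence and the frame offset of the first codon within the first
#' coding exon. Coordinates are on the plus strand only. The concatenated
#' coding sequence (after dropping `frame_offset` leading bases) must be a
#' whole number of codons.
#'
#' @param name gene name.
#' @param length_bp total gene length in bp.
#' @param exons two-column matrix or data.frame (`start`, `end`) of exon
#'   intervals, 1-based inclusive, sorted and non-overlapping.
#' @param cds_exon_indices indices (into `exons`) of coding exons; defaults
#'   to all exons.
#' @param frame_offset 0, 1 or 2: bases to skip at the start of the first
#'   coding exon before the first codon.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, length_bp, exons,
                       cds_exon_indices = seq_len(nrow(exons)),
                       frame_offset = 0L) {
  exons <- as.data.frame(exons)
  if (ncol(exons) < 2) stop("exons must have start and end columns")
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1) stop("at least one exon required")
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (is.unsorted(exons$start, strictly = TRUE)) stop("exons must be sorted by start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons")
  if (exons$start[1] < 1 || exons$end[nrow(exons)] > length_bp)
    stop("exons outside [1, length_bp]")
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0 || frame_offset > 2) stop("frame_offset must be 0, 1 or 2")
  cds_exon_indices <- sort(as.integer(cds_exon_indices))
  if (length(cds_exon_indices) < 1) stop("at least one coding exon required")
  if (any(cds_exon_indices < 1 | cds_exon_indices > nrow(exons)))
    stop("cds_exon_indices out of range")
  m <- structure(
    list(name = name, length_bp = as.integer(length_bp), exons = exons,
         cds_exon_indices = cds_exon_indices, frame_offset = frame_offset,
         strand = "+"),
    class = "gene_model")
  cl <- length(cds_positions(m))
  if (cl %% 3L != 0L)
    stop("CDS length (", cl, " bp after frame offset) not divisible by 3")
  m
}

#' Genomic positions of the coding sequence, in codon order
#'
#' @param model a [gene_model()].
#' @return integer vector of genomic positions making up the CDS (after the
#'   frame offset), length divisible by 3.
#' @export
cds_positions <- function(model) {
  ex <- model$exons[model$cds_exon_indices, , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
  if (model$frame_offset > 0) pos <- pos[-seq_len(model$frame_offset)]
  pos
}

#' Name the gene feature containing a position
#'
#' Positions before the first exon are `5'-UTR`, after the last exon
#' `3'-UTR`, between exons `intron<k>` and within exon k `exon<k>`.
#'
#' @param model a [gene_model()].
#' @param pos integer vector of 1-based gene positions.
#' @return character vector of region labels.
#' @export
region_of <- function(model, pos) {
  ex <- model$exons
  vapply(pos, function(p) {
    if (p < 1 || p > model$length_bp) stop("position ", p, " outside gene")
    if (p < ex$start[1]) return("5'-UTR")
    if (p > ex$end[nrow(ex)]) return("3'-UTR")
    k <- which(p >= ex$start & p <= ex$end)
    if (length(k) == 1) return(paste0("exon", k))
    k <- max(which(p > ex$end))
    paste0("intron", k)
  }, character(1))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$name, ":", x$length_bp, "bp,",
      nrow(x$exons), "exons,", length(cds_positions(x)), "coding bp\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# AlignmentSet

#' Construct an alignment set
#'
#' A rectangular nucleotide alignment. When `is_haplotype = TRUE` each row is
#' one haplotype (gametic phase known) and only `A C G T - N` are allowed;
#' when `FALSE` each row is one diploid consensus and IUPAC ambiguity codes
#' mark heterozygous positions. Sequence-based population-genetic statistics
#' require haplotype alignments.
#'
#' @param ids unique sequence identifiers.
#' @param mat character matrix (rows = sequences, single characters).
#' @param is_haplotype logical flag, see Details.
#' @param ref_positions optional integer vector mapping columns of `mat` to
#'   positions on the original reference coordinate system (defaults to
#'   `1:ncol(mat)`); maintained by [strip_indel_columns()].
#' @return an object of class `alignment_set`.
#' @export
alignment_set <- function(ids, mat, is_haplotype = TRUE, ref_positions = NULL) {
  if (!is.matrix(mat) || !is.character(mat)) stop("mat must be a character matrix")
  if (length(ids) != nrow(mat)) stop("ids length must equal nrow(mat)")
  if (anyDuplicated(ids)) stop("duplicate ids")
  if (ncol(mat) < 1) stop("alignment must have at least one column")
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  allowed <- c(NUC, "-", "N", if (!is_haplotype) IUPAC_HET)
  bad <- setdiff(unique(as.vector(mat)), allowed)
  if (length(bad))
    stop("non-nucleotide symbols in alignment: ", paste(bad, collapse = " "))
  if (is.null(ref_positions)) ref_positions <- seq_len(ncol(mat))
  if (length(ref_positions) != ncol(mat)) stop("ref_positions length mismatch")
  rownames(mat) <- ids
  structure(list(ids = as.character(ids), mat = mat,
                 is_haplotype = isTRUE(is_haplotype),
                 ref_positions = as.integer(ref_positions)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("<alignment_set>", nrow(x$mat), if (x$is_haplotype) "haplotypes," else "consensus sequences,",
      ncol(x$mat), "columns\n")
  invisible(x)
}

n_seq <- function(aln) nrow(aln$mat)
n_col <- function(aln) ncol(aln$mat)

#' Read a FASTA alignment
#'
#' Sequences are uppercased and `U` is mapped to `T`. All records must have
#' equal length; ragged input is an error.
#'
#' @param path FASTA file.
#' @param is_haplotype see [alignment_set()].
#' @return an [alignment_set()].
#' @export
read_fasta_alignment <- function(path, is_haplotype = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1) stop("ragged alignment: record lengths ", paste(unique(w), collapse = ", "))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate ids in FASTA")
  chars <- strsplit(as.character(ss), "", fixed = TRUE)
  mat <- do.call(rbind, chars)
  alignment_set(ids, mat, is_haplotype = is_haplotype)
}

#' Write an alignment set as FASTA
#'
#' @param aln an [alignment_set()].
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SnpCatalog

#' Construct a SNP catalog
#'
#' One row per biallelic SNP: reference position, major/minor alleles, label
#' (minor allele, then major allele, then 1-based position, e.g. `CG615`),
#' transition/transversion class, functional class, minor-allele frequency
#' and an informativeness flag. Multiallelic positions and removed indel
#' column intervals travel along as attributes.
#'
#' @param loci data.frame with at least `position`, `major`, `minor`;
#'   optional `maf`, `n_called`, `minor_count`, `mutation_class`,
#'   `functional_class`, `informative`, `creates_stop`.
#' @param removed_indel_columns data.frame (`start`, `end`) of reference
#'   column intervals removed as indels.
#' @param multiallelic_positions integer vector of positions excluded for
#'   having more than two alleles.
#' @return data.frame of class `snp_catalog`.
#' @export
snp_catalog <- function(loci, removed_indel_columns = NULL,
                        multiallelic_positions = integer()) {
  loci <- as.data.frame(loci)
  need <- c("position", "major", "minor")
  if (!all(need %in% names(loci))) stop("loci needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(loci$position)) stop("duplicate SNP positions")
  if (is.unsorted(loci$position)) loci <- loci[order(loci$position), , drop = FALSE]
  if (any(loci$major == loci$minor)) stop("major and minor alleles must differ")
  loci$label <- snp_label(loci$minor, loci$major, loci$position)
  nr <- nrow(loci)
  for (col in c("maf", "n_called", "minor_count"))
    if (is.null(loci[[col]])) loci[[col]] <- rep(NA_real_, nr)
  if (is.null(loci$mutation_class))
    loci$mutation_class <- if (nr) mutation_class(loci$major, loci$minor) else character(0)
  if (is.null(loci$functional_class)) loci$functional_class <- rep(NA_character_, nr)
  if (is.null(loci$informative)) loci$informative <- rep(NA, nr)
  if (is.null(loci$creates_stop)) loci$creates_stop <- rep(NA, nr)
  if (any(!is.na(loci$maf) & (loci$maf < 0 | loci$maf > 0.5)))
    stop("maf must lie in [0, 0.5]")
  rownames(loci) <- NULL
  if (is.null(removed_indel_columns))
    removed_indel_columns <- data.frame(start = integer(), end = integer())
  structure(loci, class = c("snp_catalog", "data.frame"),
            removed_indel_columns = as.data.frame(removed_indel_columns),
            multiallelic_positions = as.integer(multiallelic_positions))
}

#' SNP label in minor-major-position form
#'
#' @param minor,major allele characters.
#' @param position 1-based reference position.
#' @return character vector like `"CG615"`.
#' @export
snp_label <- function(minor, major, position) paste0(minor, major, position)

#' Transition/transversion classification of an allele pair
#' @param a,b nucleotide characters.
#' @return `"transition"` or `"transversion"`.
#' @export
mutation_class <- function(a, b) {
  purine <- c("A", "G")
  ifelse((a %in% purine) == (b %in% purine), "transition", "transversion")
}

#' Write / read a SNP catalog as TSV
#'
#' The writer stores the removed-indel intervals and multiallelic positions
#' in `#`-prefixed header lines so that a write/read round trip is identity.
#'
#' @param cat a [snp_catalog()].
#' @param path TSV file.
#' @return `read_snp_catalog` returns a [snp_catalog()].
#' @export
write_snp_catalog <- function(cat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rem <- attr(cat, "removed_indel_columns")
  writeLines(paste0("#removed_indel_columns=",
                    paste(sprintf("%d-%d", rem$start, rem$end), collapse = ",")), con)
  writeLines(paste0("#multiallelic_positions=",
                    paste(attr(cat, "multiallelic_positions"), collapse = ",")), con)
  df <- as.data.frame(cat)
  df$maf <- fmt_fixed(df$maf, 5)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_catalog
#' @export
read_snp_catalog <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  parse_iv <- function(key) {
    ln <- sub(paste0("^#", key, "="), "", grep(paste0("^#", key, "="), hdr, value = TRUE))
    if (!length(ln) || ln == "") return(NULL)
    strsplit(ln, ",", fixed = TRUE)[[1]]
  }
  rem <- parse_iv("removed_indel_columns")
  rem <- if (is.null(rem)) data.frame(start = integer(), end = integer()) else {
    p <- do.call(rbind, strsplit(rem, "-", fixed = TRUE))
    data.frame(start = as.integer(p[, 1]), end = as.integer(p[, 2]))
  }
  multi <- parse_iv("multiallelic_positions")
  multi <- if (is.null(multi)) integer() else as.integer(multi)
  df <- read.delim(textConnection(lines[!grepl("^#", lines)]),
                   colClasses = c(major = "character", minor = "character"))
  df$maf <- as.numeric(df$maf)
  df$mutation_class <- as.character(df$mutation_class)
  df$functional_class <- as.character(df$functional_class)
  df$informative <- as.logical(df$informative)
  df$creates_stop <- as.logical(df$creates_stop)
  snp_catalog(df, removed_indel_columns = rem, multiallelic_positions = multi)
}

# ---------------------------------------------------------------------------
# GenotypeMatrix

#' Construct a genotype matrix
#'
#' Unphased diploid calls for individuals at named SNP loci. Calls are held
#' as two allele matrices with the pair sorted alphabetically so that
#' heterozygote order is irrelevant; `NA` marks missing calls.
#'
#' @param individual_ids unique individual identifiers.
#' @param loci locus labels (see [snp_label()]), or a [snp_catalog()] whose
#'   labels are used.
#' @param a1,a2 character matrices (individuals x loci) of alleles.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(individual_ids, loci, a1, a2) {
  if (inherits(loci, "snp_catalog")) loci <- loci$label
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  stopifnot(is.matrix(a1), is.matrix(a2),
            nrow(a1) == length(individual_ids), ncol(a1) == length(loci),
            all(dim(a1) == dim(a2)))
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_; a2[miss] <- NA_character_
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, loci)
  structure(list(individual_ids = as.character(individual_ids),
                 loci = as.character(loci), a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", length(x$individual_ids), "individuals x",
      length(x$loci), "loci\n")
  invisible(x)
}

#' Minor-allele dosage codes for a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a [snp_catalog()] supplying major/minor per locus; loci of
#'   `gm` absent from the catalog are dropped.
#' @return integer matrix of 0/1/2 minor-allele counts (NA = missing).
#' @export
genotype_dosage <- function(gm, catalog) {
  idx <- match(gm$loci, catalog$label)
  keep <- which(!is.na(idx))
  d <- matrix(NA_integer_, nrow = length(gm$individual_ids), ncol = length(keep),
              dimnames = list(gm$individual_ids, gm$loci[keep]))
  for (j in seq_along(keep)) {
    ci <- idx[keep[j]]
    minor <- catalog$minor[ci]; major <- catalog$major[ci]
    A1 <- gm$a1[, keep[j]]; A2 <- gm$a2[, keep[j]]
    bad <- !is.na(A1) & !(A1 %in% c(minor, major) & A2 %in% c(minor, major))
    if (any(bad))
      stop("allele not in {major, minor} at locus ", gm$loci[keep[j]],
           " for individual(s) ", paste(gm$individual_ids[bad], collapse = ", "))
    d[, j] <- (A1 == minor) + (A2 == minor)
  }
  d
}

#' Read a genotype table (TSV or minimal VCF)
#'
#' TSV dialect: a header row of locus labels with leading `id` column, then
#' one row per individual with calls like `CG`; `./.`, `NN`, `NA` or an
#' empty field mark missing. Minimal-VCF dialect: VCF v4.2 with a single
#' ALT allele per site and unphased GT (`0/1` and `1/0` are the same call);
#' locus labels are regenerated from allele frequencies as
#' minor+major+POS.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf_min"`.
#' @param catalog optional [snp_catalog()] used to validate alleles.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "vcf_min"),
                                catalog = NULL) {
  dialect <- match.arg(dialect)
  gm <- if (dialect == "tsv") read_genotype_tsv(path) else read_genotype_vcf(path)
  if (!is.null(catalog)) genotype_dosage(gm, catalog)  # validates alleles
  gm
}

read_genotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("genotype TSV needs an id column and >=1 locus")
  ids <- df[[1]]
  loci <- names(df)[-1]
  calls <- as.matrix(df[, -1, drop = FALSE])
  calls[calls %in% c("./.", ".", "NN", "NA", "--", "")] <- NA
  ok <- is.na(calls) | grepl("^[ACGT]{2}$", calls)
  if (!all(ok)) stop("malformed genotype call(s): ", paste(unique(calls[!ok]), collapse = " "))
  a1 <- substr(calls, 1, 1); dim(a1) <- dim(calls)
  a2 <- substr(calls, 2, 2); dim(a2) <- dim(calls)
  genotype_matrix(ids, loci, a1, a2)
}

read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  if (any(nchar(ref) != 1 | nchar(alt) != 1 | grepl(",", alt)))
    stop("vcf_min dialect requires single-base REF and a single ALT")
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  n <- length(ids); L <- length(pos)
  a1 <- matrix(NA_character_, n, L); a2 <- matrix(NA_character_, n, L)
  for (s in seq_len(L)) {
    g <- gt[s, ]
    miss <- is.na(g) | g %in% c("./.", ".")
    gg <- g[!miss]
    if (length(gg)) {
      parts <- strsplit(gg, "[/|]")
      if (any(lengths(parts) != 2)) stop("malformed GT at POS ", pos[s])
      ai <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE))
      if (any(is.na(ai)) || any(ai > 1 | ai < 0))
        stop("GT allele index out of range at POS ", pos[s])
      alleles <- c(ref[s], alt[s])
      a1[!miss, s] <- alleles[ai[, 1] + 1L]
      a2[!miss, s] <- alleles[ai[, 2] + 1L]
    }
  }
  # label each site from observed allele frequencies (minor first, ties
  # broken alphabetically)
  labels <- character(L)
  for (s in seq_len(L)) {
    cnt <- table(factor(c(a1[, s], a2[, s]), levels = c(ref[s], alt[s])))
    ord <- order(cnt, names(cnt))  # least frequent first, alphabetical on ties
    labels[s] <- snp_label(names(cnt)[ord[1]], names(cnt)[ord[2]], pos[s])
  }
  genotype_matrix(ids, labels, a1, a2)
}

#' Write a genotype matrix as TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotype_table <- function(gm, path) {
  calls <- matrix(paste0(gm$a1, gm$a2), nrow = length(gm$individual_ids))
  calls[is.na(gm$a1)] <- "./."
  df <- data.frame(id = gm$individual_ids, calls, check.names = FALSE)
  names(df) <- c("id", gm$loci)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeneModel and TraitTable IO

#' Read / write a gene model as an exon TSV
#'
#' Format: `#name=`, `#length_bp=`, `#frame_offset=` header lines followed
#' by a tab-separated table with columns `start`, `end`, `coding`.
#'
#' @param path TSV file.
#' @param model a [gene_model()].
#' @return `read_gene_model` returns a [gene_model()].
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  hv <- function(key) sub(paste0("^#", key, "="), "",
                          grep(paste0("^#", key, "="), lines, value = TRUE)[1])
  df <- read.delim(textConnection(lines[!grepl("^#", lines)]))
  gene_model(name = hv("name"), length_bp = as.integer(hv("length_bp")),
             exons = df[, c("start", "end")],
             cds_exon_indices = which(as.logical(df$coding)),
             frame_offset = as.integer(hv("frame_offset")))
}

#' @rdname read_gene_model
#' @export
write_gene_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#name=", model$name),
               paste0("#length_bp=", model$length_bp),
               paste0("#frame_offset=", model$frame_offset)), con)
  df <- model$exons
  df$coding <- seq_len(nrow(df)) %in% model$cds_exon_indices
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-individual trait table (CSV)
#'
#' First column is the individual id; remaining columns are numeric traits
#' (for monoterpene components, percentages of turpentine).
#'
#' @param path CSV file.
#' @param traits data.frame with an `id` column.
#' @return `read_trait_table` returns a data.frame of class `trait_table`.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  names(df)[1] <- "id"
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate individual ids in trait table")
  for (j in seq_along(df)[-1]) {
    df[[j]] <- as.numeric(df[[j]])
    if (any(is.infinite(df[[j]]))) stop("non-finite trait value in ", names(df)[j])
  }
  structure(df, class = c("trait_table", "data.frame"))
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(traits, path) {
  write.csv(as.data.frame(traits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reports

fmt_fixed <- function(x, digits) {
  out <- ifelse(is.na(x), NA_character_, formatC(as.numeric(x), format = "f", digits = digits))
  out
}

round_fixed <- function(x, digits) {
  if (is.numeric(x)) round(x, digits) else x
}

#' Write an analysis summary deterministically
#'
#' Serializes any summary produced by this package (a named list or
#' data.frame) as JSON (keys sorted, fixed decimal places) or TSV. Numeric
#' precision follows the reporting conventions used throughout: diversities
#' to 5 decimals, test statistics and p-values to 4, percentages to 2.
#'
#' @param result named list or data.frame.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @param digits decimal places applied to numeric fields.
#' @export
write_report <- function(result, path, format = c("json", "tsv"), digits = 5) {
  format <- match.arg(format)
  if (format == "json") {
    x <- if (is.data.frame(result)) lapply(as.list(result), round_fixed, digits)
         else rapply(result, round_fixed, how = "replace", digits = digits)
    if (!is.data.frame(result) && !is.null(names(x))) x <- x[order(names(x))]
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  } else {
    df <- if (is.data.frame(result)) result else {
      flat <- unlist(result)
      data.frame(key = names(flat), value = as.character(flat))
    }
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_fixed, digits)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
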