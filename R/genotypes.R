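# Genotype container, loaders, and marker-level quality control.
#
# Dosages code the count of the alternative allele (0/1/2); heterozygous calls
# are coded 1 even in inbred panels, where they represent residual
# heterozygosity. After mean imputation dosages may be real-valued in [0, 2];
# every downstream operation accepts real dosages.

#' Construct a genotype matrix object
#'
#' The central genotype container: a lines-by-markers dosage matrix plus a
#' marker map and per-marker minor allele frequencies. Markers are stored
#' sorted by (chromosome, position).
#'
#' @param dosages numeric matrix, lines in rows (unique rownames = line ids),
#'   markers in columns (unique colnames = marker ids). Values in `[0, 2]`
#'   (integers 0/1/2 for raw calls, real after imputation); `NA` marks missing.
#' @param map optional data frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per marker. When absent, a placeholder map preserving
#'   column order is created (chromosome 0, positions 1..m).
#' @return an object of class `geno_matrix` with elements `dosages`, `map`
#'   and `maf`.
#' @export
genotype_matrix <- function(dosages, map = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) || anyNA(rownames(dosages)))
    gs_error("dosage matrix must have line ids as rownames", "gs_validation_error")
  if (is.null(colnames(dosages)))
    gs_error("dosage matrix must have marker ids as colnames", "gs_validation_error")
  dup <- rownames(dosages)[duplicated(rownames(dosages))]
  if (length(dup))
    gs_error(paste0("duplicate line ids: ", paste(unique(dup), collapse = ", ")),
             "gs_validation_error")
  if (anyDuplicated(colnames(dosages)))
    gs_error("duplicate marker ids", "gs_validation_error")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    gs_error("dosages must lie in [0, 2]", "gs_validation_error")

  if (is.null(map)) {
    map <- data.frame(id = colnames(dosages), chrom = 0L,
                      pos = seq_len(ncol(dosages)),
                      ref = NA_character_, alt = NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    map <- as.data.frame(map, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "chrom", "pos") %in% names(map)))
    if (!"ref" %in% names(map)) map$ref <- NA_character_
    if (!"alt" %in% names(map)) map$alt <- NA_character_
    if (!identical(sort(map$id), sort(colnames(dosages))))
      gs_error("map ids must match dosage column names", "gs_validation_error")
    map <- map[match(colnames(dosages), map$id), , drop = FALSE]
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosages <- dosages[, map$id, drop = FALSE]

  g <- structure(list(dosages = dosages, map = map, maf = compute_maf(dosages)),
                 class = "geno_matrix")
  g
}

# MAF from dosage means over non-missing entries: f_j = mean(dosage_j)/2,
# maf_j = min(f_j, 1 - f_j).
compute_maf <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers; %d missing cells; median MAF %.3f\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages)),
              stats::median(x$maf)))
  invisible(x)
}

#' Number of lines / markers in a genotype matrix
#' @param g a `geno_matrix`.
#' @return integer count.
#' @export
n_lines <- function(g) nrow(g$dosages)

#' @rdname n_lines
#' @export
n_markers <- function(g) ncol(g$dosages)

#' Line identifiers of a genotype matrix
#' @param g a `geno_matrix`.
#' @return character vector of line ids in panel order.
#' @export
line_ids <- function(g) rownames(g$dosages)

#' Read genotypes from VCF or a plain dosage matrix
#'
#' VCF input keeps biallelic SNP records only; multi-allelic sites are skipped
#' with a message reporting the count. GT fields (phased or unphased) are
#' converted to alternative-allele dosages: `0/0` -> 0, `0/1` -> 1, `1/1` -> 2;
#' any missing allele gives `NA`. The matrix dialect is a delimited table
#' (comma or tab, sniffed from the header) whose header row holds marker ids,
#' first column line ids, cells in `{0, 1, 2, NA}`.
#'
#' @param path path to the input file.
#' @param format `"auto"` (default; `.vcf`/`.vcf.gz` extension selects VCF),
#'   `"vcf"`, or `"matrix"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path))
    gs_error(paste0("cannot read genotype file: ", path), "gs_input_error")
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_matrix(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message(sprintf("read_genotypes: skipped %d multi-allelic site(s)", n_skip))
  if (!any(biallelic))
    gs_error("no biallelic sites in VCF", "gs_input_error")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]

  dos <- gt_to_dosage(gt)           # markers x samples
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  samples <- colnames(gt)
  dup <- samples[duplicated(samples)]
  if (length(dup))
    gs_error(paste0("duplicate line ids in VCF: ", paste(unique(dup), collapse = ", ")),
             "gs_validation_error")
  dosages <- t(dos)
  dimnames(dosages) <- list(samples, ids)
  map <- data.frame(id = ids, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(dosages, map)
}

# GT strings to 0/1/2 dosages; alleles beyond {0,1} cannot occur once
# multi-allelic records are removed.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  val <- vapply(u, function(s) {
    if (is.na(s)) return(NA_real_)
    alleles <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(alleles == ".") || !length(alleles)) return(NA_real_)
    sum(alleles != "0")
  }, numeric(1))
  out <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

read_genotypes_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = NA)
  if (ncol(tab) < 2)
    gs_error("matrix dialect needs a line_id column plus marker columns", "gs_input_error")
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    gs_error(paste0("duplicate line ids: ", paste(unique(dup), collapse = ", ")),
             "gs_validation_error")
  dosages <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosages) <- "double"
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok))
    gs_error("matrix dialect cells must be 0, 1, 2 or NA", "gs_validation_error")
  rownames(dosages) <- ids
  genotype_matrix(dosages)
}

#' Write a genotype matrix in the plain dosage dialect
#'
#' Inverse of the matrix branch of [read_genotypes()]: header row
#' `line_id,<marker ids>`, one row per line, cells 0/1/2/NA. Real-valued
#' (imputed) dosages are written as-is and will not survive a strict reload;
#' write before imputing if a round trip is needed.
#'
#' @param g a `geno_matrix`.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(g, path, sep = ",") {
  tab <- data.frame(line_id = line_ids(g), g$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Filter markers by minor allele frequency
#'
#' Removes markers whose MAF is strictly below `threshold`; a marker at
#' exactly the threshold is retained. Marker order is preserved.
#'
#' @param g a `geno_matrix`.
#' @param threshold MAF cut-off as a proportion; default 0.05.
#' @return filtered `geno_matrix`.
#' @export
filter_maf <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "geno_matrix"), threshold >= 0, threshold <= 0.5)
  keep <- g$maf >= threshold
  if (!any(keep))
    gs_error(sprintf(
      "MAF filter at %.3f removes every marker; lower the threshold", threshold),
      "gs_empty_panel_error")
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
}

#' Mean-impute missing dosages per marker
#'
#' Each missing cell is replaced by its marker's mean non-missing dosage
#' (real-valued; not rounded). A marker with no observed calls cannot be
#' imputed and raises an error naming it.
#'
#' @param g a `geno_matrix`.
#' @return `geno_matrix` with no missing cells.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  if (!anyNA(X)) return(g)
  all_missing <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(all_missing))
    gs_error(paste0("marker(s) with all calls missing: ",
                    paste(all_missing, collapse = ", ")), "gs_validation_error")
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  genotype_matrix(X, g$map)
}
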