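# Single-marker association scan and QTN selection for the marker-assisted
# model. The scan is ordinary least squares of the training phenotype on
# (intercept, PC covariates, marker dosage), one marker at a time, with the
# two-sided t-test on the dosage coefficient. It is a deliberately simple,
# transparent top-k selector; it is not a re-implementation of any published
# multi-locus GWAS method.

#' PC-adjusted single-marker association scan
#'
#' For each marker `j`, regress the training phenotype on an intercept, the
#' leading principal components, and the marker dosage, and report the dosage
#' effect, its standard error, and the two-sided p-value. Covariates are
#' projected out once (Frisch-Waugh), so the scan is a single vectorised pass
#' over markers. Markers with zero dosage variance in the training set are
#' untestable and get effect 0, p-value 1.
#'
#' @param y_train phenotypes of the training lines.
#' @param g a `geno_matrix` covering the whole panel (no missing cells).
#' @param pcs a `pc_basis` covering the whole panel, or `NULL` for an
#'   unadjusted scan.
#' @param train_idx integer indices of the training lines.
#' @param n_pcs number of PC covariates (default 3; capped at the basis size).
#' @return data frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `effect`, `se`, `p_value`; attributes `n_train` and `n_covariates`.
#' @export
gwas_scan <- function(y_train, g, pcs = NULL, train_idx, n_pcs = 3) {
  stopifnot(inherits(g, "geno_matrix"))
  train_idx <- as.integer(train_idx)
  if (!length(train_idx))
    gs_error("empty training set", "gs_validation_error")
  n <- length(train_idx)
  if (length(y_train) != n)
    gs_error("y_train and train_idx lengths differ", "gs_validation_error")
  C <- matrix(1, n, 1)
  if (!is.null(pcs)) {
    n_pcs <- min(n_pcs, ncol(pcs$scores))
    C <- cbind(C, pcs$scores[train_idx, seq_len(n_pcs), drop = FALSE])
  }
  if (n <= ncol(C) + 2)
    gs_error("too few training lines for the association scan",
             "gs_insufficient_data_error")

  G <- g$dosages[train_idx, , drop = FALSE]
  if (anyNA(G))
    gs_error("scan requires complete genotypes; run impute_missing() first",
             "gs_validation_error")
  Q <- qr.Q(qr(C))
  ry <- drop(y_train - Q %*% crossprod(Q, y_train))
  RG <- G - Q %*% crossprod(Q, G)
  ss_g <- colSums(RG^2)
  df <- n - ncol(C) - 1L
  testable <- ss_g > 1e-12 * n

  effect <- numeric(ncol(G))
  se <- rep(NA_real_, ncol(G))
  p_value <- rep(1, ncol(G))
  b <- colSums(RG[, testable, drop = FALSE] * ry) / ss_g[testable]
  rss <- sum(ry^2) - b^2 * ss_g[testable]
  rss <- pmax(rss, 0)
  s2 <- rss / df
  se_t <- sqrt(s2 / ss_g[testable])
  tstat <- ifelse(se_t > 0, b / se_t, Inf * sign(b))
  effect[testable] <- b
  se[testable] <- se_t
  p_value[testable] <- pmax(2 * stats::pt(-abs(tstat), df),
                            .Machine$double.xmin)

  res <- data.frame(marker = g$map$id, chrom = g$map$chrom, pos = g$map$pos,
                    effect = effect, se = se, p_value = p_value,
                    stringsAsFactors = FALSE)
  attr(res, "n_train") <- n
  attr(res, "n_covariates") <- ncol(C) - 1L
  res
}

#' Select the top associated markers (QTNs)
#'
#' The `k` markers with the smallest scan p-values; ties are broken by
#' ascending (chromosome, position), so selection is deterministic.
#'
#' @param res a [gwas_scan()] result.
#' @param k number of markers to keep (default 10).
#' @return integer vector of marker indices (rows of `res`), most significant
#'   first.
#' @export
select_top_qtns <- function(res, k = 10) {
  if (k < 1 || k > nrow(res))
    gs_error(sprintf("k must be in [1, %d]", nrow(res)), "gs_validation_error")
  ord <- order(res$p_value, res$chrom, res$pos)
  ord[seq_len(k)]
}

#' Write a scan result to CSV
#' @param res a [gwas_scan()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_result <- function(res, path) {
  utils::write.table(res, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
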