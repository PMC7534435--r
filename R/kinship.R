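# Genomic relationship matrix and marker-derived principal components.

#' Additive genomic relationship matrix
#'
#' Default is VanRaden's method 1: with dosage matrix `M` (lines x markers)
#' and alternative-allele frequencies `p_j`, centre `Z = M - 2p` and take
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))`. Monomorphic markers have zero
#' centred columns and zero `p(1-p)`, so they contribute to neither the
#' numerator nor the denominator. The `"centered_ip"` alternative standardises
#' each polymorphic column by `sqrt(2 p_j (1-p_j))` and averages the inner
#' products over markers; gBLUP is insensitive to this proportional rescaling
#' of `K`.
#'
#' Both constructions are invariant to recoding any marker as `2 - dosage`
#' (allele-label flips) and equivariant under line permutations.
#'
#' @param g a `geno_matrix` with no missing cells (see [impute_missing()]).
#' @param method `"vanraden"` (default) or `"centered_ip"`.
#' @return symmetric n x n numeric matrix with line ids as dimnames.
#' @export
kinship <- function(g, method = c("vanraden", "centered_ip")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  if (anyNA(X))
    gs_error("kinship requires a complete matrix; run impute_missing() first",
             "gs_validation_error")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    gs_error("fewer than 2 polymorphic markers; kinship is degenerate",
             "gs_degenerate_error")
  Z <- sweep(X[, poly, drop = FALSE], 2, 2 * p[poly])
  if (method == "vanraden") {
    K <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  } else {
    Zs <- sweep(Z, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
    K <- tcrossprod(Zs) / ncol(Zs)
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(line_ids(g), line_ids(g))
  K
}

#' Write / read a kinship matrix as square CSV
#'
#' Full square layout: header row of line ids, first column of line ids.
#'
#' @param K symmetric matrix with line-id dimnames.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_kinship <- function(K, path) {
  tab <- data.frame(line_id = rownames(K), K, check.names = FALSE)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(tab[, -1, drop = FALSE])
  rownames(K) <- tab[[1]]
  storage.mode(K) <- "double"
  K
}

#' Principal components of the marker matrix
#'
#' Scores are the top-`k` principal components of the column-centred dosage
#' matrix (via SVD); `explained_variance` holds the corresponding eigenvalues
#' of the line-by-line covariance. The sign of each component is fixed by
#' making its largest-magnitude score positive, so results are deterministic
#' across linear-algebra backends.
#'
#' @param g a `geno_matrix` with no missing cells.
#' @param k number of components; must satisfy
#'   `k <= min(n_lines - 1, n_markers)`.
#' @return an object of class `pc_basis`: list with `line_ids`, `scores`
#'   (n x k matrix, columns `PC1..PCk`), `explained_variance`.
#' @export
marker_pca <- function(g, k = 3) {
  stopifnot(inherits(g, "geno_matrix"), k >= 1)
  X <- g$dosages
  if (anyNA(X))
    gs_error("PCA requires a complete matrix; run impute_missing() first",
             "gs_validation_error")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax)
    gs_error(sprintf("k = %d exceeds the maximum %d for this panel", k, kmax),
             "gs_validation_error")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(line_ids(g), paste0("PC", seq_len(k)))
  structure(list(line_ids = line_ids(g), scores = scores,
                 explained_variance = sv$d[seq_len(k)]^2 / (nrow(X) - 1)),
            class = "pc_basis")
}

#' Write principal-component scores to CSV
#' @param pcs a `pc_basis`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pc_scores <- function(pcs, path) {
  tab <- data.frame(line_id = pcs$line_ids, pcs$scores, check.names = FALSE)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
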