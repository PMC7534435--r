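# Single-kernel mixed model: y = X beta + u + e, u ~ N(0, K sigma_u^2),
# e ~ N(0, I sigma_e^2), one record per line (line means; the random-effect
# design is the identity). Variance components are estimated by REML on the
# spectral scale: K = U D U' is decomposed once, y and X are rotated by U',
# and the restricted likelihood is profiled down to a one-dimensional search
# over the variance ratio lambda = sigma_u^2 / sigma_e^2.

#' Profiled (restricted) log-likelihood of the variance ratio
#'
#' On the rotated scale the covariance of `U'y` is diagonal,
#' `sigma_e^2 * (lambda * d + 1)`, so generalised least squares reduces to
#' weighted least squares and the residual scale profiles out in closed form.
#' Exposed so the optimiser's objective can be checked against a direct
#' matrix-form evaluation (`V = lambda K + I`, determinants and solves).
#'
#' @param lambda variance ratio `sigma_u^2 / sigma_e^2`; must be positive.
#' @param d eigenvalues of the kinship matrix (non-negative).
#' @param y_rot phenotype vector rotated by the eigenvector transpose.
#' @param x_rot fixed-effect design (including intercept) rotated likewise.
#' @param reml if `TRUE` (default) the REML criterion; otherwise ML.
#' @return the profiled log-likelihood (a finite scalar).
#' @export
restricted_loglik <- function(lambda, d, y_rot, x_rot, reml = TRUE) {
  if (!is.finite(lambda) || lambda <= 0)
    gs_error("lambda must be positive", "gs_domain_error")
  n <- length(y_rot)
  x_rot <- as.matrix(x_rot)
  p <- ncol(x_rot)
  w <- lambda * d + 1
  sw <- sqrt(w)
  xw <- x_rot / sw
  yw <- y_rot / sw
  fit <- stats::lm.fit(xw, yw)
  rss <- sum(fit$residuals^2)
  if (reml) {
    df <- n - p
    sigma2 <- rss / df
    xtvx <- crossprod(xw)
    -0.5 * (df * log(2 * pi * sigma2) + df + sum(log(w)) +
              determinant(xtvx, logarithm = TRUE)$modulus[1])
  } else {
    sigma2 <- rss / n
    -0.5 * (n * log(2 * pi * sigma2) + n + sum(log(w)))
  }
}

#' Fit the single-kernel mixed model by REML
#'
#' Eigendecomposes `K` once, rotates `y` and the fixed-effect design, and
#' maximises the profiled restricted likelihood over `log10(lambda)` in
#' `[-10, 10]`: a 100-point grid pass followed by local refinement
#' (`|delta log lambda| < 1e-6`). The search is derivative-free and
#' deterministic, and the ratio may land on either boundary, so heritability
#' estimates of 0 or ~1 are reported as such rather than forced interior.
#' At the optimum, `beta` is the GLS estimate and breeding values are BLUPs:
#' `u_hat = sigma_u^2 K V^{-1} (y - X beta)` with
#' `V = sigma_u^2 K + sigma_e^2 I`.
#'
#' The kernel is standardised to mean diagonal 1 before fitting (the scale is
#' reported as `kernel_scale`): BLUPs and predictions are invariant to a
#' proportional rescaling of `K`, but the variance components are not, and on
#' this scale `sigma_u2` is the average per-line additive variance, making
#' `h2 = sigma_u2 / (sigma_u2 + sigma_e2)` the genetic fraction of line-mean
#' phenotypic variance even for fully inbred panels, whose unstandardised
#' VanRaden diagonal is close to 2. A ridge of `1e-8 * mean(diag(K))` is
#' added to the diagonal before decomposition; eigenvalues below
#' `-1e-6 * mean(diag(K))` raise an error.
#'
#' @param y numeric phenotype vector (one value per line; no `NA`).
#' @param x optional covariate matrix (e.g. principal-component scores); an
#'   intercept column is always prepended.
#' @param K kinship matrix aligned with `y` (and `x`) row order.
#' @param method `"reml"` (default) or `"ml"`.
#' @return an object of class `gs_reml_fit`: list with `beta`, `sigma_u2`,
#'   `sigma_e2`, `h2`, `u_hat`, `reml_loglik`, `lambda`, `method`,
#'   `train_ids`.
#' @export
reml_fit <- function(y, x = NULL, K, method = c("reml", "ml")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y) || any(!is.finite(y)))
    gs_error("phenotypes must be finite and non-missing", "gs_validation_error")
  X <- cbind(`(Intercept)` = rep(1, n), if (!is.null(x)) as.matrix(x))
  p <- ncol(X)
  if (nrow(X) != n || nrow(K) != n || ncol(K) != n)
    gs_error("y, x and K must be aligned on the same lines", "gs_validation_error")
  if (qr(X)$rank < p)
    gs_error("fixed-effect design is singular", "gs_design_error")
  if (n < p + 2)
    gs_error("need at least p + 2 observations", "gs_validation_error")

  kscale <- mean(diag(K))
  if (!is.finite(kscale) || kscale <= 0)
    gs_error("kinship matrix has non-positive mean diagonal", "gs_kinship_error")
  K <- K / kscale
  eig <- eigen((K + t(K)) / 2 + diag(1e-8, n), symmetric = TRUE)
  if (min(eig$values) < -1e-6)
    gs_error("kinship matrix is not positive semidefinite", "gs_kinship_error")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  y_rot <- drop(crossprod(U, y))
  x_rot <- crossprod(U, X)

  reml <- method == "reml"
  obj <- function(loglam) restricted_loglik(10^loglam, d, y_rot, x_rot, reml)
  grid <- seq(-10, 10, length.out = 100)
  ll <- vapply(grid, obj, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-7)
  if (opt$objective >= ll[i]) {
    loglam <- opt$maximum; llmax <- opt$objective
  } else {
    loglam <- grid[i]; llmax <- ll[i]
  }
  lambda <- 10^loglam

  w <- lambda * d + 1
  sw <- sqrt(w)
  fit <- stats::lm.fit(x_rot / sw, y_rot / sw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma_e2 <- rss / (n - if (reml) p else 0)
  sigma_u2 <- lambda * sigma_e2
  r_rot <- y_rot - drop(x_rot %*% beta)
  u_hat <- drop(U %*% (lambda * d / w * r_rot))
  names(u_hat) <- rownames(K)

  structure(list(beta = beta, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 h2 = lambda / (1 + lambda), u_hat = u_hat,
                 reml_loglik = llmax, lambda = lambda,
                 kernel_scale = kscale, method = method,
                 train_ids = rownames(K)),
            class = "gs_reml_fit")
}

#' @export
print.gs_reml_fit <- function(x, ...) {
  cat(sprintf("mixed-model fit (%s): sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f, logLik = %.3f\n",
              toupper(x$method), x$sigma_u2, x$sigma_e2, x$h2, x$reml_loglik))
  invisible(x)
}

#' Narrow-sense heritability from a fitted model
#'
#' `h2 = sigma_u^2 / (sigma_u^2 + sigma_e^2)`: the proportion of line-mean
#' phenotypic variance attributable to additive genetic effects.
#'
#' @param fit a `gs_reml_fit`.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "gs_reml_fit"))
  tot <- fit$sigma_u2 + fit$sigma_e2
  if (tot <= 0)
    gs_error("both variance components are zero; heritability undefined",
             "gs_degenerate_error")
  fit$sigma_u2 / tot
}

#' Genomic BLUP prediction for unphenotyped lines
#'
#' Fits the mixed model on the training lines only, then extends the BLUPs to
#' test lines through their kinship with the training set:
#' `u_test = sigma_u^2 K[test, train] V_train^{-1} (y_train - X_train beta)`.
#' Genotypes (hence kinship rows and PC scores) of test lines are always
#' available; their phenotypes are never touched.
#'
#' @param y_train phenotypes of the training lines, aligned with `train_idx`.
#' @param x_full optional covariate matrix over the whole panel (e.g. PC
#'   scores); an intercept is always included.
#' @param K_full kinship matrix over the whole panel.
#' @param train_idx,test_idx disjoint integer index vectors into the panel.
#' @param include_fixed if `TRUE` (default) predictions are
#'   `x_i beta + u_i`; otherwise the breeding value `u_i` alone.
#' @return numeric vector of predictions in `test_idx` order (named when
#'   `K_full` has dimnames). The fitted model is attached as attribute
#'   `"fit"`.
#' @export
gblup_predict <- function(y_train, x_full = NULL, K_full, train_idx, test_idx,
                          include_fixed = TRUE) {
  train_idx <- as.integer(train_idx)
  test_idx <- as.integer(test_idx)
  if (!length(train_idx))
    gs_error("empty training set", "gs_validation_error")
  if (length(intersect(train_idx, test_idx)))
    gs_error("train and test sets overlap", "gs_validation_error")
  nfull <- nrow(K_full)
  if (any(c(train_idx, test_idx) < 1L) || any(c(train_idx, test_idx) > nfull))
    gs_error("line index outside the kinship matrix", "gs_alignment_error")
  if (length(y_train) != length(train_idx))
    gs_error("y_train and train_idx lengths differ", "gs_validation_error")

  X_full <- cbind(`(Intercept)` = rep(1, nfull),
                  if (!is.null(x_full)) as.matrix(x_full))
  K_tt <- K_full[train_idx, train_idx, drop = FALSE]
  fit <- reml_fit(y_train,
                  x = if (ncol(X_full) > 1) X_full[train_idx, -1, drop = FALSE],
                  K = K_tt)

  if (!length(test_idx)) {
    out <- numeric(0)
    attr(out, "fit") <- fit
    return(out)
  }
  # fit$lambda refers to the kernel standardised inside reml_fit; use the
  # same scale here so the BLUP extension matches the fitted model exactly
  Ks <- K_full / fit$kernel_scale
  lambda <- fit$lambda
  r <- y_train - drop(X_full[train_idx, , drop = FALSE] %*% fit$beta)
  ntr <- length(train_idx)
  M <- lambda * (Ks[train_idx, train_idx] + diag(1e-8, ntr)) + diag(ntr)
  u_test <- drop(lambda * Ks[test_idx, train_idx, drop = FALSE] %*%
                   solve(M, r))
  pred <- if (include_fixed)
    drop(X_full[test_idx, , drop = FALSE] %*% fit$beta) + u_test
  else u_test
  names(pred) <- rownames(K_full)[test_idx]
  attr(pred, "fit") <- fit
  pred
}

#' Export a fitted model as JSON
#' @param fit a `gs_reml_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(
    list(beta = as.list(fit$beta), sigma_u2 = fit$sigma_u2,
         sigma_e2 = fit$sigma_e2, h2 = fit$h2,
         reml_loglik = fit$reml_loglik, n_train = length(fit$train_ids)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
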