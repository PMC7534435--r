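# REML variance components, heritability, and gBLUP prediction.

# Direct matrix-form restricted log-likelihood: V = lambda*K + I, profiled
# over beta and the residual scale, evaluated with dense solves/determinants.
# Mirrors the model definition (kernel standardised to mean diagonal 1) but
# shares no code path with restricted_loglik().
direct_rll <- function(lambda, K, y, X) {
  K <- K / mean(diag(K)) + diag(1e-8, nrow(K))   # same kernel preparation
  n <- length(y)
  p <- ncol(X)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(XtViX, logarithm = TRUE)$modulus[1])
}

test_that("spectral restricted likelihood agrees with the matrix form", {
  g <- rand_geno(10, 60, seed = 31)
  K <- kinship(g)
  set.seed(32)
  y <- rnorm(10)
  X <- cbind(1, rnorm(10))
  Ks <- K / mean(diag(K))
  eig <- eigen(Ks + diag(1e-8, 10), symmetric = TRUE)
  yr <- drop(crossprod(eig$vectors, y))
  xr <- crossprod(eig$vectors, X)
  for (lam in c(0.01, 0.5, 3, 40)) {
    # difference two lambdas to cancel any additive constant
    d_spec <- restricted_loglik(lam, pmax(eig$values, 0), yr, xr) -
      restricted_loglik(1, pmax(eig$values, 0), yr, xr)
    d_mat <- direct_rll(lam, K, y, X) - direct_rll(1, K, y, X)
    expect_equal(d_spec, d_mat, tolerance = 1e-8)
  }
  expect_error(restricted_loglik(-1, eig$values, yr, xr),
               class = "gs_domain_error")
})

test_that("with K = I the profile reduces to the (1+lambda) closed form", {
  n <- 12
  set.seed(33)
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  d <- rep(1, n)
  ols <- lm.fit(X, y)
  rss <- sum(ols$residuals^2)
  closed <- function(lam) {
    sigma2 <- rss / ((1 + lam) * (n - 1))
    -0.5 * ((n - 1) * log(2 * pi * sigma2) + (n - 1) + n * log(1 + lam) +
              log(n / (1 + lam)))
  }
  for (lam in c(0.1, 1, 10))
    expect_equal(restricted_loglik(lam, d, y, drop(X)), closed(lam),
                 tolerance = 1e-10)
})

test_that("the fitted variance ratio is a local maximum of the profile", {
  sim <- simulate_genotypes(subpop_sizes = c(A = 40), n_markers = 300,
                            fst = 0, seed = 35)
  g <- sim$genotypes
  K <- kinship(g)
  ph <- simulate_phenotypes(g, "t", n_qtl = 100, h2 = 0.6, seed = 36)
  y <- line_means(ph$phenotypes, "t")[rownames(K)]
  fit <- reml_fit(y, K = K)
  Ks <- K / fit$kernel_scale
  eig <- eigen(Ks + diag(1e-8, nrow(K)), symmetric = TRUE)
  yr <- drop(crossprod(eig$vectors, y))
  xr <- crossprod(eig$vectors, matrix(1, nrow(K), 1))
  ll_at <- function(lam) restricted_loglik(lam, pmax(eig$values, 0), yr, xr)
  expect_lte(ll_at(fit$lambda * 1.1), fit$reml_loglik + 1e-6)
  expect_lte(ll_at(fit$lambda * 0.9), fit$reml_loglik + 1e-6)
  # heritability accessor is exactly the component ratio
  expect_equal(heritability(fit), fit$sigma_u2 / (fit$sigma_u2 + fit$sigma_e2))
  expect_equal(fit$h2, heritability(fit), tolerance = 1e-12)
})

test_that("boundary cases: pure noise fits near h2 = 0, noiseless genetic
          signal near 1", {
  sim <- simulate_genotypes(subpop_sizes = c(A = 300), n_markers = 400,
                            fst = 0, seed = 40)
  K <- kinship(sim$genotypes)
  n <- nrow(K)
  h2_null <- vapply(1:20, function(s) {
    set.seed(400 + s)
    reml_fit(rnorm(n), K = K)$h2
  }, numeric(1))
  expect_lt(mean(h2_null), 0.05)

  set.seed(41)
  L <- t(chol(K / mean(diag(K)) + diag(1e-6, n)))
  y <- drop(L %*% rnorm(n))          # exact draw from N(0, K), no noise
  expect_gt(reml_fit(y, K = K)$h2, 0.9)
})

test_that("estimates are scale-equivariant and shift-invariant", {
  g <- rand_geno(40, 150, seed = 45)
  K <- kinship(g)
  pcs <- marker_pca(g, 2)
  set.seed(46)
  y <- drop(t(chol(K / mean(diag(K)) + diag(1e-6, 40))) %*% rnorm(40)) +
    rnorm(40, sd = 0.7)
  f1 <- reml_fit(y, x = pcs$scores, K = K)
  f2 <- reml_fit(3 * y, x = pcs$scores, K = K)
  expect_equal(f2$beta, 3 * f1$beta, tolerance = 1e-4)
  expect_equal(f2$u_hat, 3 * f1$u_hat, tolerance = 1e-4)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-4)
  f3 <- reml_fit(y + 11, x = pcs$scores, K = K)
  expect_equal(unname(f3$beta[1] - f1$beta[1]), 11, tolerance = 1e-4)
  expect_equal(unname(f3$beta[-1]), unname(f1$beta[-1]), tolerance = 1e-4)
  expect_equal(f3$u_hat, f1$u_hat, tolerance = 1e-4)
})

test_that("input validation: singular design, non-finite phenotypes, bad K", {
  g <- rand_geno(20, 60, seed = 47)
  K <- kinship(g)
  y <- rnorm(20)
  expect_error(reml_fit(y, x = cbind(1, 1:20 * 0), K = K),
               class = "gs_design_error")
  expect_error(reml_fit(c(y[-1], NA), K = K), class = "gs_validation_error")
  bad <- K; bad[1, 2] <- bad[1, 2] + 10; bad[2, 1] <- bad[1, 2]
  bad <- bad - diag(5, 20)
  expect_error(reml_fit(y, K = bad), class = "gs_kinship_error")
})

test_that("gBLUP prediction: empty test set, duplicated kinship rows", {
  g <- rand_geno(30, 100, seed = 50)
  dos <- g$dosages
  dos[30, ] <- dos[1, ]               # line 30 duplicates line 1
  K <- kinship(genotype_matrix(dos))
  ph <- simulate_phenotypes(genotype_matrix(dos), "t", n_qtl = 40, h2 = 0.7,
                            seed = 51)
  y <- line_means(ph$phenotypes, "t")[rownames(K)]
  expect_length(gblup_predict(y[1:29], K_full = K, train_idx = 1:29,
                              test_idx = integer(0)), 0)
  pred <- gblup_predict(y[1:29], K_full = K, train_idx = 1:29, test_idx = 30,
                        include_fixed = FALSE)
  fit <- attr(pred, "fit")
  expect_equal(as.numeric(pred), unname(fit$u_hat[1]), tolerance = 1e-6)
  expect_error(gblup_predict(y[0], K_full = K, train_idx = integer(0),
                             test_idx = 1), class = "gs_validation_error")
  expect_error(gblup_predict(y[1:10], K_full = K, train_idx = 1:10,
                             test_idx = 10), class = "gs_validation_error")
})

test_that("gBLUP equals ridge regression on marker effects", {
  g <- rand_geno(60, 300, seed = 55)
  X <- g$dosages
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p)
  cdenom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / cdenom
  dimnames(K) <- list(rownames(X), rownames(X))
  set.seed(56)
  y_all <- drop(Z %*% rnorm(300, sd = 0.05)) + rnorm(60, sd = 0.5)
  tr <- 1:45; te <- 46:60
  pred <- gblup_predict(y_all[tr], K_full = K, train_idx = tr, test_idx = te)
  fit <- attr(pred, "fit")
  # ridge oracle: penalty sigma_e^2 * c / sigma_u^2 on the training kernel,
  # with c the (standardised) cross-product denominator
  theta <- cdenom * fit$kernel_scale / fit$lambda
  r <- y_all[tr] - fit$beta[1]
  m_hat <- crossprod(Z[tr, ], solve(tcrossprod(Z[tr, ]) + diag(theta, 45), r))
  ridge <- fit$beta[1] + drop(Z[te, ] %*% m_hat)
  expect_equal(as.numeric(pred), unname(ridge), tolerance = 1e-6)
})

test_that("heritability accessor handles degenerate and symmetric cases", {
  fake <- structure(list(sigma_u2 = 0, sigma_e2 = 1), class = "gs_reml_fit")
  expect_equal(heritability(fake), 0)
  fake$sigma_u2 <- 1
  expect_equal(heritability(fake), 0.5)
  fake$sigma_u2 <- 0; fake$sigma_e2 <- 0
  expect_error(heritability(fake), class = "gs_degenerate_error")
})
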