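# The four compared prediction models behind one dispatch contract:
#   QTN10           marker-assisted selection: top-k scan hits, joint OLS
#   PC_ONLY         fixed-effect regression on leading principal components
#   KINSHIP         gBLUP with intercept-only fixed effects
#   PC_PLUS_KINSHIP gBLUP with PC covariates (fixed) plus the kinship kernel
# All four train exclusively on training-set phenotypes; test-set genotypes
# (dosages, kinship rows, PC scores) are used for prediction, never test
# phenotypes.

MODEL_KINDS <- c("QTN10", "PC_ONLY", "KINSHIP", "PC_PLUS_KINSHIP")

#' Specify a prediction model
#'
#' @param kind one of `"QTN10"`, `"PC_ONLY"`, `"KINSHIP"`,
#'   `"PC_PLUS_KINSHIP"`.
#' @param n_qtns number of top scan hits used by `QTN10` (default 10).
#' @param n_pcs number of principal components used as covariates (default 3).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = MODEL_KINDS, n_qtns = 10, n_pcs = 3) {
  kind <- match.arg(kind)
  stopifnot(n_qtns >= 1, n_pcs >= 1)
  structure(list(kind = kind, n_qtns = as.integer(n_qtns),
                 n_pcs = as.integer(n_pcs)), class = "model_spec")
}

#' Predict test-line phenotypes under one of the four models
#'
#' `QTN10` runs the association scan on the training lines, selects the top
#' `n_qtns` markers, fits a joint ordinary least squares of the training
#' phenotype on those dosages, and predicts test lines from their dosages
#' (collinear QTNs are dropped with a warning). `PC_ONLY` fits OLS on the
#' leading PC scores. `KINSHIP` is gBLUP with an intercept only;
#' `PC_PLUS_KINSHIP` is gBLUP with the PCs as fixed covariates.
#'
#' @param model a [model_spec()] (or a kind string).
#' @param y_train training phenotypes, aligned with `train_idx`.
#' @param g `geno_matrix` over the whole panel (complete; needed by `QTN10`).
#' @param K kinship matrix over the whole panel.
#' @param pcs `pc_basis` over the whole panel.
#' @param train_idx,test_idx disjoint integer index vectors.
#' @param include_fixed passed to [gblup_predict()] for the kinship models.
#'
#' @details With very small training sets (deep within-subpopulation masking)
#' the full covariate design can exceed the available degrees of freedom; the
#' PC count is then truncated to `n_train - 3` (possibly zero, leaving an
#' intercept-only fixed part) with a warning, so the factorial designs remain
#' runnable down to a handful of training lines.
#'
#' @return numeric predictions in `test_idx` order.
#' @export
predict_model <- function(model, y_train, g, K, pcs, train_idx, test_idx,
                          include_fixed = TRUE) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "model_spec"))
  train_idx <- as.integer(train_idx)
  test_idx <- as.integer(test_idx)
  if (length(intersect(train_idx, test_idx)))
    gs_error("train and test sets overlap", "gs_validation_error")
  n_pcs_eff <- min(model$n_pcs, ncol(pcs$scores),
                   max(0L, length(train_idx) - 3L))
  if (model$kind != "QTN10" && model$kind != "KINSHIP" &&
      n_pcs_eff < min(model$n_pcs, ncol(pcs$scores)))
    warning(sprintf("training set of %d supports only %d PC covariate(s)",
                    length(train_idx), n_pcs_eff))

  switch(model$kind,
    QTN10 = {
      scan <- gwas_scan(y_train, g, pcs, train_idx, n_pcs = model$n_pcs)
      qtn <- select_top_qtns(scan, model$n_qtns)
      Xtr <- cbind(1, g$dosages[train_idx, qtn, drop = FALSE])
      Xte <- cbind(1, g$dosages[test_idx, qtn, drop = FALSE])
      fit <- stats::lm.fit(Xtr, y_train)
      coefs <- fit$coefficients
      if (anyNA(coefs)) {
        warning(sprintf("dropped %d collinear QTN column(s) from the MAS design",
                        sum(is.na(coefs))))
        coefs[is.na(coefs)] <- 0
      }
      drop(Xte %*% coefs)
    },
    PC_ONLY = {
      S <- pcs$scores[, seq_len(n_pcs_eff), drop = FALSE]
      Xtr <- cbind(1, S[train_idx, , drop = FALSE])
      fit <- stats::lm.fit(Xtr, y_train)
      drop(cbind(1, S[test_idx, , drop = FALSE]) %*% fit$coefficients)
    },
    KINSHIP = {
      as.numeric(gblup_predict(y_train, x_full = NULL, K_full = K,
                               train_idx = train_idx, test_idx = test_idx,
                               include_fixed = include_fixed))
    },
    PC_PLUS_KINSHIP = {
      S <- if (n_pcs_eff > 0)
        pcs$scores[, seq_len(n_pcs_eff), drop = FALSE]
      as.numeric(gblup_predict(y_train, x_full = S, K_full = K,
                               train_idx = train_idx, test_idx = test_idx,
                               include_fixed = include_fixed))
    })
}
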