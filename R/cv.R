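# Cross-validation designs over a subpopulation-stratified panel.
#
# Three sampling scenarios:
#   WHOLE          test lines drawn from the full panel, subpopulations ignored
#   WITHIN_SUBPOP  test AND training lines both from one target subpopulation
#   ACROSS_SUBPOP  test lines from the target subpopulation; training = the
#                  rest of that subpopulation plus every other subpopulation
# Test-set size is round-half-away-from-zero of proportion * pool, clamped so
# training is never empty (WITHIN/WHOLE); ACROSS additionally supports masking
# an entire subpopulation, since its training set stays non-empty regardless.

SCENARIOS <- c("WHOLE", "WITHIN_SUBPOP", "ACROSS_SUBPOP")

#' Build one train/test split
#'
#' Sampling is uniform without replacement and seeded deterministically from
#' `(seed, scenario, target_subpop, proportion, replicate)` via [cell_seed()],
#' so any cell of a factorial design reproduces in isolation.
#'
#' @param scenario `"WHOLE"`, `"WITHIN_SUBPOP"` or `"ACROSS_SUBPOP"`.
#' @param subpops named character vector (line id -> subpopulation label) in
#'   panel order; indices in the result refer to this order.
#' @param target_subpop subpopulation label; required for the two
#'   subpopulation scenarios.
#' @param proportion testing proportion in `[0.05, 0.95]` (`ACROSS` accepts up
#'   to 1).
#' @param replicate replicate index (folded into the seed).
#' @param seed master seed.
#' @return an object of class `split_plan` with `train_idx`, `test_idx` and
#'   the cell coordinates.
#' @export
make_split <- function(scenario = SCENARIOS, subpops, target_subpop = NULL,
                       proportion, replicate = 1, seed = 1) {
  scenario <- match.arg(scenario)
  n <- length(subpops)
  all_idx <- seq_len(n)
  pmax_allowed <- if (scenario == "ACROSS_SUBPOP") 1 else 0.95
  if (proportion < 0.05 || proportion > pmax_allowed)
    gs_error(sprintf("proportion %.2f outside [0.05, %.2f] for %s",
                     proportion, pmax_allowed, scenario), "gs_validation_error")
  if (scenario != "WHOLE") {
    if (is.null(target_subpop))
      gs_error("target_subpop is required for subpopulation scenarios",
               "gs_validation_error")
    pool <- which(subpops == target_subpop)
    if (!length(pool))
      gs_error(paste0("unknown subpopulation: ", target_subpop),
               "gs_validation_error")
    if (scenario == "WITHIN_SUBPOP" && length(pool) < 3)
      gs_error(sprintf("subpopulation %s has %d lines; within-subpopulation CV needs >= 3",
                       target_subpop, length(pool)), "gs_infeasible_error")
  } else {
    pool <- all_idx
  }
  np <- length(pool)
  n_test <- round_half_up(proportion * np)
  hi <- if (scenario == "ACROSS_SUBPOP") np else np - 1L
  n_test <- min(max(n_test, 1L), hi)

  s <- cell_seed(seed, scenario, target_subpop %||% "", proportion, replicate)
  test_idx <- with_seed(s, sort(sample(pool, n_test)))
  train_idx <- switch(scenario,
    WHOLE = setdiff(all_idx, test_idx),
    WITHIN_SUBPOP = setdiff(pool, test_idx),
    ACROSS_SUBPOP = sort(c(setdiff(pool, test_idx), setdiff(all_idx, pool))))

  structure(list(scenario = scenario, target_subpop = target_subpop,
                 proportion = proportion, replicate = replicate, seed = seed,
                 train_idx = train_idx, test_idx = test_idx),
            class = "split_plan")
}

#' Pearson prediction accuracy
#'
#' The sample Pearson correlation between predicted and observed values of
#' the testing population. Undefined (returns `NA`) when either vector is
#' constant or fewer than 3 finite pairs remain.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    gs_error("predicted and observed lengths differ", "gs_validation_error")
  if (length(predicted) < 2)
    gs_error("need at least 2 pairs", "gs_validation_error")
  ok <- is.finite(predicted) & is.finite(observed)
  if (sum(ok) < 3) return(NA_real_)
  p <- predicted[ok]; o <- observed[ok]
  if (stats::sd(p) == 0 || stats::sd(o) == 0) return(NA_real_)
  stats::cor(p, o)
}

#' Bundle a panel for analysis
#'
#' Aligns genotypes, phenotypes and subpopulation labels, computes the
#' kinship matrix, the leading principal components, and the per-line trait
#' means used by every downstream fit.
#'
#' @param g `geno_matrix` (complete; run [impute_missing()] first if needed).
#' @param pheno phenotype table (see [phenotype_table()]).
#' @param subpops named character vector line id -> subpopulation label;
#'   every genotyped line must have exactly one label.
#' @param n_pcs number of principal components (default 3).
#' @param kinship_method passed to [kinship()].
#' @return an object of class `gs_panel`: `geno`, `pheno`, `subpops`, `K`,
#'   `pcs`, and `Y` (lines x traits matrix of line means; `NA` where a line
#'   has no observations).
#' @export
build_panel <- function(g, pheno, subpops, n_pcs = 3,
                        kinship_method = "vanraden") {
  stopifnot(inherits(g, "geno_matrix"))
  pheno <- phenotype_table(pheno)
  ids <- line_ids(g)
  missing_lab <- setdiff(ids, names(subpops))
  if (length(missing_lab))
    gs_error(paste0("lines without subpopulation label: ",
                    paste(utils::head(missing_lab, 5), collapse = ", ")),
             "gs_validation_error")
  subpops <- subpops[ids]
  traits <- trait_names(pheno)
  Y <- matrix(NA_real_, length(ids), length(traits),
              dimnames = list(ids, traits))
  for (tr in traits) {
    m <- line_means(pheno, tr)
    common <- intersect(ids, names(m))
    Y[common, tr] <- m[common]
  }
  structure(list(geno = g, pheno = pheno, subpops = subpops,
                 K = kinship(g, kinship_method),
                 pcs = marker_pca(g, n_pcs), Y = Y),
            class = "gs_panel")
}

#' @export
print.gs_panel <- function(x, ...) {
  cat(sprintf("gs_panel: %d lines, %d markers, %d traits; subpopulations: %s\n",
              n_lines(x$geno), n_markers(x$geno), ncol(x$Y),
              paste(sprintf("%s=%d", names(table(x$subpops)), table(x$subpops)),
                    collapse = ", ")))
  invisible(x)
}

# Run one model on one split for one trait; returns NA accuracy (with a
# message) rather than aborting the whole factorial when a cell fails.
cv_cell <- function(panel, model, trait, split, include_fixed = TRUE) {
  y <- panel$Y[, trait]
  tr <- split$train_idx[!is.na(y[split$train_idx])]
  te <- split$test_idx[!is.na(y[split$test_idx])]
  acc <- tryCatch({
    pred <- predict_model(model, y[tr], panel$geno, panel$K, panel$pcs,
                          tr, te, include_fixed = include_fixed)
    pearson_accuracy(pred, y[te])
  }, error = function(e) {
    message(sprintf("cell failed (%s, %s): %s", model$kind, trait,
                    conditionMessage(e)))
    NA_real_
  })
  data.frame(model = model$kind, trait = trait,
             scenario = split$scenario,
             subpop = split$target_subpop %||% NA_character_,
             proportion = split$proportion, replicate = split$replicate,
             n_train = length(tr), n_test = length(te), accuracy = acc,
             stringsAsFactors = FALSE)
}

#' Compare prediction models on random whole-panel splits
#'
#' The model-selection design: for each replicate, one whole-panel split
#' (default 20% testing) shared by all models and traits (a paired design, so
#' model contrasts are within-split), accuracies recorded per
#' (model, trait, replicate).
#'
#' @param panel a [build_panel()] result.
#' @param models list of [model_spec()] objects or kind strings; default all
#'   four.
#' @param traits traits to evaluate; default all traits in the panel.
#' @param n_replicates number of random splits (default 20).
#' @param proportion testing proportion (default 0.2).
#' @param seed master seed.
#' @param include_fixed passed to the kinship models.
#' @return data frame of class `cv_result` (one row per
#'   model x trait x replicate).
#' @export
run_model_comparison <- function(panel, models = as.list(MODEL_KINDS),
                                 traits = NULL, n_replicates = 20,
                                 proportion = 0.2, seed = 1,
                                 include_fixed = TRUE) {
  stopifnot(inherits(panel, "gs_panel"))
  traits <- traits %||% colnames(panel$Y)
  models <- lapply(models, function(m) if (is.character(m)) model_spec(m) else m)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    split <- make_split("WHOLE", panel$subpops, proportion = proportion,
                        replicate = r, seed = seed)
    rows <- lapply(traits, function(tr)
      do.call(rbind, lapply(models, function(m)
        cv_cell(panel, m, tr, split, include_fixed))))
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_result", "data.frame")
  res
}

#' Assess gBLUP accuracy across scenarios, proportions and subpopulations
#'
#' Full factorial over scenario x subpopulation (where applicable) x testing
#' proportion x replicate, with one model (default gBLUP with PC covariates,
#' the best performer of the model comparison). Infeasible cells (e.g.
#' within-subpopulation CV on a subpopulation below 3 lines) are skipped with
#' a message.
#'
#' @param panel a [build_panel()] result.
#' @param scenarios subset of `c("WHOLE", "WITHIN_SUBPOP", "ACROSS_SUBPOP")`.
#' @param proportions testing proportions (default 0.1 to 0.9 by 0.1).
#' @param n_replicates replicates per cell (default 100).
#' @param traits traits to evaluate; default all.
#' @param model a [model_spec()]; default `PC_PLUS_KINSHIP`.
#' @param seed master seed.
#' @param include_fixed passed to the kinship models.
#' @return data frame of class `cv_result`.
#' @export
run_gblup_assessment <- function(panel, scenarios = SCENARIOS,
                                 proportions = seq(0.1, 0.9, by = 0.1),
                                 n_replicates = 100, traits = NULL,
                                 model = model_spec("PC_PLUS_KINSHIP"),
                                 seed = 1, include_fixed = TRUE) {
  stopifnot(inherits(panel, "gs_panel"))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  traits <- traits %||% colnames(panel$Y)
  labels <- unique(panel$subpops)
  out <- list()
  for (sc in scenarios) {
    targets <- if (sc == "WHOLE") list(NULL) else as.list(labels)
    for (tg in targets) {
      for (pr in proportions) {
        for (r in seq_len(n_replicates)) {
          split <- tryCatch(
            make_split(sc, panel$subpops, target_subpop = tg,
                       proportion = pr, replicate = r, seed = seed),
            gs_infeasible_error = function(e) {
              if (r == 1) message("skipping cell: ", conditionMessage(e))
              NULL
            })
          if (is.null(split)) break
          out[[length(out) + 1L]] <- do.call(rbind, lapply(traits, function(tr)
            cv_cell(panel, model, tr, split, include_fixed)))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_result", "data.frame")
  res
}

#' Summarise cross-validation accuracies
#'
#' Mean, standard deviation and effective replicate count (cells with a
#' defined correlation) per (scenario, model, trait, subpopulation,
#' proportion).
#'
#' @param res a `cv_result` data frame.
#' @return summary data frame, one row per cell.
#' @export
summarize_cv <- function(res) {
  keys <- intersect(c("scenario", "model", "trait", "subpop", "proportion"),
                    names(res))
  res <- as.data.frame(res)
  if ("subpop" %in% keys) res$subpop[is.na(res$subpop)] <- "ALL"
  agg <- stats::aggregate(
    res["accuracy"], res[keys],
    function(a) c(mean = mean(a, na.rm = TRUE),
                  sd = stats::sd(a, na.rm = TRUE),
                  n_effective = sum(!is.na(a))))
  out <- cbind(agg[keys], as.data.frame(agg$accuracy))
  names(out)[names(out) == "mean"] <- "mean_accuracy"
  names(out)[names(out) == "sd"] <- "sd_accuracy"
  out[order(out$scenario %||% "", out$trait), ]
}

#' Heritability report per trait and environment subset
#'
#' For each trait and each environment subset (every single environment plus
#' all environments combined), fits the mixed model to the corresponding line
#' means with the leading principal components as fixed covariates and
#' reports the variance components and heritability. The combined column is
#' computed on across-environment line means, not by averaging
#' per-environment heritabilities. Subsets with fewer than 10 phenotyped
#' lines are skipped with a warning.
#'
#' @param panel a [build_panel()] result.
#' @param traits traits to report; default all.
#' @return data frame with columns `trait`, `environment`, `n`, `sigma_u2`,
#'   `sigma_e2`, `h2`.
#' @export
heritability_report <- function(panel, traits = NULL) {
  stopifnot(inherits(panel, "gs_panel"))
  traits <- traits %||% colnames(panel$Y)
  envs <- sort(unique(panel$pheno$env))
  subsets <- c(as.list(envs), list(NULL))
  names(subsets) <- c(envs, "combined")
  ids <- line_ids(panel$geno)
  rows <- list()
  for (tr in traits) {
    if (!tr %in% panel$pheno$trait) {
      warning("trait not in phenotype table, skipped: ", tr)
      next
    }
    for (en in names(subsets)) {
      m <- line_means(panel$pheno, tr, environments = subsets[[en]])
      common <- intersect(ids, names(m))
      if (length(common) < 10) {
        warning(sprintf("skipping %s / %s: only %d phenotyped lines",
                        tr, en, length(common)))
        next
      }
      idx <- match(common, ids)
      fit <- reml_fit(m[common], x = panel$pcs$scores[idx, , drop = FALSE],
                      K = panel$K[idx, idx])
      rows[[length(rows) + 1L]] <-
        data.frame(trait = tr, environment = en, n = length(common),
                   sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
                   h2 = fit$h2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
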