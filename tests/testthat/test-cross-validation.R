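# Split construction, accuracy, and the CV harnesses.

# subpopulation labels shaped like the reference panel: 27/67/193/211
panel_labels <- function() {
  sizes <- c(SS = 27, NSS = 67, TST = 193, MIXED = 211)
  setNames(rep(names(sizes), sizes),
           sprintf("L%03d", seq_len(sum(sizes))))
}

test_that("whole-panel split at 20% gives 100 test / 398 train of 498", {
  sp <- make_split("WHOLE", panel_labels(), proportion = 0.2,
                   replicate = 1, seed = 42)
  expect_length(sp$test_idx, 100)
  expect_length(sp$train_idx, 398)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:498)
})

test_that("within-subpopulation split keeps both sides inside the target", {
  labs <- panel_labels()
  sp <- make_split("WITHIN_SUBPOP", labs, target_subpop = "SS",
                   proportion = 0.1, replicate = 1, seed = 42)
  expect_length(sp$test_idx, 3)      # round(0.1 * 27)
  expect_length(sp$train_idx, 24)
  expect_true(all(labs[sp$test_idx] == "SS"))
  expect_true(all(labs[sp$train_idx] == "SS"))
  # training never empty: extreme proportion clamps to pool - 1
  sp90 <- make_split("WITHIN_SUBPOP", labs, target_subpop = "SS",
                     proportion = 0.95, replicate = 1, seed = 42)
  expect_length(sp90$test_idx, 26)
  expect_length(sp90$train_idx, 1)
  tiny <- setNames(c("A", "A", "B", "B", "B"), paste0("x", 1:5))
  expect_error(make_split("WITHIN_SUBPOP", tiny, target_subpop = "A",
                          proportion = 0.5, seed = 1),
               class = "gs_infeasible_error")
})

test_that("across-subpopulation split trains on the remainder plus all other
          subpopulations, up to full masking", {
  labs <- panel_labels()
  sp <- make_split("ACROSS_SUBPOP", labs, target_subpop = "NSS",
                   proportion = 0.3, replicate = 2, seed = 42)
  expect_length(sp$test_idx, 20)     # round(0.3 * 67)
  expect_true(all(labs[sp$test_idx] == "NSS"))
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:498)
  # the across design extends to masking an entire subpopulation
  spfull <- make_split("ACROSS_SUBPOP", labs, target_subpop = "SS",
                       proportion = 1, replicate = 1, seed = 42)
  expect_length(spfull$test_idx, 27)
  expect_true(all(labs[spfull$train_idx] != "SS"))
  expect_error(make_split("WHOLE", labs, proportion = 1, seed = 1),
               class = "gs_validation_error")
})

test_that("splits are deterministic in the master seed and vary by replicate", {
  labs <- panel_labels()
  a <- make_split("WHOLE", labs, proportion = 0.2, replicate = 3, seed = 9)
  b <- make_split("WHOLE", labs, proportion = 0.2, replicate = 3, seed = 9)
  c <- make_split("WHOLE", labs, proportion = 0.2, replicate = 4, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$test_idx, c$test_idx))
  # seeding does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_split("WHOLE", labs, proportion = 0.2, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("Pearson accuracy matches hand-computed values", {
  obs <- c(4, 7, 1, 3)
  expect_equal(pearson_accuracy(obs, obs), 1)
  expect_equal(pearson_accuracy(-obs + 7, obs), -1)
  expect_equal(pearson_accuracy(c(1, 2, 3), c(2, 2, 5)), sqrt(3) / 2)
  expect_true(is.na(pearson_accuracy(rep(1, 5), rnorm(5))))
  expect_error(pearson_accuracy(1:3, 1:4), class = "gs_validation_error")
})

small_panel <- function() {
  sim <- simulate_genotypes(subpop_sizes = c(A = 35, B = 35, MIXED = 30),
                            n_markers = 250, seed = 77)
  ph <- simulate_phenotypes(sim$genotypes, "t", n_qtl = 60, h2 = 0.6,
                            seed = 78)
  build_panel(sim$genotypes, ph$phenotypes, sim$subpops)
}

test_that("model comparison shares one split per replicate (paired design)", {
  panel <- small_panel()
  res <- run_model_comparison(panel, models = list("KINSHIP", "KINSHIP"),
                              n_replicates = 3, seed = 5)
  acc <- split(res$accuracy, seq_len(nrow(res)) %% 2)
  expect_equal(acc[["1"]], acc[["0"]])            # identical models, identical cells
  expect_equal(nrow(res), 3 * 2)
  res1 <- run_model_comparison(panel, models = list("PC_ONLY"),
                               n_replicates = 1, seed = 5)
  expect_equal(nrow(res1), 1)                     # one cell per model x trait
  # reruns with the same master seed reproduce exactly
  res2 <- run_model_comparison(panel, models = list("PC_ONLY"),
                               n_replicates = 1, seed = 5)
  expect_identical(res1, res2)
})

test_that("the assessment factorial covers scenarios and skips infeasible
          cells without failing", {
  panel <- small_panel()
  res <- run_gblup_assessment(panel, scenarios = c("WHOLE", "WITHIN_SUBPOP"),
                              proportions = c(0.2, 0.8), n_replicates = 2,
                              seed = 6)
  expect_true(all(c("WHOLE", "WITHIN_SUBPOP") %in% res$scenario))
  expect_true(all(res$n_train + res$n_test <= 100))
  within_rows <- res[res$scenario == "WITHIN_SUBPOP", ]
  expect_setequal(unique(within_rows$subpop), c("A", "B", "MIXED"))
  smry <- summarize_cv(res)
  expect_true(all(c("mean_accuracy", "sd_accuracy", "n_effective") %in%
                    names(smry)))
  # summary means agree with a manual aggregate
  cell <- res[res$scenario == "WHOLE" & res$proportion == 0.2, "accuracy"]
  got <- smry[smry$scenario == "WHOLE" & smry$proportion == 0.2,
              "mean_accuracy"]
  expect_equal(got, mean(cell, na.rm = TRUE))
})

test_that("combined-environment heritability is computed on pooled line means,
          not averaged per-environment estimates", {
  sim <- simulate_genotypes(subpop_sizes = c(A = 60), n_markers = 200,
                            fst = 0, seed = 80)
  g <- sim$genotypes
  ph <- simulate_phenotypes(g, "t", n_qtl = 50, h2 = 0.7, n_env = 2,
                            seed = 81)
  # inflate noise in E2 only, so per-env and combined h2 must differ
  tab <- ph$phenotypes
  e2 <- tab$env == "E2"
  set.seed(82)
  tab$value[e2] <- tab$value[e2] + rnorm(sum(e2), sd = 5 * sd(tab$value))
  panel <- build_panel(g, phenotype_table(tab), sim$subpops)
  rep <- heritability_report(panel)
  expect_setequal(rep$environment, c("E1", "E2", "combined"))
  h <- setNames(rep$h2, rep$environment)
  expect_false(isTRUE(all.equal(h[["combined"]],
                                mean(c(h[["E1"]], h[["E2"]])))))
  # direct check against a pooled-mean fit
  ym <- line_means(panel$pheno, "t")[rownames(panel$K)]
  fit <- reml_fit(ym, x = panel$pcs$scores, K = panel$K)
  expect_equal(h[["combined"]], fit$h2, tolerance = 1e-8)
  expect_warning(heritability_report(panel, traits = c("t", "ghost")),
                 "ghost")
})
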