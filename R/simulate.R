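# Synthetic structured panels and polygenic traits with known ground truth.
#
# Genotypes follow a Balding-Nichols construction: each marker has an
# ancestral frequency p0, and each "pure" subpopulation draws its own
# frequency from Beta(p0 (1-fst)/fst, (1-p0)(1-fst)/fst), whose mean is p0
# and whose spread is governed by the differentiation parameter fst. A
# subpopulation named "MIXED" is generated as per-line admixture of the pure
# subpopulations' frequencies (admixture proportions ~ Dirichlet(1, ..., 1)),
# giving it genuinely intermediate kinship with the others. Lines are inbred:
# with the default inbreeding = 1 every locus is homozygous (dosage 0 or 2).

#' Simulate a structured inbred panel
#'
#' @param subpop_sizes named integer vector of lines per subpopulation;
#'   default `c(SS = 27, NSS = 67, TST = 193, MIXED = 211)`. A subpopulation
#'   named `"MIXED"` (when others exist) is built by admixture of the rest.
#' @param n_markers number of markers to attempt (default 2000). Markers
#'   whose panel-wide MAF falls below 0.05 are resampled up to 100 times and
#'   then dropped, so the realised count can be slightly lower.
#' @param fst differentiation among pure subpopulations, in `[0, 0.5]`
#'   (default 0.15); 0 gives an unstructured panel.
#' @param maf_range range of ancestral allele frequencies
#'   (default `c(0.05, 0.5)`).
#' @param inbreeding probability a line is fully homozygous at a locus
#'   (default 1, fully inbred lines; 0 gives Hardy-Weinberg draws).
#' @param seed integer seed; output is deterministic given the full
#'   configuration.
#' @return list with `genotypes` (a [genotype_matrix()]), `subpops` (named
#'   character vector), and `freqs` (list: `ancestral` per-marker p0,
#'   `subpop` matrix of per-subpopulation frequencies).
#' @export
simulate_genotypes <- function(subpop_sizes = c(SS = 27, NSS = 67, TST = 193,
                                                MIXED = 211),
                               n_markers = 2000, fst = 0.15,
                               maf_range = c(0.05, 0.5), inbreeding = 1,
                               seed = 1) {
  if (is.null(names(subpop_sizes)) || any(names(subpop_sizes) == ""))
    gs_error("subpop_sizes must be a named vector", "gs_config_error")
  if (sum(subpop_sizes) < 10)
    gs_error("panel must have at least 10 lines", "gs_config_error")
  if (fst < 0 || fst > 0.5)
    gs_error("fst must lie in [0, 0.5]", "gs_config_error")
  if (diff(maf_range) <= 0 && fst == 0)
    gs_error("zero-width maf_range with fst = 0 gives constant markers",
             "gs_config_error")

  labels <- names(subpop_sizes)
  admixed <- if ("MIXED" %in% labels && length(labels) > 1) "MIXED" else NULL
  pure <- setdiff(labels, admixed)
  line_lab <- rep(labels, subpop_sizes)
  ids <- unlist(lapply(labels, function(l)
    sprintf("%s_%03d", l, seq_len(subpop_sizes[[l]]))))

  with_seed(seed, {
    # fixed per-line ancestry of admixed lines, shared across resampling rounds
    A <- NULL
    if (!is.null(admixed)) {
      nm <- subpop_sizes[[admixed]]
      A <- matrix(stats::rexp(nm * length(pure)), nm, length(pure))
      A <- A / rowSums(A)
      colnames(A) <- pure
    }

    draw_markers <- function(b) {
      p0 <- stats::runif(b, maf_range[1], maf_range[2])
      P <- matrix(NA_real_, length(pure), b, dimnames = list(pure, NULL))
      for (s in pure) {
        P[s, ] <- if (fst > 0)
          stats::rbeta(b, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
        else p0
      }
      dos <- matrix(NA_real_, length(line_lab), b)
      for (s in pure) {
        rows <- which(line_lab == s)
        pf <- matrix(P[s, ], length(rows), b, byrow = TRUE)
        dos[rows, ] <- draw_dosage(pf, inbreeding)
      }
      if (!is.null(admixed)) {
        rows <- which(line_lab == admixed)
        pf <- A %*% P      # per-line expected frequency
        dos[rows, ] <- draw_dosage(pf, inbreeding)
      }
      list(p0 = p0, P = P, dos = dos)
    }

    mk <- draw_markers(n_markers)
    for (attempt in seq_len(100)) {
      maf <- compute_maf(mk$dos)
      bad <- which(maf < 0.05)
      if (!length(bad)) break
      redo <- draw_markers(length(bad))
      mk$p0[bad] <- redo$p0
      mk$P[, bad] <- redo$P
      mk$dos[, bad] <- redo$dos
    }
    maf <- compute_maf(mk$dos)
    keep <- maf >= 0.05
    if (!all(keep))
      message(sprintf("simulate_genotypes: dropped %d marker(s) still below MAF 0.05 after resampling",
                      sum(!keep)))
    dos <- mk$dos[, keep, drop = FALSE]

    m <- ncol(dos)
    n_chr <- 10L
    chrom <- rep(seq_len(n_chr), each = ceiling(m / n_chr))[seq_len(m)]
    pos <- as.integer(stats::ave(seq_len(m), chrom, FUN = seq_along)) * 1000L
    mid <- sprintf("m%05d", seq_len(m))
    dimnames(dos) <- list(ids, mid)
    map <- data.frame(id = mid, chrom = chrom, pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
    list(genotypes = genotype_matrix(dos, map),
         subpops = stats::setNames(line_lab, ids),
         freqs = list(ancestral = mk$p0[keep],
                      subpop = mk$P[, keep, drop = FALSE]))
  })
}

# Dosages from a matrix of per-line-per-marker allele frequencies: fully
# inbred loci are 0/2 Bernoulli draws, outbred loci binomial(2, p).
draw_dosage <- function(pf, inbreeding) {
  n <- length(pf)
  hom <- if (inbreeding >= 1) rep(TRUE, n)
         else if (inbreeding <= 0) rep(FALSE, n)
         else as.logical(stats::rbinom(n, 1, inbreeding))
  out <- numeric(n)
  out[hom] <- 2 * stats::rbinom(sum(hom), 1, pf[hom])
  out[!hom] <- stats::rbinom(sum(!hom), 2, pf[!hom])
  dim(out) <- dim(pf)
  out
}

#' Simulate a replicated multi-environment polygenic trait
#'
#' Additive architecture: `n_qtl` causal markers are drawn uniformly from the
#' polymorphic markers; effects are either Gaussian or geometric-decay
#' (magnitudes spanning two orders, random signs — a few moderate QTL plus
#' many small ones). The true breeding value of line `i` is
#' `TBV_i = sum_j effect_j * dosage_ij`. Plot observations add a shared
#' environment mean and i.i.d. residual noise whose variance is calibrated so
#' that at the line-mean level
#' `var(TBV) / (var(TBV) + var(residual of the line mean)) = h2`: the plot
#' residual standard deviation is the line-mean residual SD times
#' `sqrt(n_env * n_rep)`. Heritability is thus defined (and recovered) at the
#' line-mean scale at which the pipeline operates.
#'
#' @param g a `geno_matrix`.
#' @param trait_name trait label used in the phenotype table.
#' @param n_qtl number of causal markers.
#' @param h2 target narrow-sense heritability of line means, in `(0, 1)`.
#' @param effect_dist `"geometric"` (default) or `"gaussian"`.
#' @param n_env,n_rep environments and replicates per environment
#'   (defaults 2 and 3).
#' @param env_effect_sd SD of environment means (default 1).
#' @param intercept baseline trait value added to every observation.
#' @param genetic_sd optional target SD of the true breeding values; effects
#'   are rescaled to hit it (useful for realistic trait units).
#' @param seed integer seed.
#' @return list with `phenotypes` (long-format [phenotype_table()]) and
#'   `truth` (list: `tbv`, `qtl_idx`, `qtl_effects`, `h2_target`,
#'   `h2_realized`).
#' @export
simulate_phenotypes <- function(g, trait_name = "trait", n_qtl = 300,
                                h2 = 0.5, effect_dist = c("geometric",
                                                          "gaussian"),
                                n_env = 2, n_rep = 3, env_effect_sd = 1,
                                intercept = 0, genetic_sd = NULL, seed = 1) {
  effect_dist <- match.arg(effect_dist)
  stopifnot(inherits(g, "geno_matrix"))
  if (h2 <= 0 || h2 >= 1)
    gs_error("h2 must lie strictly in (0, 1)", "gs_config_error")
  poly <- which(g$maf > 0)
  if (n_qtl > length(poly))
    gs_error(sprintf("n_qtl = %d exceeds the %d polymorphic markers",
                     n_qtl, length(poly)), "gs_config_error")

  with_seed(seed, {
    qtl <- sort(sample(poly, n_qtl))
    effects <- switch(effect_dist,
      gaussian = stats::rnorm(n_qtl),
      geometric = {
        mag <- 0.01^((seq_len(n_qtl) - 1) / max(n_qtl - 1, 1))
        sample(mag) * sample(c(-1, 1), n_qtl, replace = TRUE)
      })
    tbv <- drop(g$dosages[, qtl, drop = FALSE] %*% effects)
    if (stats::var(tbv) == 0)
      gs_error("true breeding values are constant; target h2 unreachable",
               "gs_simulation_error")
    if (!is.null(genetic_sd)) {
      sc <- genetic_sd / stats::sd(tbv)
      effects <- effects * sc
      tbv <- tbv * sc
    }
    var_g <- stats::var(tbv)
    plot_sd <- sqrt(var_g * (1 - h2) / h2 * n_env * n_rep)
    env_means <- stats::rnorm(n_env, 0, env_effect_sd)

    n <- length(tbv)
    grid <- expand.grid(line = seq_len(n), env = seq_len(n_env),
                        rep = seq_len(n_rep))
    value <- intercept + env_means[grid$env] + tbv[grid$line] +
      stats::rnorm(nrow(grid), 0, plot_sd)
    pheno <- phenotype_table(data.frame(
      line_id = line_ids(g)[grid$line],
      env = paste0("E", grid$env), rep = grid$rep,
      trait = trait_name, value = value, stringsAsFactors = FALSE))

    lm_means <- line_means(pheno, trait_name)[line_ids(g)]
    truth <- list(tbv = stats::setNames(tbv, line_ids(g)),
                  qtl_idx = qtl, qtl_effects = effects,
                  h2_target = h2,
                  h2_realized = var_g / stats::var(lm_means))
    list(phenotypes = pheno, truth = truth)
  })
}

#' One-call reference panel emulating a structured maize association panel
#'
#' Generates the default structured panel (498 fully inbred lines split
#' 27/67/193/211 over the SS, NSS, TST and MIXED subpopulations, 2000 markers
#' at differentiation 0.15) and four husk-style traits measured in 2
#' environments with 3 replicates each, with target line-mean heritabilities
#' spanning moderate to high: HL 0.45, HW 0.60, HN 0.70, HT 0.80. Trait
#' baselines and genetic SDs give values on plausible scales (HL/HW/HT in cm,
#' HN a layer count).
#'
#' @param seed master seed; every trait derives its own sub-seed from it.
#' @param dir optional directory: when given, the bundle is serialised as
#'   `genotypes.csv` (matrix dialect), `phenotypes.csv`, `subpops.csv` and
#'   `ground_truth.json`.
#' @return list with `genotypes`, `subpops`, `phenotypes` (all four traits in
#'   one table), `truth` (per-trait ground-truth list), `freqs`.
#' @export
simulate_reference_panel <- function(seed = 1, dir = NULL) {
  sim <- simulate_genotypes(seed = cell_seed(seed, "genotypes"))
  traits <- list(
    HL = list(h2 = 0.45, intercept = 25, genetic_sd = 2.0),
    HW = list(h2 = 0.60, intercept = 8, genetic_sd = 0.8),
    HN = list(h2 = 0.70, intercept = 10, genetic_sd = 1.2),
    HT = list(h2 = 0.80, intercept = 0.45, genetic_sd = 0.06))
  pheno <- list()
  truth <- list()
  for (tr in names(traits)) {
    cfg <- traits[[tr]]
    ph <- simulate_phenotypes(sim$genotypes, trait_name = tr, n_qtl = 300,
                              h2 = cfg$h2, intercept = cfg$intercept,
                              genetic_sd = cfg$genetic_sd,
                              env_effect_sd = cfg$genetic_sd / 2,
                              seed = cell_seed(seed, "trait", tr))
    pheno[[tr]] <- ph$phenotypes
    truth[[tr]] <- ph$truth
  }
  pheno_all <- phenotype_table(do.call(rbind, pheno))
  bundle <- list(genotypes = sim$genotypes, subpops = sim$subpops,
                 phenotypes = pheno_all, truth = truth, freqs = sim$freqs)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_matrix(sim$genotypes, file.path(dir, "genotypes.csv"))
    utils::write.csv(pheno_all, file.path(dir, "phenotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(line_id = names(sim$subpops),
                                subpop = unname(sim$subpops)),
                     file.path(dir, "subpops.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(truth, function(t) list(
        qtl_idx = t$qtl_idx, qtl_effects = t$qtl_effects,
        h2_target = t$h2_target, h2_realized = t$h2_realized,
        tbv = as.list(t$tbv))),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Weir-Cockerham FST over subpopulations
#'
#' Multi-marker Weir-Cockerham theta (ratio of averages), treating each
#' fully inbred line as one independent allele draw, with the standard
#' corrections for unequal subpopulation sizes and finite sampling. Used to
#' check that the simulator's realised differentiation matches its `fst`
#' parameter.
#'
#' @param g a `geno_matrix`.
#' @param subpops named character vector of subpopulation labels.
#' @param exclude labels to leave out (admixed groups sit between the others
#'   by construction); default `"MIXED"`.
#' @return scalar FST estimate.
#' @export
realized_fst <- function(g, subpops, exclude = "MIXED") {
  labs <- setdiff(unique(subpops), exclude)
  r <- length(labs)
  if (r < 2) gs_error("need at least two subpopulations", "gs_validation_error")
  rows <- lapply(labs, function(l) which(subpops[line_ids(g)] == l))
  ns <- lengths(rows)
  pmat <- vapply(rows, function(rr) colMeans(g$dosages[rr, , drop = FALSE]) / 2,
                 numeric(n_markers(g)))
  nbar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  pbar <- as.vector(pmat %*% (ns / sum(ns)))
  s2 <- rowSums(sweep(sweep(pmat, 1, pbar)^2, 2, ns, "*")) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  keep <- pbar > 0 & pbar < 1
  sum(a[keep]) / sum((a + b)[keep])
}
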