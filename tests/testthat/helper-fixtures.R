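# Shared fixtures. Heavy objects (the 498-line reference panel) are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Reference panel genotypes: 498 inbred lines, 4 subpopulations (27/67/193/211),
# ~2000 markers at differentiation 0.15.
ref_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_genotypes(seed = 20260901)
  .fixture_cache$sim
}

ref_kinship <- function() {
  if (is.null(.fixture_cache$K))
    .fixture_cache$K <- kinship(ref_sim()$genotypes)
  .fixture_cache$K
}

ref_pcs <- function() {
  if (is.null(.fixture_cache$pcs))
    .fixture_cache$pcs <- marker_pca(ref_sim()$genotypes, 3)
  .fixture_cache$pcs
}

# Full bundle with the four reference traits (h2 0.45/0.60/0.70/0.80).
ref_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    bundle <- simulate_reference_panel(seed = 20260901)
    .fixture_cache$panel <- build_panel(bundle$genotypes, bundle$phenotypes,
                                        bundle$subpops)
    .fixture_cache$truth <- bundle$truth
  }
  .fixture_cache$panel
}

# Small random genotype matrix: unstructured dosages in {0,1,2} with
# marker-specific allele frequencies.
rand_geno <- function(n, m, seed = 1, maf_min = 0.1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    p <- runif(m, maf_min, 1 - maf_min)
    dos <- vapply(p, function(pj) rbinom(n, 2, pj), numeric(n))
    dimnames(dos) <- list(sprintf("L%03d", seq_len(n)),
                          sprintf("M%04d", seq_len(m)))
    genotype_matrix(dos)
  })
}

# Write a small VCF fixture; `extra_triallelic` injects one multi-allelic site.
write_test_vcf <- function(path, extra_triallelic = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "L1", "L2", "L3", sep = "\t"))
  rows <- c(
    paste("1", "100", "s1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "s2", "G", "C", ".", "PASS", ".", "GT",
          "0|0", "0|0", "0|1", sep = "\t"),
    paste("2", "100", "s3", "A", "G", ".", "PASS", ".", "GT",
          "1/1", "0/1", "./.", sep = "\t"),
    paste("2", "300", "s4", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "1/1", "0/0", sep = "\t"))
  if (extra_triallelic)
    rows <- c(rows,
              paste("3", "50", "s5", "A", "T,G", ".", "PASS", ".", "GT",
                    "0/1", "1/2", "0/0", sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}
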