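# Phenotype records and subpopulation assignments.
#
# Phenotypes are long-format plot observations: one row per
# (line, environment, replicate, trait). Analyses run on per-line means taken
# across all replications and the selected environments, so unbalanced data
# are tolerated: a line's mean uses whatever observations it has.

#' Validate a long-format phenotype table
#'
#' @param df data frame with columns `line_id`, `env`, `rep`, `trait`,
#'   `value`. `value` may contain `NA`; non-missing values must be finite.
#' @return the validated data frame (invisibly classed `pheno_table`).
#' @export
phenotype_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("line_id", "env", "rep", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gs_error(paste0("phenotype table missing column(s): ",
                    paste(miss, collapse = ", ")), "gs_validation_error")
  key <- paste(df$line_id, df$env, df$rep, df$trait, sep = "\r")
  if (anyDuplicated(key))
    gs_error("duplicate (line, environment, replicate, trait) records",
             "gs_validation_error")
  bad <- !is.na(df$value) & !is.finite(df$value)
  if (any(bad))
    gs_error("non-finite phenotype values present", "gs_validation_error")
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Read phenotypes from a long-format CSV
#'
#' Expects columns `line_id`, `env`, `rep`, `trait`, `value`.
#'
#' @param path CSV path.
#' @return a validated phenotype table.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path))
    gs_error(paste0("cannot read phenotype file: ", path), "gs_input_error")
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Traits present in a phenotype table
#' @param p a phenotype table.
#' @return character vector of trait names.
#' @export
trait_names <- function(p) sort(unique(p$trait))

#' Per-line trait means across environments and replications
#'
#' The arithmetic mean of all non-missing observations of `trait` for each
#' line, over the selected environments (all by default). Lines with no
#' observations are omitted from the result.
#'
#' @param p a phenotype table.
#' @param trait trait name.
#' @param environments optional character vector restricting to a subset of
#'   environments; `NULL` means all.
#' @return named numeric vector, names = line ids.
#' @export
line_means <- function(p, trait, environments = NULL) {
  if (!trait %in% p$trait)
    gs_error(paste0("unknown trait '", trait, "'; available: ",
                    paste(trait_names(p), collapse = ", ")),
             "gs_validation_error")
  sub <- p[p$trait == trait & !is.na(p$value), , drop = FALSE]
  if (!is.null(environments)) sub <- sub[sub$env %in% environments, , drop = FALSE]
  if (!nrow(sub)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(sub$value, sub$line_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Read a line-to-subpopulation assignment
#'
#' CSV with columns `line_id`, `subpop`. Every line must appear exactly once.
#'
#' @param path CSV path.
#' @return named character vector mapping line id to subpopulation label.
#' @export
read_subpops <- function(path) {
  if (!file.exists(path))
    gs_error(paste0("cannot read subpopulation file: ", path), "gs_input_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "subpop") %in% names(df)))
    gs_error("subpopulation file needs columns line_id, subpop",
             "gs_validation_error")
  if (anyDuplicated(df$line_id))
    gs_error("duplicate line ids in subpopulation assignment",
             "gs_validation_error")
  stats::setNames(as.character(df$subpop), df$line_id)
}
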