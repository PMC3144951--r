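# Delimited-text readers/writers for the pipeline's external interfaces.
# Comma- and tab-separated inputs are both accepted (sniffed from the
# header line).

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, required) {
  df <- read.table(path, header = TRUE, sep = sniff_sep(path),
                   stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a Ct-well table
#'
#' Expects columns `sample_id`, `assay` (`target`/`control`),
#' `replicate`, `ct`; comma- or tab-separated with a header.
#'
#' @param path File path.
#' @return A validated Ct-well data.frame.
#' @export
read_ct_wells <- function(path) {
  df <- read_delim_checked(path, c("sample_id", "assay", "replicate", "ct"))
  df$sample_id <- as.character(df$sample_id)
  validate_ct_wells(df)
  df
}

#' Read a dilution-series table
#'
#' Expects columns `log10_quantity`, `replicate`, `ct`.
#'
#' @param path File path.
#' @return A data.frame accepted by [fit_standard_curve()].
#' @export
read_dilution_series <- function(path) {
  df <- read_delim_checked(path, c("log10_quantity", "replicate", "ct"))
  if (any(!is.finite(df$ct)))
    stop("non-finite Ct values in '", path, "'")
  df
}

#' Read a phenotype table
#'
#' Expects `sample_id` plus trait columns (by default `shell_length`,
#' `shell_width`, `body_weight`); present trait values must be positive.
#'
#' @param path File path.
#' @param traits Trait columns required to exist.
#' @return A phenotype data.frame.
#' @export
read_phenotypes <- function(path,
                            traits = c("shell_length", "shell_width",
                                       "body_weight")) {
  df <- read_delim_checked(path, c("sample_id", traits))
  df$sample_id <- as.character(df$sample_id)
  for (tr in traits) {
    bad <- !is.na(df[[tr]]) & df[[tr]] <= 0
    if (any(bad))
      stop("non-positive ", tr, " value(s) in '", path, "'")
  }
  df
}

#' Write a genotype result table as TSV
#'
#' Writes the output of [genotype_population()] with columns `sample_id`,
#' `mean_ct_target`, `mean_ct_control`, `raw_estimate`, `call`,
#' `no_call_reason`.
#'
#' @param results Genotype result data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an end-to-end simulation scenario from JSON
#'
#' The scenario file describes one population, its Ct noise model and
#' (optionally) phenotype effects, e.g.:
#' \preformatted{
#' {
#'   "population": {"id": "JH", "n": 100,
#'                  "distribution": {"3": 0.4, "4": 0.49, "2": 0.11}},
#'   "noise": {"baseline_control_ct": 26, "replicate_sd": 0.1,
#'             "between_sample_sd": 0.3},
#'   "dilution": {"amplification_factor": 1.97, "levels": [0,-1,-2,-3,-4]}
#' }
#' }
#'
#' @param path Path to a JSON scenario file.
#' @return A list with elements `population` ([population_spec()]),
#'   `noise` ([ct_noise_model()]), optional `effects` data.frame and
#'   optional `dilution` parameters.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$population))
    stop("scenario must define a population")
  pop <- cfg$population
  spec <- population_spec(pop$id %||% "population",
                          unlist(pop$distribution), pop$n %||% 100L)
  noise <- do.call(ct_noise_model, as.list(cfg$noise %||% list()))
  out <- list(population = spec, noise = noise)
  if (!is.null(cfg$effects))
    out$effects <- as.data.frame(cfg$effects)
  if (!is.null(cfg$dilution))
    out$dilution <- cfg$dilution
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an end-to-end simulation scenario
#'
#' Draws a population, its Ct-well table and (if effects are given)
#' phenotypes from a scenario, in the exact formats consumed by
#' [genotype_population()] and [associate()].
#'
#' @param scenario A list from [read_scenario()] (or built by hand).
#' @param seed Integer seed applied once, up front.
#' @param replicates Wells per sample per assay.
#' @return A list with `genotypes`, `wells`, and optionally `phenotypes`
#'   and `dilution` data.frames.
#' @export
simulate_scenario <- function(scenario, seed = NULL, replicates = 3L) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- simulate_population(scenario$population)
  wells <- simulate_ct_table(genotypes, scenario$noise,
                             replicates = replicates)
  out <- list(genotypes = genotypes, wells = wells)
  if (!is.null(scenario$effects))
    out$phenotypes <- simulate_phenotypes(genotypes, scenario$effects)
  if (!is.null(scenario$dilution)) {
    d <- scenario$dilution
    out$dilution <- simulate_dilution_series(
      d$amplification_factor,
      levels = d$levels %||% 0:-4,
      replicates = d$replicates %||% 3L,
      noise_sd = d$noise_sd %||% 0)
  }
  out
}
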