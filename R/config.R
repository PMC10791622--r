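#' Analysis configuration
#'
#' Bundles every numeric threshold used across the pipeline. Defaults are the
#' values used throughout the delimitation workflow: the species read filter
#' (identity at least 95%, read coverage at least 70%), the genomovar
#' read-identity rule (at least 99.3%, i.e. at most one mismatch in a 150 bp
#' read), the genomovar ANI threshold (above 99.5%), the strain rule (ANI
#' above 99.99% and shared gene content above 99.0%), the allele-uniqueness
#' floor (below 99.8% identity), reciprocal
#' best-hit orthology cut-offs (90% identity, 90% coverage), the Gaussian KDE
#' bandwidth factor (0.15 x sample standard deviation), the bootstrap and
#' permutation counts, the regression window on the accumulation curve
#' (20 to 100 genomes), and the prediction-interval level (99%).
#'
#' @param species_identity_floor percent identity floor for the species read
#'   set (default 95).
#' @param species_read_coverage_floor percent of the read length that must be
#'   aligned (default 70).
#' @param genomovar_read_identity percent identity for genomovar-level read
#'   assignment (default 99.3).
#' @param genomovar_ani_threshold ANI threshold (strict `>`) for genomovar
#'   clustering (default 99.5).
#' @param strain_ani_threshold ANI threshold (strict `>`) for strain
#'   clustering (default 99.99).
#' @param strain_gene_share_threshold shared gene-content threshold (strict
#'   `>`) for strain clustering (default 99).
#' @param allele_identity_floor two alleles of one core gene are distinct when
#'   their identity is below this floor (default 99.8).
#' @param rbh_identity,rbh_coverage reciprocal best-hit cut-offs (default 90).
#' @param kde_bandwidth_factor KDE bandwidth as a multiple of the sample
#'   standard deviation (default 0.15).
#' @param bootstrap_iterations bootstrap resamples for gap detection
#'   (default 10000).
#' @param permutations random genome orderings for the accumulation curve
#'   (default 100).
#' @param fit_window genome-count interval for the richness regression
#'   (default `c(20, 100)`).
#' @param pi_level prediction-interval level (default 0.99).
#' @param nominal_read_length read length assumed when a hit table carries no
#'   read lengths (default 150).
#' @param gap_search_window ANI interval searched for the deepest valley
#'   (default `c(99, 100)`).
#' @param coverage_at_genomovar_step apply the >= 70% read-coverage rule at the
#'   99.3% step as well (default TRUE; conservative).
#' @param min_alignment_length optional minimum alignment length applied before
#'   best-hit selection (default 0 = off).
#' @param rng_seed integer seed used by seeded operations (default 1).
#'
#' @return An object of class `ani_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$genomovar_ani_threshold
#' @export
analysis_config <- function(species_identity_floor = 95,
                            species_read_coverage_floor = 70,
                            genomovar_read_identity = 99.3,
                            genomovar_ani_threshold = 99.5,
                            strain_ani_threshold = 99.99,
                            strain_gene_share_threshold = 99,
                            allele_identity_floor = 99.8,
                            rbh_identity = 90,
                            rbh_coverage = 90,
                            kde_bandwidth_factor = 0.15,
                            bootstrap_iterations = 10000L,
                            permutations = 100L,
                            fit_window = c(20L, 100L),
                            pi_level = 0.99,
                            nominal_read_length = 150L,
                            gap_search_window = c(99, 100),
                            coverage_at_genomovar_step = TRUE,
                            min_alignment_length = 0L,
                            rng_seed = 1L) {
  cfg <- list(
    species_identity_floor = species_identity_floor,
    species_read_coverage_floor = species_read_coverage_floor,
    genomovar_read_identity = genomovar_read_identity,
    genomovar_ani_threshold = genomovar_ani_threshold,
    strain_ani_threshold = strain_ani_threshold,
    strain_gene_share_threshold = strain_gene_share_threshold,
    allele_identity_floor = allele_identity_floor,
    rbh_identity = rbh_identity,
    rbh_coverage = rbh_coverage,
    kde_bandwidth_factor = kde_bandwidth_factor,
    bootstrap_iterations = as.integer(bootstrap_iterations),
    permutations = as.integer(permutations),
    fit_window = as.integer(fit_window),
    pi_level = pi_level,
    nominal_read_length = as.integer(nominal_read_length),
    gap_search_window = as.numeric(gap_search_window),
    coverage_at_genomovar_step = isTRUE(coverage_at_genomovar_step),
    min_alignment_length = as.integer(min_alignment_length),
    rng_seed = as.integer(rng_seed)
  )
  pct <- c("species_identity_floor", "species_read_coverage_floor",
           "genomovar_read_identity", "genomovar_ani_threshold",
           "strain_ani_threshold", "strain_gene_share_threshold",
           "allele_identity_floor", "rbh_identity", "rbh_coverage")
  for (p in pct) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100)
      stop(sprintf("'%s' must be a percent in [0, 100]", p))
  }
  if (!(cfg$species_identity_floor < cfg$genomovar_read_identity &&
        cfg$genomovar_read_identity < cfg$strain_ani_threshold))
    stop("thresholds must satisfy species_identity_floor < ",
         "genomovar_read_identity < strain_ani_threshold")
  if (cfg$bootstrap_iterations < 1L || cfg$permutations < 1L)
    stop("iteration counts must be positive")
  if (length(cfg$fit_window) != 2L || diff(cfg$fit_window) <= 0)
    stop("'fit_window' must be an increasing interval")
  if (cfg$pi_level <= 0 || cfg$pi_level >= 1)
    stop("'pi_level' must lie in (0, 1)")
  structure(cfg, class = "ani_config")
}

#' @export
print.ani_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = " - ")))
  }
  invisible(x)
}

.as_config <- function(config) {
  if (is.null(config)) return(analysis_config())
  if (!inherits(config, "ani_config"))
    stop("'config' must be built with analysis_config()")
  config
}
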