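#' Read-coverage incidence matrix over genomovar representatives
#'
#' For the accumulation analysis every qualifying match is preserved (not just
#' the best hit): a read "covers" a representative when it matches it at
#' identity >= 99.3% (and, optionally, the read-coverage rule).
#'
#' @param hits a `hit_table` with all hits per read.
#' @param representatives genomovar_id -> representative genome_id.
#' @param config an [analysis_config()].
#' @return Logical matrix (reads x representatives); reads with no qualifying
#'   match are omitted (they never contribute to the curve).
#' @export
read_cover_matrix <- function(hits, representatives,
                              config = analysis_config()) {
  config <- .as_config(config)
  dt <- data.table::as.data.table(hits)
  dt <- dt[dt$genome_id %in% representatives]
  qual <- dt$identity >= config$genomovar_read_identity
  if (config$coverage_at_genomovar_step)
    qual <- qual & (100 * dt$alignment_length / dt$read_length >=
                      config$species_read_coverage_floor)
  dt <- dt[qual]
  if (nrow(dt) == 0L) stop("no qualifying matches")
  reads <- unique(dt$read_id)
  K <- length(representatives)
  m <- matrix(FALSE, length(reads), K,
              dimnames = list(NULL, names(representatives)))
  gi <- match(dt$genome_id, representatives)
  ri <- match(dt$read_id, reads)
  m[cbind(ri, gi)] <- TRUE
  m
}

#' Leave-genomes-out accumulation curve
#'
#' Representatives are added in random order; after adding k genomes the
#' curve records the fraction of species reads covered by at least one
#' included genome, `f_k = |covered reads| / species_read_count`. The process
#' is repeated over random orderings (100 by default) and is deterministic for
#' a fixed seed.
#'
#' @param cover logical reads x representatives matrix
#'   (see [read_cover_matrix()]).
#' @param species_read_count denominator: reads matching any reference at the
#'   species identity floor.
#' @param permutations number of random orderings.
#' @param seed integer seed.
#' @return An object of class `accumulation_curve`: list with `f` (matrix
#'   permutations x K), `mean_f` (per-step mean), `K`, `species_read_count`.
#' @export
accumulation_curve <- function(cover, species_read_count,
                               permutations = 100L, seed = 1L) {
  if (species_read_count <= 0L) stop("species_read_count must be positive")
  K <- ncol(cover)
  if (K < 2L) stop("need at least 2 representatives")
  cover <- cover[rowSums(cover) > 0L, , drop = FALSE]
  set.seed(seed)
  f <- matrix(NA_real_, permutations, K)
  for (p in seq_len(permutations)) {
    ord <- sample.int(K)
    # first position in this ordering at which each read becomes covered
    first <- max.col(cover[, ord, drop = FALSE], ties.method = "first")
    f[p, ] <- cumsum(tabulate(first, nbins = K)) / species_read_count
  }
  stopifnot(all(diff(t(f)) >= -1e-12))  # monotone within each permutation
  structure(list(f = f, mean_f = colMeans(f), K = K,
                 species_read_count = species_read_count,
                 permutations = permutations, seed = seed),
            class = "accumulation_curve")
}

#' Log-linear richness extrapolation with prediction interval
#'
#' Fits `log10(k) = a + b * f` by ordinary unweighted least squares on the
#' per-step mean fraction across permutations, restricted to the genome-count
#' window (default 20 to 100, clipped with a warning when fewer
#' representatives are available), and extrapolates to full coverage of the
#' species reads (f = 1): `N_hat = 10^(a + b)`. The prediction interval at
#' f = 1 uses the standard t-based formula for a new observation on the
#' transformed scale (n - 2 degrees of freedom) and is back-transformed.
#'
#' @param curve an `accumulation_curve`, or a numeric vector of per-step mean
#'   fractions (element k = mean f at k genomes).
#' @param config an [analysis_config()]; supplies `fit_window` and `pi_level`.
#' @param pooled fit on the pooled permutation cloud instead of the mean curve
#'   (sensitivity analysis; narrower, pseudo-replicated intervals).
#' @return An object of class `richness_estimate`: `slope`, `intercept`,
#'   `pearson_r`, `n_points`, `fit_window`, `N_hat`, `pi_low`, `pi_high`,
#'   `pi_level`, `valid` (FALSE when the fitted slope is not positive).
#' @export
fit_extrapolate <- function(curve, config = analysis_config(),
                            pooled = FALSE) {
  config <- .as_config(config)
  win <- config$fit_window
  if (inherits(curve, "accumulation_curve")) {
    K <- curve$K
    mean_f <- curve$mean_f
  } else {
    mean_f <- as.numeric(curve)
    K <- length(mean_f)
  }
  lo <- max(win[1], 1L); hi <- min(win[2], K)
  if (hi < lo)
    stop(sprintf("fit window [%d, %d] does not intersect the available ",
                 win[1], win[2]), "range 1..", K)
  if (hi < win[2] || lo > win[1])
    warning(sprintf("fit window clipped to [%d, %d] (K = %d)", lo, hi, K))
  ks <- lo:hi
  if (pooled && inherits(curve, "accumulation_curve")) {
    x <- as.vector(curve$f[, ks])
    y <- rep(log10(ks), each = nrow(curve$f))
  } else {
    x <- mean_f[ks]
    y <- log10(ks)
  }
  if (length(unique(x)) < 3L) stop("fewer than 3 usable points in fit window")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2]); a <- unname(stats::coef(fit)[1])
  pr <- suppressWarnings(stats::predict(fit, newdata = data.frame(x = 1),
                                        interval = "prediction",
                                        level = config$pi_level))
  est <- structure(list(
    slope = b, intercept = a,
    pearson_r = stats::cor(x, y),
    n_points = length(x),
    fit_window = c(lo, hi),
    N_hat = 10^pr[1, "fit"],
    pi_low = 10^pr[1, "lwr"], pi_high = 10^pr[1, "upr"],
    pi_level = config$pi_level,
    log_base = 10,
    valid = b > 0
  ), class = "richness_estimate")
  if (!est$valid)
    warning("non-increasing fit (slope <= 0): extrapolation flagged invalid")
  est
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Richness extrapolation (window %d-%d genomes, %d points)\n",
              x$fit_window[1], x$fit_window[2], x$n_points))
  cat(sprintf("  log10(k) = %.4f + %.4f f   (Pearson r = %.5f)\n",
              x$intercept, x$slope, x$pearson_r))
  cat(sprintf("  N_hat = %.0f genomovars  (%d%% PI: %.0f - %.0f)%s\n",
              x$N_hat, round(100 * x$pi_level), x$pi_low, x$pi_high,
              if (!x$valid) "  [invalid: slope <= 0]" else ""))
  invisible(x)
}
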