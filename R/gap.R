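#' Expected per-bin count under a uniform spread of ANI values
#'
#' Number of values expected per bin if `n_values_above_floor` values were
#' distributed uniformly between `floor` and `ceiling`; identical for every
#' bin of width `bin_width`. For the depletion analysis of the intra-species
#' ANI distribution: 578 values above 99% spread uniformly over \[99, 100\]
#' give 57.8 expected values per 0.1-point bin.
#'
#' @param n_values_above_floor count of values in the range.
#' @param floor,ceiling percent bounds of the range (ceiling > floor).
#' @param bin_width bin width in ANI percent points.
#' @return The per-bin expectation (a single number).
#' @examples
#' expected_uniform_per_bin(578, 99, 100, 0.1)  # 57.8
#' @export
expected_uniform_per_bin <- function(n_values_above_floor, floor, ceiling,
                                     bin_width) {
  if (ceiling <= floor) stop("zero- or negative-width range")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (n_values_above_floor < 0) stop("negative count")
  n_values_above_floor * bin_width / (ceiling - floor)
}

#' Fold-depletion of an observed bin count relative to expectation
#'
#' @param expected_per_bin expected count (must be positive).
#' @param observed_per_bin observed count (zero gives `Inf`, flagged via the
#'   `infinite` attribute).
#' @return expected / observed.
#' @examples
#' depletion_ratio(57.8, 15.5)  # ~3.73
#' @export
depletion_ratio <- function(expected_per_bin, observed_per_bin) {
  if (expected_per_bin <= 0) stop("expected_per_bin must be positive")
  if (observed_per_bin < 0) stop("negative observed count")
  if (observed_per_bin == 0)
    return(structure(Inf, infinite = TRUE))
  expected_per_bin / observed_per_bin
}

#' Binned ANI counts with uniform expectation and depletion ratios
#'
#' Counts ANI values in half-open bins `[lo, hi)` of width `bin_width` over
#' `[floor, ceiling)`, and contrasts each bin against the expectation under a
#' uniform spread of the in-range values.
#'
#' @param values numeric ANI percents.
#' @param floor,ceiling range bounds.
#' @param bin_width bin width (default 0.1).
#' @return A data.frame of class `bin_stats` with columns `bin_lo`, `bin_hi`,
#'   `observed`, `expected_uniform`, `depletion_ratio` (Inf when observed is
#'   0). The attribute `n_in_range` records the number of in-range values.
#' @export
ani_bin_stats <- function(values, floor, ceiling, bin_width = 0.1) {
  values <- values[!is.na(values)]
  edges <- seq(floor, ceiling, by = bin_width)
  if (abs(edges[length(edges)] - ceiling) > 1e-9)
    stop("bin_width must divide the range")
  inr <- values >= floor & values < ceiling
  n <- sum(inr)
  # half-open [lo, hi) bins
  idx <- findInterval(values[inr], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  exp_per_bin <- expected_uniform_per_bin(n, floor, ceiling, bin_width)
  dep <- ifelse(counts == 0L, Inf, exp_per_bin / counts)
  if (n == 0L) dep <- rep(NA_real_, length(counts))
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    observed = counts, expected_uniform = exp_per_bin,
                    depletion_ratio = dep)
  attr(out, "n_in_range") <- n
  class(out) <- c("bin_stats", "data.frame")
  out
}

#' Kernel-density extrema of an ANI value distribution
#'
#' Evaluates a Gaussian kernel density with bandwidth
#' `bandwidth_factor * sd(values)` on a uniform grid over
#' `[min - 3h, max + 3h]` clipped to `[0, 100]`, and locates local extrema by
#' strict neighbour comparison: a grid point is a peak (valley) iff its density
#' is strictly greater (smaller) than both neighbours. The deepest valley is
#' the valley of minimum density inside `search_window` (absent if none).
#'
#' @param values numeric ANI percents (at least 10, non-constant).
#' @param bandwidth_factor multiple of the sample standard deviation
#'   (default 0.15).
#' @param grid_points grid resolution (default 1024).
#' @param search_window interval searched for the deepest valley
#'   (default `c(99, 100)`).
#' @return An object of class `gap_report`: list with `grid`, `density`,
#'   `peaks`, `valleys` (grid positions), `deepest_valley` (position or NA),
#'   `bandwidth`, `search_window`.
#' @export
kde_extrema <- function(values, bandwidth_factor = 0.15, grid_points = 1024L,
                        search_window = c(99, 100)) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero-variance input: bandwidth undefined")
  h <- bandwidth_factor * s
  lo <- max(0, min(values) - 3 * h)
  hi <- min(100, max(values) + 3 * h)
  d <- stats::density(values, bw = h, kernel = "gaussian",
                      from = lo, to = hi, n = grid_points)
  y <- d$y
  n <- length(y)
  mid <- 2:(n - 1L)
  is_peak <- c(FALSE, y[mid] > y[mid - 1L] & y[mid] > y[mid + 1L], FALSE)
  is_valley <- c(FALSE, y[mid] < y[mid - 1L] & y[mid] < y[mid + 1L], FALSE)
  valleys <- d$x[is_valley]
  inwin <- valleys >= search_window[1] & valleys <= search_window[2]
  deepest <- NA_real_
  if (any(inwin)) {
    vy <- y[is_valley][inwin]
    vx <- valleys[inwin]
    deepest <- vx[which.min(vy)]
  }
  structure(list(grid = d$x, density = y, peaks = d$x[is_peak],
                 valleys = valleys, deepest_valley = deepest,
                 bandwidth = h, search_window = search_window),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("ANI gap report\n")
  cat(sprintf("  bandwidth: %.4f  peaks: %d  valleys: %d\n",
              x$bandwidth, length(x$peaks), length(x$valleys)))
  if (!is.null(x$deepest_valley))
    cat(sprintf("  deepest valley in [%.2f, %.2f]: %s\n",
                x$search_window[1], x$search_window[2],
                ifelse(is.na(x$deepest_valley), "none",
                       sprintf("%.4f", x$deepest_valley))))
  if (!is.null(x$bootstrap_percentiles)) {
    bp <- x$bootstrap_percentiles
    cat(sprintf("  bootstrap (%d iterations): valley position 2.5/50/97.5%% = %.4f / %.4f / %.4f\n",
                x$n_iterations, bp[1], bp[2], bp[3]))
    cat(sprintf("  valley-free iterations: %d (%.1f%%)%s\n",
                x$n_valley_free, 100 * x$n_valley_free / x$n_iterations,
                if (isTRUE(x$no_robust_gap)) "  [no robust gap]" else ""))
  }
  invisible(x)
}

#' Bootstrapped valley localisation in an ANI distribution
#'
#' Resamples the ANI value set with replacement, applies [kde_extrema()] to
#' each resample, and collects the position of the deepest valley inside the
#' search window across iterations. Reports the 2.5/50/97.5 percentiles of the
#' valley position and the count of valley-free iterations; if more than half
#' of the iterations find no valley in the window the report is flagged
#' `no_robust_gap`.
#'
#' @param values numeric ANI percents.
#' @param config an [analysis_config()]; supplies the bandwidth factor,
#'   iteration count, search window and RNG seed unless overridden.
#' @param iterations,search_window,grid_points optional overrides.
#' @param seed optional seed override (an integer).
#' @return A `gap_report` with the additional fields
#'   `bootstrap_percentiles` (named 2.5%/50%/97.5%), `valley_positions`,
#'   `n_iterations`, `n_valley_free`, `no_robust_gap`; the point-estimate
#'   fields come from a single evaluation on the full data set.
#' @export
bootstrap_gap <- function(values, config = analysis_config(),
                          iterations = NULL, search_window = NULL,
                          grid_points = 1024L, seed = NULL) {
  config <- .as_config(config)
  if (is.null(iterations)) iterations <- config$bootstrap_iterations
  if (is.null(search_window)) search_window <- config$gap_search_window
  if (is.null(seed)) seed <- config$rng_seed
  values <- values[!is.na(values)]
  point <- kde_extrema(values, config$kde_bandwidth_factor, grid_points,
                       search_window)
  set.seed(seed)
  pos <- rep(NA_real_, iterations)
  n <- length(values)
  for (it in seq_len(iterations)) {
    res <- values[sample.int(n, n, replace = TRUE)]
    if (stats::sd(res) == 0) next  # degenerate resample counts as valley-free
    rep_i <- kde_extrema(res, config$kde_bandwidth_factor, grid_points,
                         search_window)
    pos[it] <- rep_i$deepest_valley
  }
  n_free <- sum(is.na(pos))
  bp <- if (n_free < iterations) {
    stats::quantile(pos, c(0.025, 0.5, 0.975), na.rm = TRUE, names = TRUE)
  } else {
    stats::setNames(rep(NA_real_, 3), c("2.5%", "50%", "97.5%"))
  }
  point$valley_positions <- pos
  point$bootstrap_percentiles <- bp
  point$n_iterations <- iterations
  point$n_valley_free <- n_free
  point$no_robust_gap <- n_free > iterations / 2
  point
}
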