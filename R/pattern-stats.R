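#' Fit a Gaussian to property samples
#'
#' Default method is moments: sample mean and population (1/n) standard
#' deviation, so pooling per-pattern fits reproduces the global moments
#' exactly. The `"histogram"` method least-squares fits a Gaussian density to
#' a histogram of the samples, the way a distribution curve is fitted to a
#' plotted histogram.
#'
#' @param samples Numeric vector, at least one finite value.
#' @param method `"moments"` (default) or `"histogram"`.
#' @param bins Histogram bin count for the histogram method (default 50).
#' @return A `gaussian_fit`: list with `mu`, `sigma`, `n`, `method`.
#' @export
fit_gaussian <- function(samples, method = c("moments", "histogram"), bins = 50) {
  method <- match.arg(method)
  if (length(samples) == 0L || !all(is.finite(samples))) {
    abort("`samples` must be non-empty and finite")
  }
  n <- length(samples)
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  if (method == "histogram" && n >= 2L && sigma > 0) {
    h <- graphics::hist(samples, breaks = bins, plot = FALSE)
    mids <- h$mids
    dens <- h$density
    fit <- tryCatch(
      stats::nls(
        dens ~ stats::dnorm(mids, m, s),
        start = list(m = mu, s = sigma),
        control = stats::nls.control(warnOnly = TRUE)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      mu <- unname(cf["m"])
      sigma <- abs(unname(cf["s"]))
    }
  }
  structure(list(mu = mu, sigma = sigma, n = n, method = method),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit (%s): mu = %.4g, sigma = %.4g, n = %d>\n",
              x$method, x$mu, x$sigma, x$n))
  invisible(x)
}

#' Per-pattern Gaussian statistics of frame properties
#'
#' Joins a label table to a property table by `(trajectory_id, frame)` and
#' fits one Gaussian per (pattern, property). Per-atom charge columns
#' `charge_1..charge_A` are treated as one property per atom. Frames with a
#' missing property are excluded from that property's fits; patterns with no
#' property-bearing frames are omitted with a warning.
#'
#' @param labels Label tibble (`trajectory_id`, `frame`, pattern column).
#' @param properties Property tibble (see [read_property_table()]).
#' @param pattern_col Pattern column name in `labels` (default `"pattern"`).
#' @param property_cols Properties to fit; default: every non-key numeric
#'   column of `properties`.
#' @param method Passed to [fit_gaussian()].
#' @return Tibble: `pattern`, `property`, `mu`, `sigma`, `n`.
#' @export
per_pattern_stats <- function(labels, properties, pattern_col = "pattern",
                              property_cols = NULL,
                              method = c("moments", "histogram")) {
  method <- match.arg(method)
  labels <- tibble::as_tibble(labels)
  properties <- tibble::as_tibble(properties)
  if (is.null(property_cols)) {
    property_cols <- setdiff(names(properties), c("trajectory_id", "frame", "time"))
    property_cols <- property_cols[vapply(properties[property_cols], is.numeric, logical(1))]
  }
  joined <- dplyr::inner_join(
    dplyr::select(labels, "trajectory_id", "frame",
                  pattern = dplyr::all_of(pattern_col)),
    properties, by = c("trajectory_id", "frame")
  )
  n_missing <- nrow(labels) - nrow(joined)
  if (n_missing > 0L) {
    warn(sprintf("%d labelled frame(s) had no property row and were excluded",
                 n_missing))
  }
  long <- tidyr::pivot_longer(
    joined[c("pattern", property_cols)],
    cols = dplyr::all_of(property_cols),
    names_to = "property", values_to = "value"
  ) |>
    dplyr::filter(is.finite(.data$value))
  empty <- setdiff(
    as.vector(outer(unique(joined$pattern), property_cols, paste)),
    paste(long$pattern, long$property)
  )
  if (length(empty) > 0L) {
    warn(sprintf("%d (pattern, property) cell(s) had no finite values; fits omitted",
                 length(empty)))
  }
  long |>
    dplyr::group_by(.data$pattern, .data$property) |>
    dplyr::summarise(
      fit = list(fit_gaussian(.data$value, method = method)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mu = purrr::map_dbl(.data$fit, "mu"),
      sigma = purrr::map_dbl(.data$fit, "sigma"),
      n = purrr::map_int(.data$fit, "n")
    ) |>
    dplyr::select(-"fit") |>
    dplyr::arrange(.data$pattern, .data$property)
}

#' Two-sided standard-normal coverage of mu +/- z sigma
#'
#' The probability mass of a Gaussian within z standard deviations of the
#' mean, `Phi(z) - Phi(-z)`. At z = 2.58 this is 0.9901 — the "99%" interval
#' conventionally drawn as error bars on per-atom charge distributions.
#'
#' @param z Non-negative number of standard deviations.
#' @return Probability in `[0, 1]`.
#' @examples
#' gaussian_coverage(2.58)
#' @export
gaussian_coverage <- function(z) {
  if (!is.numeric(z) || any(z < 0)) abort("`z` must be >= 0")
  pnorm(z) - pnorm(-z)
}

#' Coverage interval of a Gaussian fit
#'
#' @param fit A `gaussian_fit`.
#' @param z Half-width in standard deviations (default 2.58, the 99%
#'   convention).
#' @return Named numeric `c(lower, upper)` = `mu -/+ z * sigma`.
#' @export
coverage_interval <- function(fit, z = 2.58) {
  stopifnot(inherits(fit, "gaussian_fit"))
  c(lower = fit$mu - z * fit$sigma, upper = fit$mu + z * fit$sigma)
}

#' Gaussian-broadened emission spectrum from snapshot energies
#'
#' Estimates a fluorescence emission band from an ensemble of vertical
#' S1 -> S0 emission energies (one per snapshot) by summing unit-area
#' Gaussians centred at each energy. With unit intensity per snapshot the
#' integral of the spectrum equals the snapshot count. The grid spans all
#' energies plus three broadening widths on each side.
#'
#' @param energies Energies in eV, at least one, finite.
#' @param broadening_fwhm Gaussian full width at half maximum, eV
#'   (default 0.2).
#' @param grid_step Grid spacing in eV (default `broadening_fwhm / 20`).
#' @return A tibble of class `emission_spectrum` with columns `energy` (eV)
#'   and `intensity` (1/eV), attributes `broadening_fwhm` and `n_snapshots`.
#' @export
emission_spectrum <- function(energies, broadening_fwhm = 0.2,
                              grid_step = broadening_fwhm / 20) {
  if (length(energies) == 0L || !all(is.finite(energies))) {
    abort("`energies` must be non-empty and finite")
  }
  if (broadening_fwhm <= 0) abort("`broadening_fwhm` must be positive")
  sigma <- broadening_fwhm / (2 * sqrt(2 * log(2)))
  lo <- min(energies) - 3 * broadening_fwhm
  hi <- max(energies) + 3 * broadening_fwhm
  grid <- lo + (0:ceiling((hi - lo) / grid_step)) * grid_step
  intensity <- rowSums(vapply(
    energies,
    function(e) stats::dnorm(grid, mean = e, sd = sigma),
    numeric(length(grid))
  ))
  out <- tibble::tibble(energy = grid, intensity = intensity)
  attr(out, "broadening_fwhm") <- broadening_fwhm
  attr(out, "n_snapshots") <- length(energies)
  class(out) <- c("emission_spectrum", class(out))
  out
}
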