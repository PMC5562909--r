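#' Tidy a fitted pattern model
#'
#' One row per pattern: size and the back-mapped centroid dihedrals in
#' degrees.
#'
#' @param x A `pattern_model`.
#' @param ... Unused.
#' @return A tibble with columns `pattern`, `n`, and one `<dihedral>` column
#'   per descriptor.
#' @exportS3Method generics::tidy
tidy.pattern_model <- function(x, ...) {
  deg <- x$centroids_deg
  colnames(deg) <- x$dihedral_names
  dplyr::bind_cols(
    tibble::tibble(pattern = 0:(x$k - 1L), n = x$sizes),
    tibble::as_tibble(deg)
  )
}

#' @rdname tidy.pattern_model
#' @exportS3Method generics::glance
glance.pattern_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, embedding = x$embedding, seed = x$seed,
    n_frames = nrow(x$labels), inertia = x$inertia,
    min_size = min(x$sizes), max_size = max(x$sizes)
  )
}

#' Tidy a transition model
#'
#' Long form of the kinetic network: one row per ordered pattern pair with
#' its transition count and row-normalized probability.
#'
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return Tibble: `from`, `to`, `count`, `probability`.
#' @exportS3Method generics::tidy
tidy.transition_model <- function(x, ...) {
  k <- x$k
  tibble::tibble(
    from = rep(0:(k - 1L), k),
    to = rep(0:(k - 1L), each = k),
    count = as.vector(x$counts),
    probability = as.vector(x$probabilities)
  ) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @rdname tidy.transition_model
#' @exportS3Method generics::glance
glance.transition_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, lag = x$lag, n_pairs = x$n_pairs,
    n_zero_rows = sum(x$zero_rows),
    n_edges = sum(x$counts[row(x$counts) != col(x$counts)] > 0)
  )
}

#' Tidy a Gaussian fit
#'
#' @param x A `gaussian_fit`.
#' @param z Half-width for the reported coverage interval (default 2.58).
#' @param ... Unused.
#' @return One-row tibble: `mu`, `sigma`, `n`, `method`, `lower`, `upper`.
#' @exportS3Method generics::tidy
tidy.gaussian_fit <- function(x, z = 2.58, ...) {
  ci <- coverage_interval(x, z)
  tibble::tibble(mu = x$mu, sigma = x$sigma, n = x$n, method = x$method,
                 lower = ci[["lower"]], upper = ci[["upper"]])
}

#' Tidy a prediction report
#'
#' @param x A `prediction_report`.
#' @param ... Unused.
#' @return The per-frame tibble of predicted, reference, and the ratio or
#'   deviation value.
#' @exportS3Method generics::tidy
tidy.prediction_report <- function(x, ...) {
  x$data
}

#' @rdname tidy.prediction_report
#' @exportS3Method generics::glance
glance.prediction_report <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n = nrow(x$data), mu = x$fit$mu, sigma = x$fit$sigma,
    rmse = sqrt(mean((x$data$predicted - x$data$reference)^2)),
    n_excluded = x$n_excluded
  )
}
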