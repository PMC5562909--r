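#' Select reference conformers per pattern for PEM
#'
#' The Prediction-with-Ensemble-Models parameter set is M patterns times n
#' reference conformers per pattern, each carrying its descriptor vector and
#' the properties to interpolate. Three selection modes trade cost against
#' variance: `"batch"` keeps every member of every pattern, `"stochastic"`
#' keeps a single seeded uniform draw per pattern, and `"mini-batch"`
#' (default, n = 10) keeps a small seeded sample without replacement —
#' clusters smaller than n contribute all their members.
#'
#' @param dataset A tibble with columns `trajectory_id`, `frame`, a pattern
#'   column, the dihedral descriptor columns, and the property columns.
#'   Typically built by joining `fit_patterns(...)$labels` with the
#'   descriptor and property tables; see [pem_dataset()].
#' @param dihedrals Character vector naming the descriptor columns.
#' @param properties Character vector naming the property columns (per-atom
#'   charge columns `charge_*` are picked up automatically in addition).
#' @param mode `"mini-batch"` (default), `"batch"`, or `"stochastic"`.
#' @param n References per pattern for mini-batch (default 10).
#' @param seed Integer seed for the sampling modes.
#' @param pattern_col Name of the pattern column (default `"pattern"`).
#' @param angular Use wrapped angular differences in distances (default TRUE).
#' @return A `reference_set`: list with `refs` (tibble), `dihedral_names`,
#'   `property_names`, `charge_cols`, `M`, `mode`, `n`, `seed`, `angular`.
#' @export
select_references <- function(dataset, dihedrals, properties = NULL,
                              mode = c("mini-batch", "batch", "stochastic"),
                              n = 10L, seed = 1L, pattern_col = "pattern",
                              angular = TRUE) {
  mode <- match.arg(mode)
  dataset <- tibble::as_tibble(dataset)
  if (!pattern_col %in% names(dataset)) {
    abort(sprintf("no `%s` column in dataset", pattern_col))
  }
  missing_dih <- setdiff(dihedrals, names(dataset))
  if (length(missing_dih)) {
    abort(paste0("descriptor column(s) missing: ", paste(missing_dih, collapse = ", ")))
  }
  charge_cols <- charge_columns(dataset)
  if (is.null(properties)) {
    properties <- setdiff(
      names(dataset)[vapply(dataset, is.numeric, logical(1))],
      c("trajectory_id", "frame", "time", pattern_col, dihedrals, charge_cols)
    )
  }
  prop_all <- c(properties, charge_cols)
  if (length(prop_all) == 0L) abort("no property columns to carry")
  ok <- stats::complete.cases(dataset[c(dihedrals, prop_all)])
  pool <- dataset[ok, , drop = FALSE]
  pool$.pattern <- as.integer(pool[[pattern_col]])

  all_patterns <- sort(unique(as.integer(dataset[[pattern_col]])))
  kept <- sort(unique(pool$.pattern))
  dropped <- setdiff(all_patterns, kept)
  if (length(dropped)) {
    warn(sprintf("pattern(s) %s had no property-bearing members and were dropped",
                 paste(dropped, collapse = ", ")))
  }
  if (length(kept) == 0L) abort("every pattern lacks property-bearing members")

  refs <- with_local_seed(seed, {
    purrr::map_dfr(kept, function(g) {
      sub <- pool[pool$.pattern == g, , drop = FALSE]
      take <- switch(mode,
        "batch" = seq_len(nrow(sub)),
        "stochastic" = sample.int(nrow(sub), 1L),
        "mini-batch" = if (nrow(sub) <= n) seq_len(nrow(sub)) else sample.int(nrow(sub), n)
      )
      sub[take, , drop = FALSE]
    })
  })
  meta <- intersect(c("trajectory_id", "frame", "time"), names(refs))
  refs <- dplyr::select(
    refs, dplyr::all_of(meta), pattern = ".pattern",
    dplyr::all_of(c(dihedrals, prop_all))
  )
  structure(
    list(refs = refs, dihedral_names = dihedrals,
         property_names = properties, charge_cols = charge_cols,
         M = length(kept), mode = mode, n = as.integer(n),
         seed = as.integer(seed), angular = angular),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set: M = %d patterns, %d references (%s), p = %d descriptors, %d propert%s>\n",
    x$M, nrow(x$refs), x$mode, length(x$dihedral_names),
    length(x$property_names) + (length(x$charge_cols) > 0),
    if (length(x$property_names) + (length(x$charge_cols) > 0) == 1) "y" else "ies"
  ))
  invisible(x)
}

#' Join pattern labels, descriptors, and properties into a PEM dataset
#'
#' @param model A `pattern_model` (or a label tibble with a pattern column).
#' @param descriptors Descriptor tibble from [compute_descriptors()].
#' @param properties Optional property tibble.
#' @return A tibble keyed by `(trajectory_id, frame)` with pattern,
#'   descriptor, and property columns.
#' @export
pem_dataset <- function(model, descriptors, properties = NULL) {
  labels <- if (inherits(model, "pattern_model")) model$labels else tibble::as_tibble(model)
  out <- dplyr::inner_join(labels, tibble::as_tibble(descriptors),
                           by = intersect(names(labels), names(descriptors)))
  if (!is.null(properties)) {
    out <- dplyr::left_join(out, tibble::as_tibble(properties),
                            by = c("trajectory_id", "frame"))
  }
  out
}

#' General distance between descriptor vectors
#'
#' Euclidean norm of the elementwise descriptor differences between a query
#' conformer and a reference. With `angular = TRUE` (default) each difference
#' is the wrapped circular difference in `(-180, 180]` degrees, so the
#' distance respects dihedral periodicity.
#'
#' @param x,x_ref Numeric descriptor vectors of equal length p, degrees.
#' @param angular Wrap differences circularly (default TRUE).
#' @return Non-negative scalar distance (degrees).
#' @examples
#' general_distance(c(179, 0), c(-179, 0)) # 2, not 358
#' @export
general_distance <- function(x, x_ref, angular = TRUE) {
  if (length(x) != length(x_ref)) {
    abort(sprintf("descriptor lengths differ: %d vs %d", length(x), length(x_ref)))
  }
  d <- if (angular) wrap_angle_diff(x, x_ref) else x - x_ref
  sqrt(sum(d^2))
}

# query matrix (q x p) vs reference matrix (r x p) -> q x r distance matrix
distance_matrix <- function(qx, rx, angular = TRUE) {
  q <- nrow(qx)
  r <- nrow(rx)
  d2 <- matrix(0, q, r)
  for (m in seq_len(ncol(qx))) {
    dm <- outer(qx[, m], rx[, m], `-`)
    if (angular) dm <- wrap_angle_diff(dm, 0)
    d2 <- d2 + dm^2
  }
  sqrt(d2)
}

#' PEM kernel weights for a query conformer
#'
#' Inverse-distance kernel weights over all (pattern, reference) entries.
#' `"shepard"` mode (default) is the normalized Shepard kernel
#' `w_ij = u_ij^(-p_w) / sum u^(-p_w)` with exponent `p_w` (default 4): the
#' weights are a partition of unity, continuous away from references, and
#' decay with the general distance so remote patterns contribute little.
#' `"as-printed"` mode evaluates the unnormalized literal form
#' `w_ij = (1/u_ij) / sum (1/u)^4` for comparison; its weights need not sum
#' to one. If the query coincides with one or more references (u = 0), the
#' weight collapses to those references, split equally — the continuous limit
#' of the kernel, guaranteeing exact interpolation at every reference.
#'
#' @param x Query descriptor vector (degrees, length p).
#' @param refs A `reference_set`.
#' @param mode `"shepard"` or `"as-printed"`.
#' @param p_w Kernel exponent (default 4).
#' @return Numeric weight vector aligned with `refs$refs` rows.
#' @export
pem_weights <- function(x, refs, mode = c("shepard", "as-printed"), p_w = 4) {
  mode <- match.arg(mode)
  stopifnot(inherits(refs, "reference_set"))
  rx <- as.matrix(refs$refs[refs$dihedral_names])
  if (nrow(rx) == 0L) abort("empty reference set")
  u <- distance_matrix(matrix(x, nrow = 1L), rx, refs$angular)[1L, ]
  kernel_weights(u, mode, p_w)
}

kernel_weights <- function(u, mode, p_w, zero_tol = 1e-9) {
  u <- unname(u)
  hits <- u <= zero_tol
  if (any(hits)) {
    w <- numeric(length(u))
    w[hits] <- 1 / sum(hits)
    return(w)
  }
  if (mode == "shepard") {
    lw <- -p_w * log(u)
    lw <- lw - max(lw) # overflow guard for very small distances
    w <- exp(lw)
    w / sum(w)
  } else {
    (1 / u) / sum((1 / u)^4)
  }
}

#' Predict a scalar property by ensemble-model interpolation
#'
#' The PEM estimate of a property at query descriptors X is the kernel-
#' weighted double sum over patterns i and their reference conformers j:
#' `V(X) = sum_i sum_j w_ij(X) T_ij`. No training beyond the clustering is
#' involved; one prediction costs O(M n) distance evaluations.
#'
#' @inheritParams pem_weights
#' @param property Name of the property column to interpolate.
#' @return Predicted scalar, in the property's units.
#' @export
pem_predict <- function(x, refs, property, mode = c("shepard", "as-printed"),
                        p_w = 4) {
  mode <- match.arg(mode)
  if (!property %in% names(refs$refs)) {
    abort(sprintf("unknown property '%s'", property))
  }
  w <- pem_weights(x, refs, mode, p_w)
  sum(w * refs$refs[[property]])
}

#' Predict per-atom partial charges by ensemble-model interpolation
#'
#' Applies the PEM weighted sum elementwise over the per-atom charge columns
#' with a single shared weight vector. With `renormalize = TRUE` the residual
#' between the configured net charge and the summed prediction is spread
#' uniformly over the atoms, so the returned vector sums to `net_charge`
#' exactly.
#'
#' @inheritParams pem_weights
#' @param renormalize Enforce the molecular net charge (default FALSE).
#' @param net_charge Total molecular charge in e (default 0).
#' @return Named numeric vector of per-atom charges, e.
#' @export
pem_predict_charges <- function(x, refs, mode = c("shepard", "as-printed"),
                                p_w = 4, renormalize = FALSE, net_charge = 0) {
  mode <- match.arg(mode)
  if (length(refs$charge_cols) == 0L) abort("reference set carries no charge columns")
  w <- pem_weights(x, refs, mode, p_w)
  q <- as.matrix(refs$refs[refs$charge_cols])
  pred <- as.vector(t(q) %*% w)
  names(pred) <- refs$charge_cols
  if (renormalize) {
    pred <- pred + (net_charge - sum(pred)) / length(pred)
  }
  pred
}

#' Predict a property for every row of a descriptor table
#'
#' Vectorized PEM over many query conformers; framewise it is identical to
#' calling [pem_predict()] on each row.
#'
#' @param descriptors Descriptor tibble (or matrix of angles).
#' @param refs A `reference_set`.
#' @inheritParams pem_predict
#' @return The descriptor table's key columns plus a `.pred` column.
#' @export
predict_timeseries <- function(descriptors, refs, property,
                               mode = c("shepard", "as-printed"), p_w = 4) {
  mode <- match.arg(mode)
  parts <- descriptor_parts(descriptors, refs$dihedral_names)
  rx <- as.matrix(refs$refs[refs$dihedral_names])
  u <- distance_matrix(parts$angles, rx, refs$angular)
  tvals <- refs$refs[[property]]
  if (is.null(tvals)) abort(sprintf("unknown property '%s'", property))
  pred <- apply(u, 1L, function(ui) sum(kernel_weights(ui, mode, p_w) * tvals))
  dplyr::bind_cols(parts$keys, tibble::tibble(.pred = pred))
}

#' Compare predictions against reference values
#'
#' The validation statistic of the PEM protocol: either the ratio series
#' predicted / reference, summarized by a Gaussian fit (a faithful predictor
#' gives mu near 1 with small sigma), or the deviation series
#' predicted - reference.
#'
#' @param predicted,reference Aligned numeric vectors.
#' @param mode `"ratio"` or `"deviation"`.
#' @return A `prediction_report`: list with `data` (tibble `predicted`,
#'   `reference`, `value`), `mode`, `fit` (a `gaussian_fit` of the values),
#'   `n_excluded` (ratio mode: zero-reference frames dropped).
#' @export
validate_predictions <- function(predicted, reference,
                                 mode = c("ratio", "deviation")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(reference) || length(predicted) == 0L) {
    abort("`predicted` and `reference` must be non-empty and aligned")
  }
  n_excluded <- 0L
  if (mode == "ratio") {
    keep <- reference != 0
    n_excluded <- sum(!keep)
    if (n_excluded > 0L) {
      warn(sprintf("%d frame(s) with zero reference excluded from ratios", n_excluded))
    }
    predicted <- predicted[keep]
    reference <- reference[keep]
    value <- predicted / reference
  } else {
    value <- predicted - reference
  }
  structure(
    list(
      data = tibble::tibble(predicted = predicted, reference = reference,
                            value = value),
      mode = mode,
      fit = fit_gaussian(value),
      n_excluded = n_excluded
    ),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report (%s): n = %d, mu = %.4g, sigma = %.4g>\n",
              x$mode, nrow(x$data), x$fit$mu, x$fit$sigma))
  invisible(x)
}

#' Persist / restore a reference set as JSON
#'
#' @param refs A `reference_set`.
#' @param path File path.
#' @return `path` (write) or the restored `reference_set` (read).
#' @export
write_reference_set <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  payload <- unclass(refs)
  payload$refs <- as.data.frame(refs$refs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$refs <- tibble::as_tibble(payload$refs)
  payload$charge_cols <- as.character(payload$charge_cols %||% character(0))
  payload$property_names <- as.character(payload$property_names %||% character(0))
  structure(payload[c("refs", "dihedral_names", "property_names", "charge_cols",
                      "M", "mode", "n", "seed", "angular")],
            class = "reference_set")
}
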