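#' Cluster conformers into meta-stable patterns with K-means
#'
#' Each meta-stable pattern is a basin of structurally similar conformers;
#' K-means over the dihedral descriptors identifies them. By default each
#' angle theta is embedded as `(cos theta, sin theta)` ("circular"
#' embedding), so the chord metric respects dihedral periodicity and
#' conformers at +179 and -179 degrees are near neighbours; `"raw"` clusters
#' the plain wrapped angles. Lloyd iterations run via [stats::kmeans()] from
#' k-means++ initial centers; the best of `n_init` seeded starts (lowest
#' within-cluster sum of squares) is kept, so results are deterministic given
#' `seed`.
#'
#' @param descriptors A descriptor tibble (see [compute_descriptors()]) or a
#'   plain numeric matrix of angles in degrees.
#' @param k Number of patterns (the package-wide default for chromophore
#'   analyses is 12).
#' @param embedding `"circular"` (default) or `"raw"`.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_init Number of k-means++ restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per start (default 300).
#' @param dihedrals Optional character vector naming the descriptor columns;
#'   defaults to every column after `trajectory_id`/`frame`/`time`.
#' @return A `pattern_model`: list with `k`, `embedding`, `seed`, `centroids`
#'   (embedded space), `centroids_deg` (back-mapped angles, degrees),
#'   `dihedral_names`, `inertia`, `sizes`, and `labels` (tibble
#'   `trajectory_id`, `frame`, `time`, `pattern` with patterns in `0:(k-1)`).
#' @export
fit_patterns <- function(descriptors, k, embedding = c("circular", "raw"),
                         seed = 1L, n_init = 10L, max_iter = 300L,
                         dihedrals = NULL) {
  embedding <- match.arg(embedding)
  parts <- descriptor_parts(descriptors, dihedrals)
  ang <- parts$angles
  if (nrow(ang) == 0L) abort("no descriptor rows to cluster")
  if (k < 1L) abort("`k` must be >= 1")
  emb <- embed_angles(ang, embedding)
  n_distinct <- nrow(unique(emb))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct embedded points", k, n_distinct))
  }

  fit <- with_local_seed(seed, kmeanspp_best(emb, k, n_init, max_iter))
  centroids <- fit$centers
  labels0 <- fit$cluster - 1L

  model <- structure(
    list(
      k = k, embedding = embedding, seed = seed,
      centroids = centroids,
      centroids_deg = centroids_to_degrees(centroids, embedding, ncol(ang)),
      dihedral_names = colnames(ang),
      inertia = fit$tot.withinss,
      sizes = tabulate(labels0 + 1L, nbins = k),
      labels = dplyr::bind_cols(parts$keys, tibble::tibble(pattern = labels0))
    ),
    class = "pattern_model"
  )
  model
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf(
    "<pattern_model: k = %d, embedding = %s, %d frames, inertia = %.4g>\n",
    x$k, x$embedding, nrow(x$labels), x$inertia
  ))
  invisible(x)
}

# split a descriptor tibble/matrix into key columns and the angle matrix
descriptor_parts <- function(descriptors, dihedrals = NULL) {
  if (is.matrix(descriptors)) {
    ang <- descriptors
    if (is.null(colnames(ang))) {
      colnames(ang) <- paste0("dih_", seq_len(ncol(ang)))
    }
    keys <- tibble::tibble(
      trajectory_id = "traj",
      frame = seq_len(nrow(ang)) - 1L,
      time = as.numeric(seq_len(nrow(ang)) - 1L)
    )
    return(list(keys = keys, angles = ang))
  }
  descriptors <- tibble::as_tibble(descriptors)
  meta <- intersect(c("trajectory_id", "frame", "time"), names(descriptors))
  if (is.null(dihedrals)) {
    dihedrals <- setdiff(names(descriptors), meta)
  }
  if (length(dihedrals) == 0L) abort("no dihedral columns found")
  ang <- as.matrix(descriptors[dihedrals])
  if (!is.numeric(ang) || !all(is.finite(ang))) {
    abort("descriptor columns must be finite numeric angles")
  }
  keys <- descriptors[meta]
  if (!"trajectory_id" %in% names(keys)) keys$trajectory_id <- "traj"
  if (!"frame" %in% names(keys)) keys$frame <- seq_len(nrow(ang)) - 1L
  if (!"time" %in% names(keys)) keys$time <- as.numeric(keys$frame)
  list(keys = keys[c("trajectory_id", "frame", "time")], angles = ang)
}

embed_angles <- function(ang, embedding) {
  if (embedding == "raw") {
    return(wrap_angle(ang))
  }
  rad <- ang * pi / 180
  emb <- cbind(cos(rad), sin(rad))
  colnames(emb) <- c(paste0("cos_", colnames(ang)), paste0("sin_", colnames(ang)))
  emb
}

centroids_to_degrees <- function(centroids, embedding, p) {
  if (embedding == "raw") {
    deg <- wrap_angle(centroids)
  } else {
    deg <- wrap_angle(atan2(centroids[, p + seq_len(p), drop = FALSE],
                            centroids[, seq_len(p), drop = FALSE]) * 180 / pi)
  }
  deg
}

# run RNG-dependent code under a seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# k-means++ seeding (Arthur & Vassilvitskii 2007)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      # all remaining mass at chosen centers: pick any distinct point
      cand <- which(!duplicated(rbind(centers[seq_len(j - 1L), , drop = FALSE], x))[-seq_len(j - 1L)])
      pick <- if (length(cand)) cand[1L] else sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

kmeanspp_best <- function(x, k, n_init, max_iter) {
  best <- NULL
  for (s in seq_len(max(1L, n_init))) {
    fit <- NULL
    for (try in 1:5) {
      init <- kmeanspp_centers(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init, iter.max = max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL
      )
      # empty clusters surface as fewer than k non-empty groups; re-draw
      if (!is.null(fit) && all(fit$size > 0L)) break
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed: could not find k non-empty clusters")
  best
}

#' Classify a conformer into its meta-stable pattern
#'
#' The fitted clustering acts as a classifier: a query descriptor vector is
#' assigned to the nearest centroid in the model's embedding space. Ties are
#' broken toward the lowest pattern id.
#'
#' @param model A `pattern_model` from [fit_patterns()].
#' @param x Numeric vector of angles (degrees, length p) or a matrix /
#'   descriptor tibble of queries.
#' @return Integer pattern id(s) in `0:(k-1)`.
#' @export
assign_pattern <- function(model, x) {
  stopifnot(inherits(model, "pattern_model"))
  p <- length(model$dihedral_names)
  if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1L)
  } else if (!is.matrix(x)) {
    x <- descriptor_parts(x, model$dihedral_names)$angles
  }
  if (ncol(x) != p) {
    abort(sprintf("query has %d descriptors; model expects %d", ncol(x), p))
  }
  colnames(x) <- model$dihedral_names
  emb <- embed_angles(x, model$embedding)
  d2 <- outer(rowSums(emb^2), rep(1, model$k)) -
    2 * emb %*% t(model$centroids) +
    outer(rep(1, nrow(emb)), rowSums(model$centroids^2))
  # lowest-index tie-break, robust to rounding in the distance expansion
  apply(d2, 1L, function(r) which(r <= min(r) + 1e-9 * (1 + abs(min(r))))[1L]) - 1L
}

#' Sweep cluster counts and report per-cluster geometric spread
#'
#' Diagnoses the choice of k: for each candidate it fits a model under the
#' same seed protocol and reports the member count and circular standard
#' deviation of each cluster's dihedrals, plus the within-cluster inertia.
#' The working criterion is geometric tightness: pick the smallest k at which
#' the maximum per-cluster spread falls below what you consider "one basin"
#' (heavy-atom deviations under about 0.5 Angstrom in the motivating data).
#'
#' @inheritParams fit_patterns
#' @param k_values Integer vector of candidate cluster counts.
#' @return A tibble with one row per k: `k`, `inertia`, `max_spread_deg`,
#'   `mean_spread_deg`, `min_size`, and a list-column `diagnostics` holding
#'   the per-cluster table from [cluster_diagnostics()].
#' @export
select_k <- function(descriptors, k_values, embedding = c("circular", "raw"),
                     seed = 1L, n_init = 10L, max_iter = 300L,
                     dihedrals = NULL) {
  embedding <- match.arg(embedding)
  if (length(k_values) == 0L) abort("`k_values` must be non-empty")
  purrr::map_dfr(k_values, function(k) {
    fit <- tryCatch(
      fit_patterns(descriptors, k, embedding, seed, n_init, max_iter, dihedrals),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        k = k, inertia = NA_real_, max_spread_deg = NA_real_,
        mean_spread_deg = NA_real_, min_size = NA_integer_,
        diagnostics = list(NULL)
      ))
    }
    diag <- cluster_diagnostics(fit, descriptors, dihedrals)
    tibble::tibble(
      k = k, inertia = fit$inertia,
      max_spread_deg = max(diag$spread_deg),
      mean_spread_deg = mean(diag$spread_deg),
      min_size = min(diag$n),
      diagnostics = list(diag)
    )
  })
}

#' Per-cluster membership and angular spread
#'
#' @param model A `pattern_model`.
#' @param descriptors The descriptor table the model was fitted on.
#' @param dihedrals Optional descriptor column names.
#' @return Tibble: `pattern`, `n`, `spread_deg` (root-mean circular standard
#'   deviation over the dihedrals, degrees).
#' @export
cluster_diagnostics <- function(model, descriptors, dihedrals = NULL) {
  ang <- descriptor_parts(descriptors, dihedrals %||% model$dihedral_names)$angles
  lab <- model$labels$pattern
  purrr::map_dfr(0:(model$k - 1L), function(g) {
    a <- ang[lab == g, , drop = FALSE]
    tibble::tibble(
      pattern = g, n = nrow(a),
      spread_deg = if (nrow(a) == 0L) NA_real_ else {
        sqrt(mean(circ_sd_deg(a)^2))
      }
    )
  })
}

# circular standard deviation per column, degrees
circ_sd_deg <- function(ang) {
  rad <- ang * pi / 180
  rbar <- sqrt(colMeans(cos(rad))^2 + colMeans(sin(rad))^2)
  rbar <- pmin(pmax(rbar, 1e-12), 1)
  sqrt(-2 * log(rbar)) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimizing the RMSD of `mov_coords`
#' onto `ref_coords`, via the SVD of the cross-covariance with the usual
#' reflection guard, and reports the post-fit RMSD. Used to measure the
#' Cartesian tightness of a pattern (the motivating analysis aligns heavy
#' atoms and expects per-pattern deviations under ~0.5 Angstrom).
#'
#' @param ref_coords,mov_coords `n x 3` matrices, n >= 3, Angstrom. Pass a
#'   logical/integer `mask` to superpose on a subset (e.g. heavy atoms only).
#' @param mask Optional atom selection applied to both structures.
#' @return List: `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the masked atoms), `fitted` (all of `mov_coords`
#'   transformed).
#' @export
superpose <- function(ref_coords, mov_coords, mask = NULL) {
  stopifnot(is.matrix(ref_coords), is.matrix(mov_coords),
            ncol(ref_coords) == 3L, ncol(mov_coords) == 3L,
            nrow(ref_coords) == nrow(mov_coords))
  if (!is.null(mask)) {
    ref <- ref_coords[mask, , drop = FALSE]
    mov <- mov_coords[mask, , drop = FALSE]
  } else {
    ref <- ref_coords
    mov <- mov_coords
  }
  if (nrow(ref) < 3L) abort("superposition needs at least 3 atoms")
  cr <- colMeans(ref)
  cm <- colMeans(mov)
  a <- sweep(ref, 2, cr)
  b <- sweep(mov, 2, cm)
  if (qr(a)$rank < 2L) abort("degenerate (collinear) reference coordinates")
  h <- t(b) %*% a
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted_sel <- sweep(b %*% t(rot), 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted_sel - ref)^2)))
  fitted_all <- sweep(sweep(mov_coords, 2, cm) %*% t(rot), 2, cr, `+`)
  list(rotation = rot, translation = cr - as.vector(cm %*% t(rot)) ,
       rmsd = rmsd, fitted = fitted_all)
}

#' Merge mirror-symmetric pattern pairs
#'
#' Dihedral rotations in a near-planar chromophore come in clockwise /
#' anti-clockwise pairs: pattern i and its mirror i' have centroid dihedrals
#' related by elementwise negation. This detects such pairs (greedy nearest
#' pairing on the circular distance between `c_i` and `-c_j`, accepted within
#' `tolerance_deg`), maps each pair to the lower pattern id, and relabels the
#' frames, halving the pattern count where the mirror symmetry is real.
#' A centroid near (0, ..., 0) or (+-180, ...) is its own mirror and maps to
#' itself.
#'
#' @param model A `pattern_model`.
#' @param tolerance_deg Acceptance tolerance on the root-mean-square circular
#'   mismatch between a centroid and a partner's negation (default 10).
#' @return List: `pairs` (tibble `pattern`, `merged` giving the mapping),
#'   `labels` (the model's label tibble with a `merged` column), `n_merged`
#'   (number of distinct merged patterns).
#' @export
merge_symmetric_pairs <- function(model, tolerance_deg = 10) {
  stopifnot(inherits(model, "pattern_model"))
  cen <- model$centroids_deg
  k <- model$k
  # mismatch(i, j): how far centroid j is from the mirror image of centroid i
  mis <- matrix(Inf, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      mis[i, j] <- sqrt(mean(wrap_angle_diff(cen[j, ], -cen[i, ])^2))
    }
  }
  mapping <- seq_len(k) - 1L
  taken <- rep(FALSE, k)
  # self-mirrors first: diagonal within tolerance
  for (i in seq_len(k)) {
    if (!taken[i] && mis[i, i] <= tolerance_deg) taken[i] <- TRUE
  }
  # greedy nearest pairing among the rest
  repeat {
    free <- which(!taken)
    if (length(free) < 2L) break
    sub <- mis[free, free, drop = FALSE]
    diag(sub) <- Inf
    if (min(sub) > tolerance_deg) break
    idx <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- free[idx[1L]]
    j <- free[idx[2L]]
    lo <- min(i, j) - 1L
    mapping[c(i, j)] <- lo
    taken[c(i, j)] <- TRUE
  }
  leftovers <- which(!taken & mapping == seq_len(k) - 1L)
  multi <- sum(rowSums(mis <= tolerance_deg) > 2L)
  if (multi > 0L) {
    warn(sprintf("%d centroid(s) had multiple mirror candidates; greedy nearest pairing used", multi))
  }
  pairs <- tibble::tibble(pattern = seq_len(k) - 1L, merged = mapping)
  labels <- model$labels
  labels$merged <- mapping[labels$pattern + 1L]
  list(pairs = pairs, labels = labels, n_merged = dplyr::n_distinct(mapping))
}
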