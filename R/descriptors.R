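#' Compute dihedral-angle descriptors for every frame of a trajectory
#'
#' The molecular descriptor vector of a conformer is the ordered list of its
#' configured dihedral angles, wrapped to `[-180, 180)` degrees. Internal
#' coordinates are invariant under rigid-body translation and rotation, which
#' is what makes them usable across uncoupled trajectories.
#'
#' @param traj A `trajectory` object (see [read_xyz_trajectory()]).
#' @param dihedrals A tibble from [read_dihedral_spec()]: columns `name` and
#'   1-based atom indices `a, b, c, d`.
#' @return A tibble with one row per frame: `trajectory_id`, `frame`
#'   (0-based), `time` (fs), then one column per dihedral named after
#'   `dihedrals$name`, degrees in `[-180, 180)`.
#' @examples
#' xyz <- chain_from_torsions(c(37, -120))
#' traj <- trajectory_from_coords(list(xyz), paste0("C", 1:5), timestep_fs = 0.5)
#' spec <- tibble::tibble(name = "phi", a = 1, b = 2, c = 3, d = 4)
#' compute_descriptors(traj, spec)
#' @export
compute_descriptors <- function(traj, dihedrals) {
  stopifnot(inherits(traj, "trajectory"))
  validate_dihedral_spec(dihedrals, n_atoms = length(traj$symbols))
  idx <- as.matrix(dihedrals[, c("a", "b", "c", "d")])
  vals <- purrr::imap(traj$coords, function(xyz, fi) {
    tryCatch(
      vapply(seq_len(nrow(idx)), function(r) {
        dihedral_angle(xyz[idx[r, 1], ], xyz[idx[r, 2], ],
                       xyz[idx[r, 3], ], xyz[idx[r, 4], ])
      }, numeric(1)),
      error = function(e) {
        abort(sprintf("frame %d: %s", fi - 1L, conditionMessage(e)))
      }
    )
  })
  mat <- do.call(rbind, vals)
  colnames(mat) <- dihedrals$name
  dplyr::bind_cols(
    tibble::tibble(
      trajectory_id = traj$trajectory_id,
      frame = seq_along(traj$coords) - 1L,
      time = traj$times
    ),
    tibble::as_tibble(mat)
  )
}

#' Build a trajectory object from in-memory coordinates
#'
#' @param coords List of `n_atoms x 3` coordinate matrices (Angstrom), one
#'   per frame.
#' @param symbols Character vector of element symbols.
#' @param timestep_fs Frame spacing in fs.
#' @param trajectory_id Trajectory label.
#' @return A `trajectory` object.
#' @export
trajectory_from_coords <- function(coords, symbols, timestep_fs = 0.5,
                                   trajectory_id = "traj") {
  stopifnot(is.list(coords), length(coords) >= 1)
  for (xyz in coords) {
    if (!is.matrix(xyz) || ncol(xyz) != 3L || nrow(xyz) != length(symbols) ||
        !all(is.finite(xyz))) {
      abort("each frame must be a finite n_atoms x 3 matrix matching `symbols`")
    }
  }
  new_trajectory(trajectory_id, symbols, coords, timestep_fs)
}

#' Indices of interior local minima of a scalar series
#'
#' Used to subsample trajectory snapshots at local minima of a per-frame
#' energy before property statistics and reference selection. Endpoints are
#' never returned. With `strict = TRUE` (default) an index `i` qualifies iff
#' `series[i] < series[i - 1]` and `series[i] < series[i + 1]`; with
#' `strict = FALSE`, interior plateaus that are flanked by strictly larger
#' values count as a single minimum reported at their first index.
#'
#' @param series Numeric vector, length at least 3, all finite.
#' @param strict Logical; plateau handling as described above.
#' @return Integer vector of 0-based frame indices (possibly empty), matching
#'   the `frame` column of descriptor and property tables.
#' @examples
#' filter_local_minima(c(3, 1, 2, 0, 4)) # frames 1 and 3
#' @export
filter_local_minima <- function(series, strict = TRUE) {
  if (length(series) < 3L) abort("`series` must have length >= 3")
  if (!all(is.finite(series))) abort("`series` contains non-finite values")
  n <- length(series)
  if (strict) {
    i <- 2:(n - 1)
    return(i[series[i] < series[i - 1] & series[i] < series[i + 1]] - 1L)
  }
  # plateau mode: run-length encode, a run is a minimum if both neighbours
  # are strictly larger; report the run's first interior index
  r <- rle(series)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in seq_along(r$values)) {
    if (j == 1L || j == length(r$values)) next
    if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]) {
      out <- c(out, starts[j])
    }
  }
  out - 1L
}
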