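#' Read a multi-frame XYZ trajectory
#'
#' Parses the standard multi-frame XYZ format (repeated blocks: atom count
#' line, comment line, then one `symbol x y z` line per atom, coordinates in
#' Angstrom) into a trajectory object. Frame times are assigned as
#' `(frame - 1) * timestep_fs`.
#'
#' @param path Path to an XYZ file.
#' @param timestep_fs Time between consecutive frames, femtoseconds.
#' @param trajectory_id Label for the trajectory; defaults to the file name
#'   without extension.
#' @return A `trajectory` object: list with `trajectory_id`, `symbols`
#'   (character vector, shared by all frames), `coords` (list of
#'   `n_atoms x 3` matrices), `times` (fs), `timestep` (fs).
#' @seealso [write_xyz_trajectory()], [compute_descriptors()]
#' @export
read_xyz_trajectory <- function(path, timestep_fs = 0.5,
                                trajectory_id = NULL) {
  lines <- readLines(path)
  lines <- sub("\\s+$", "", lines)
  # drop trailing blank lines only; blanks inside a block are malformed
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) abort(paste0("no frames in XYZ file: ", path))
  if (is.null(trajectory_id)) {
    trajectory_id <- sub("\\.[^.]*$", "", basename(path))
  }
  coords <- list()
  symbols <- NULL
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    n_atoms <- suppressWarnings(as.integer(lines[pos]))
    if (is.na(n_atoms) || n_atoms < 1L) {
      abort(sprintf("frame %d: malformed atom-count line %d", frame, pos))
    }
    if (pos + 1L + n_atoms > length(lines)) {
      abort(sprintf("frame %d: truncated block (expected %d atom lines)",
                    frame, n_atoms))
    }
    atom_lines <- lines[(pos + 2L):(pos + 1L + n_atoms)]
    fields <- strsplit(trimws(atom_lines), "\\s+")
    if (any(lengths(fields) < 4L)) {
      abort(sprintf("frame %d: atom line with fewer than 4 fields", frame))
    }
    syms <- vapply(fields, `[[`, character(1), 1L)
    xyz <- matrix(
      suppressWarnings(as.numeric(t(vapply(fields, function(f) f[2:4],
                                           character(3))))),
      ncol = 3L, byrow = FALSE
    )
    if (anyNA(xyz) || !all(is.finite(xyz))) {
      abort(sprintf("frame %d: non-numeric or non-finite coordinate", frame))
    }
    if (is.null(symbols)) {
      symbols <- syms
    } else if (length(syms) != length(symbols) || any(syms != symbols)) {
      abort(sprintf("frame %d: atom count or symbol order differs from frame 1",
                    frame))
    }
    coords[[frame]] <- xyz
    pos <- pos + 2L + n_atoms
  }
  new_trajectory(trajectory_id, symbols, coords, timestep_fs)
}

new_trajectory <- function(trajectory_id, symbols, coords, timestep_fs) {
  structure(
    list(
      trajectory_id = trajectory_id,
      symbols = symbols,
      coords = coords,
      times = (seq_along(coords) - 1) * timestep_fs,
      timestep = timestep_fs
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory '%s': %d frames, %d atoms, timestep %g fs>\n",
    x$trajectory_id, length(x$coords), length(x$symbols), x$timestep
  ))
  invisible(x)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A `trajectory` object.
#' @param path Output file path.
#' @param digits Coordinate decimal places (default 8).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 8) {
  stopifnot(inherits(traj, "trajectory"))
  n_atoms <- length(traj$symbols)
  blocks <- purrr::imap_chr(traj$coords, function(xyz, i) {
    paste0(
      n_atoms, "\n",
      sprintf("frame %d t= %g fs", i - 1L, traj$times[i]), "\n",
      paste(sprintf(paste0("%-2s %.", digits, "f %.", digits, "f %.", digits, "f"),
                    traj$symbols, xyz[, 1], xyz[, 2], xyz[, 3]),
            collapse = "\n")
    )
  })
  writeLines(blocks, path)
  invisible(path)
}

#' Read a dihedral-descriptor definition file
#'
#' Whitespace- or comma-delimited text with a header `name a b c d`; atom
#' indices are 1-based as chemists write them. Lines starting with `#` are
#' comments.
#'
#' @param path Path to the definition file.
#' @return A tibble with columns `name` and integer `a, b, c, d` (1-based).
#' @export
read_dihedral_spec <- function(path) {
  df <- readr::read_table(path, comment = "#", show_col_types = FALSE)
  names(df) <- tolower(names(df))
  required <- c("name", "a", "b", "c", "d")
  if (!all(required %in% names(df))) {
    abort("dihedral spec needs columns: name a b c d")
  }
  spec <- tibble::as_tibble(df[required])
  validate_dihedral_spec(spec)
  spec
}

validate_dihedral_spec <- function(spec, n_atoms = NULL) {
  idx <- as.matrix(spec[, c("a", "b", "c", "d")])
  if (anyNA(idx) || any(idx < 1) || any(idx != round(idx))) {
    abort("dihedral atom indices must be positive integers (1-based)")
  }
  if (any(apply(idx, 1, function(r) length(unique(r)) != 4L))) {
    abort("each dihedral needs four distinct atom indices")
  }
  if (!is.null(n_atoms) && any(idx > n_atoms)) {
    abort(sprintf("dihedral atom index exceeds atom count (%d)", n_atoms))
  }
  invisible(spec)
}

#' Read or write a per-frame property table
#'
#' Delimited text (tab by default) with header columns `trajectory_id`,
#' `frame` (0-based frame index), then named scalar properties (for example
#' `energy`, `excitation_energy`) and optionally per-atom charges as
#' `charge_1 .. charge_A`. Property tables are joined to descriptor tables by
#' `(trajectory_id, frame)`.
#'
#' @param path File path.
#' @return A tibble keyed by `trajectory_id` and `frame`.
#' @export
read_property_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("trajectory_id", "frame") %in% names(df))) {
    abort("property table needs `trajectory_id` and `frame` columns")
  }
  df$trajectory_id <- as.character(df$trajectory_id)
  tibble::as_tibble(df)
}

#' @param tbl A tibble with `trajectory_id` and `frame` columns.
#' @rdname read_property_table
#' @export
write_property_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Names of the per-atom charge columns in a property table
#'
#' @param tbl A property tibble.
#' @return Character vector `charge_1 .. charge_A` present in `tbl`, ordered
#'   by atom index (possibly empty).
#' @export
charge_columns <- function(tbl) {
  nm <- grep("^charge_[0-9]+$", names(tbl), value = TRUE)
  nm[order(as.integer(sub("^charge_", "", nm)))]
}
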