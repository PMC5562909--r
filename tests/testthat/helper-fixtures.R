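# shared fixtures built in code

# toy trajectory: n frames of a 6-atom chain with prescribed torsion paths
toy_trajectory <- function(torsion_rows, timestep = 0.5, id = "toy") {
  coords <- lapply(seq_len(nrow(torsion_rows)), function(i) {
    chain_from_torsions(torsion_rows[i, ])
  })
  trajectory_from_coords(coords, rep("C", ncol(torsion_rows) + 3L),
                         timestep_fs = timestep, trajectory_id = id)
}

chain_dihedral_spec <- function(p) {
  tibble::tibble(
    name = paste0("dih_", seq_len(p)),
    a = seq_len(p), b = seq_len(p) + 1L, c = seq_len(p) + 2L, d = seq_len(p) + 3L
  )
}

# independent torsion oracle: normal-vector cross products + atan2, with the
# sign taken from the triple product against the central bond
oracle_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  cosphi <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  cosphi <- max(min(cosphi, 1), -1)
  phi <- acos(cosphi) * 180 / pi
  if (sum(pracma::cross(n1, n2) * b2) < 0) phi <- -phi
  pemnet::wrap_angle(phi)
}

# quaternion-method rigid superposition oracle (Horn 1987); returns RMSD
oracle_quaternion_rmsd <- function(ref, mov) {
  a <- sweep(ref, 2, colMeans(ref))
  b <- sweep(mov, 2, colMeans(mov))
  sxx <- t(b) %*% a
  s <- function(i, j) sxx[i, j]
  nmat <- matrix(c(
    s(1,1)+s(2,2)+s(3,3), s(2,3)-s(3,2),        s(3,1)-s(1,3),        s(1,2)-s(2,1),
    s(2,3)-s(3,2),        s(1,1)-s(2,2)-s(3,3), s(1,2)+s(2,1),        s(3,1)+s(1,3),
    s(3,1)-s(1,3),        s(1,2)+s(2,1),        s(2,2)-s(1,1)-s(3,3), s(2,3)+s(3,2),
    s(1,2)-s(2,1),        s(3,1)+s(1,3),        s(2,3)+s(3,2),        s(3,3)-s(1,1)-s(2,2)
  ), 4, 4, byrow = TRUE)
  q <- eigen(nmat, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- b %*% t(rot)
  sqrt(mean(rowSums((fitted - a)^2)))
}

# random rotation matrix from a seeded quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
}

# naive direct-summation PEM oracle: scalar loops, no shared code path
oracle_pem <- function(x, ref_mat, tvals, p_w = 4, angular = TRUE,
                       mode = "shepard") {
  u <- apply(ref_mat, 1, function(r) {
    d <- x - r
    if (angular) d <- ((d + 180) %% 360) - 180  # symmetric; |d| identical
    sqrt(sum(d^2))
  })
  if (any(u < 1e-9)) {
    w <- as.numeric(u < 1e-9)
    w <- w / sum(w)
  } else if (mode == "shepard") {
    w <- u^(-p_w) / sum(u^(-p_w))
  } else {
    w <- (1 / u) / sum((1 / u)^4)
  }
  sum(w * tvals)
}

small_refs <- function(ref_mat, tvals, charges = NULL, angular = TRUE) {
  p <- ncol(ref_mat)
  refs <- tibble::tibble(
    trajectory_id = "t", frame = seq_len(nrow(ref_mat)) - 1L,
    pattern = 0L
  )
  colnames(ref_mat) <- paste0("dih_", seq_len(p))
  refs <- dplyr::bind_cols(refs, tibble::as_tibble(ref_mat))
  refs$energy <- tvals
  charge_cols <- character(0)
  if (!is.null(charges)) {
    colnames(charges) <- paste0("charge_", seq_len(ncol(charges)))
    refs <- dplyr::bind_cols(refs, tibble::as_tibble(charges))
    charge_cols <- colnames(charges)
  }
  structure(
    list(refs = refs, dihedral_names = paste0("dih_", seq_len(p)),
         property_names = "energy", charge_cols = charge_cols,
         M = 1L, mode = "batch", n = nrow(ref_mat), seed = 1L,
         angular = angular),
    class = "reference_set"
  )
}
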