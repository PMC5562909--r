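#' Define a synthetic trajectory-generating model
#'
#' The generator emulates the statistical structure the pattern-mining
#' pipeline assumes in real excited-state ensembles: a Markov chain over
#' k latent conformational states (the planted meta-stable patterns), von
#' Mises dihedral emissions around per-state mean angles, and properties
#' drawn from a smooth periodic surface of the dihedrals plus Gaussian
#' noise. Per-atom charges come from independent Fourier surfaces shifted so
#' each frame's charges sum exactly to `net_charge`.
#'
#' The scalar-property surface is the truncated Fourier form
#' `T*(X) = a0 + sum_m (b_m cos theta_m + c_m sin theta_m)` — smooth,
#' periodic, and cheaply differentiable, encoding the premise that similar
#' conformations have similar properties.
#'
#' @param transition_matrix k x k row-stochastic matrix among latent states.
#' @param state_centers k x p matrix of per-state mean dihedrals, degrees.
#' @param state_kappa von Mises concentration(s), length 1 or k (default 50,
#'   about an 8-degree angular spread).
#' @param property_coeffs List with `a0` (scalar), `b`, `c` (length-p
#'   vectors) for the scalar property surface.
#' @param noise_sigma Additive Gaussian property noise, property units.
#' @param charge_coeffs Optional list with `a0`, `b`, `c` each having one row
#'   per atom (`b`, `c` are A x p matrices) for per-atom charge surfaces.
#' @param net_charge Exact per-frame total charge, e (default 0).
#' @param charge_noise_sigma Additive per-atom charge noise before the net-
#'   charge shift (default 0).
#' @param timestep Frame spacing, fs (default 0.5).
#' @param property_name Name for the scalar property column (default
#'   `"excitation_energy"`).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(transition_matrix, state_centers, state_kappa = 50,
                           property_coeffs, noise_sigma = 0.05,
                           charge_coeffs = NULL, net_charge = 0,
                           charge_noise_sigma = 0, timestep = 0.5,
                           property_name = "excitation_energy") {
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != ncol(tm) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-8)) {
    abort("`transition_matrix` must be square, non-negative, rows summing to 1")
  }
  centers <- as.matrix(state_centers)
  if (nrow(centers) != nrow(tm)) {
    abort("`state_centers` must have one row per state")
  }
  kappa <- rep(state_kappa, length.out = nrow(tm))
  if (any(kappa <= 0)) abort("`state_kappa` must be positive")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  p <- ncol(centers)
  stopifnot(length(property_coeffs$b) == p, length(property_coeffs$c) == p,
            length(property_coeffs$a0) == 1L)
  structure(
    list(
      k = nrow(tm), p = p, transition_matrix = tm,
      state_centers = wrap_angle(centers), state_kappa = kappa,
      property_coeffs = property_coeffs, noise_sigma = noise_sigma,
      charge_coeffs = charge_coeffs, net_charge = net_charge,
      charge_noise_sigma = charge_noise_sigma,
      timestep = timestep, property_name = property_name,
      dihedral_names = paste0("dih_", seq_len(p))
    ),
    class = "synthetic_spec"
  )
}

#' Noiseless property surface of a synthetic spec
#'
#' Evaluates `T*(X)` (the planted truncated-Fourier property surface) at
#' descriptor vectors — the ground-truth oracle against which predictions and
#' noise calibration are checked.
#'
#' @param spec A `synthetic_spec`.
#' @param x Length-p descriptor vector (degrees) or an n x p matrix.
#' @return Numeric value(s) of the surface.
#' @export
property_oracle <- function(spec, x) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != spec$p) abort("descriptor length mismatch with spec")
  rad <- x * pi / 180
  as.vector(
    spec$property_coeffs$a0 +
      cos(rad) %*% spec$property_coeffs$b +
      sin(rad) %*% spec$property_coeffs$c
  )
}

# per-atom charge surfaces, then exact net-charge shift; A x 1 result per frame
charge_oracle <- function(spec, x) {
  cc <- spec$charge_coeffs
  if (is.null(cc)) return(NULL)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  rad <- x * pi / 180
  raw <- matrix(cc$a0, nrow(x), length(cc$a0), byrow = TRUE) +
    cos(rad) %*% t(cc$b) + sin(rad) %*% t(cc$c)
  raw + (spec$net_charge - rowSums(raw)) / ncol(raw)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler for circular emissions around a mean
#' direction. Returns degrees wrapped to `[-180, 180)`.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration (> 0); large kappa approaches a wrapped
#'   Gaussian with sd `1/sqrt(kappa)` radians.
#' @return Numeric vector of n angles, degrees.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 0) abort("`kappa` must be positive")
  mu <- mu_deg * pi / 180
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nf <- sum(ok)
    if (nf > 0L) {
      u3 <- runif(nf)
      theta <- sign(u3 - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nf)] <- theta
      got <- got + nf
    }
  }
  wrap_angle((mu + out) * 180 / pi)
}

#' Simulate an ensemble of synthetic trajectories
#'
#' Each trajectory starts from the chain's stationary distribution, evolves
#' by the transition matrix, and emits von Mises dihedrals around the current
#' state's center; properties are the planted surface plus noise. Fully
#' reproducible given `seed`.
#'
#' @param spec A `synthetic_spec`.
#' @param n_traj,n_frames Ensemble size and frames per trajectory.
#' @param seed Integer seed.
#' @return A `synthetic_dataset`: list with `descriptors` (tibble:
#'   `trajectory_id`, `frame`, `time`, `state` ground truth, dihedral
#'   columns), `properties` (tibble: keys, scalar property, charge columns if
#'   configured), `spec`, `seed`.
#' @export
simulate_trajectories <- function(spec, n_traj, n_frames, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_traj < 1L || n_frames < 1L) abort("`n_traj` and `n_frames` must be >= 1")
  k <- spec$k
  p <- spec$p
  pi0 <- stationary_distribution(spec$transition_matrix)
  with_local_seed(seed, {
    all <- purrr::map(seq_len(n_traj), function(tj) {
      states <- integer(n_frames)
      states[1L] <- sample.int(k, 1L, prob = pi0)
      if (n_frames > 1L) {
        for (t in 2:n_frames) {
          states[t] <- sample.int(k, 1L, prob = spec$transition_matrix[states[t - 1L], ])
        }
      }
      ang <- matrix(0, n_frames, p)
      for (s in unique(states)) {
        rows <- which(states == s)
        for (m in seq_len(p)) {
          ang[rows, m] <- rvonmises_deg(length(rows),
                                        spec$state_centers[s, m],
                                        spec$state_kappa[s])
        }
      }
      list(states = states, ang = ang)
    })
    states <- unlist(purrr::map(all, "states"))
    ang <- do.call(rbind, purrr::map(all, "ang"))
    colnames(ang) <- spec$dihedral_names
    keys <- tibble::tibble(
      trajectory_id = rep(sprintf("traj_%03d", seq_len(n_traj)), each = n_frames),
      frame = rep(seq_len(n_frames) - 1L, n_traj),
      time = rep((seq_len(n_frames) - 1L) * spec$timestep, n_traj)
    )
    descriptors <- dplyr::bind_cols(
      keys, tibble::tibble(state = states - 1L), tibble::as_tibble(ang)
    )
    prop <- property_oracle(spec, ang) +
      rnorm(nrow(ang), sd = spec$noise_sigma)
    properties <- dplyr::bind_cols(keys, tibble::tibble(!!spec$property_name := prop))
    q <- charge_oracle(spec, ang)
    if (!is.null(q)) {
      if (spec$charge_noise_sigma > 0) {
        eps <- matrix(rnorm(length(q), sd = spec$charge_noise_sigma),
                      nrow(q), ncol(q))
        eps <- eps - rowMeans(eps) # keep the net charge exact
        q <- q + eps
      }
      colnames(q) <- paste0("charge_", seq_len(ncol(q)))
      properties <- dplyr::bind_cols(properties, tibble::as_tibble(q))
    }
    structure(
      list(descriptors = descriptors, properties = properties,
           spec = spec, seed = as.integer(seed)),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d states, %d trajectories x %d frames, p = %d, seed = %d>\n",
    x$spec$k, dplyr::n_distinct(x$descriptors$trajectory_id),
    max(x$descriptors$frame) + 1L, x$spec$p, x$seed
  ))
  invisible(x)
}

#' Embed a synthetic dataset as Cartesian XYZ trajectories
#'
#' Realizes each frame's p dihedrals as the torsions of a toy carbon chain of
#' p + 3 atoms (see [chain_from_torsions()]), so synthetic data round-trips
#' through the same multi-frame XYZ reader/writer and descriptor computation
#' as real trajectories. The matching dihedral definitions are the chain's
#' consecutive quadruples.
#'
#' @param dataset A `synthetic_dataset`.
#' @return List: `trajectories` (list of `trajectory` objects) and
#'   `dihedrals` (spec tibble usable with [compute_descriptors()]).
#' @export
dataset_to_trajectories <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  p <- dataset$spec$p
  symbols <- rep("C", p + 3L)
  dihedrals <- tibble::tibble(
    name = dataset$spec$dihedral_names,
    a = seq_len(p), b = seq_len(p) + 1L, c = seq_len(p) + 2L, d = seq_len(p) + 3L
  )
  ang_cols <- dataset$spec$dihedral_names
  trajectories <- dataset$descriptors |>
    dplyr::group_split(.data$trajectory_id) |>
    purrr::map(function(df) {
      coords <- purrr::map(seq_len(nrow(df)), function(i) {
        chain_from_torsions(as.numeric(df[i, ang_cols]))
      })
      trajectory_from_coords(coords, symbols, dataset$spec$timestep,
                             trajectory_id = df$trajectory_id[1L])
    })
  list(trajectories = trajectories, dihedrals = dihedrals)
}

#' Construct a named benchmark dataset with known ground truth
#'
#' Presets with planted structure and machine-readable expectations:
#' \describe{
#'   \item{`two_state_easy`}{2 well-separated states, kappa 50 — clustering
#'     should recover the planted labels essentially perfectly.}
#'   \item{`twelve_state_mirror`}{12 states built as 6 mirror pairs
#'     (centers of pair i' are the elementwise negation of pair i), kappa 50
#'     — emulates clockwise/anti-clockwise conformer pairs that merge to 6
#'     patterns.}
#'   \item{`noisy_overlap`}{3 states, kappa 8 (about 21-degree spread) and
#'     larger property noise — a hard case; expectations carry no ARI
#'     guarantee.}
#' }
#'
#' @param preset_name One of the presets above.
#' @param n_traj,n_frames Ensemble size (defaults per preset).
#' @param seed Integer seed.
#' @return List: `dataset` (a `synthetic_dataset`), `expected` (list with
#'   `k`, `state_centers`, `transition_matrix`, `stationary`, `labels`
#'   ground-truth tibble, `mirror_pairs` count or NA, `oracle` function).
#' @export
make_benchmark <- function(preset_name, n_traj = NULL, n_frames = NULL,
                           seed = 1L) {
  presets <- c("two_state_easy", "twelve_state_mirror", "noisy_overlap")
  if (!preset_name %in% presets) {
    abort(paste0("unknown preset '", preset_name, "'; available: ",
                 paste(presets, collapse = ", ")))
  }
  spec <- switch(preset_name,
    two_state_easy = synthetic_spec(
      transition_matrix = matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
      state_centers = rbind(c(-60, 40, 150), c(70, -120, -30)),
      state_kappa = 50,
      property_coeffs = list(a0 = 2.3, b = c(0.4, 0.25, -0.3), c = c(-0.2, 0.35, 0.15)),
      noise_sigma = 0.05,
      charge_coeffs = toy_charge_coeffs(n_atoms = 6L, p = 3L),
      net_charge = 0
    ),
    twelve_state_mirror = {
      base <- rbind(
        c(25, 70, 115),
        c(80, 130, 40),
        c(140, 20, 95),
        c(55, 160, 145),
        c(110, 100, 20),
        c(165, 50, 70)
      )
      centers <- rbind(base, -base) # states 7..12 mirror states 1..6
      synthetic_spec(
        transition_matrix = mirror_chain_matrix(12L, stay = 0.9),
        state_centers = centers,
        state_kappa = 50,
        property_coeffs = list(a0 = 2.3, b = c(0.4, 0.25, -0.3), c = c(-0.2, 0.35, 0.15)),
        noise_sigma = 0.05,
        charge_coeffs = toy_charge_coeffs(n_atoms = 6L, p = 3L),
        net_charge = 0
      )
    },
    noisy_overlap = synthetic_spec(
      transition_matrix = matrix(c(
        0.90, 0.05, 0.05,
        0.05, 0.90, 0.05,
        0.05, 0.05, 0.90
      ), 3, byrow = TRUE),
      state_centers = rbind(c(-90, 60, 170), c(30, -60, -60), c(150, 170, 60)),
      state_kappa = 8,
      property_coeffs = list(a0 = 2.3, b = c(0.4, 0.25, -0.3), c = c(-0.2, 0.35, 0.15)),
      noise_sigma = 0.2,
      charge_coeffs = toy_charge_coeffs(n_atoms = 6L, p = 3L),
      net_charge = 0
    )
  )
  defaults <- switch(preset_name,
    two_state_easy = c(20L, 200L),
    twelve_state_mirror = c(60L, 300L),
    noisy_overlap = c(20L, 200L)
  )
  n_traj <- n_traj %||% defaults[1L]
  n_frames <- n_frames %||% defaults[2L]
  dataset <- simulate_trajectories(spec, n_traj, n_frames, seed = seed)
  expected <- list(
    k = spec$k,
    state_centers = spec$state_centers,
    transition_matrix = spec$transition_matrix,
    stationary = stationary_distribution(spec$transition_matrix),
    labels = dplyr::select(dataset$descriptors, "trajectory_id", "frame",
                           "time", "state"),
    mirror_pairs = if (preset_name == "twelve_state_mirror") 6L else NA_integer_,
    oracle = function(x) property_oracle(spec, x)
  )
  list(dataset = dataset, expected = expected)
}

# fixed small per-atom Fourier coefficient set for toy charges
toy_charge_coeffs <- function(n_atoms, p) {
  a0 <- seq(-0.3, 0.3, length.out = n_atoms)
  b <- outer(seq_len(n_atoms), seq_len(p), function(a, m) 0.1 * sin(a + m))
  c <- outer(seq_len(n_atoms), seq_len(p), function(a, m) 0.08 * cos(2 * a - m))
  list(a0 = a0, b = b, c = c)
}

# chain over 12 states: each mirror pair talks to itself, its neighbours on
# the base chain, and its mirror partner
mirror_chain_matrix <- function(k, stay = 0.9) {
  half <- k %/% 2L
  tm <- matrix(0, k, k)
  for (i in seq_len(k)) {
    base <- ((i - 1L) %% half) + 1L
    mirror <- if (i <= half) i + half else i - half
    nb <- c()
    if (base > 1L) nb <- c(nb, i - 1L)
    if (base < half) nb <- c(nb, i + 1L)
    targets <- c(nb, mirror)
    tm[i, i] <- stay
    tm[i, targets] <- (1 - stay) / length(targets)
  }
  tm
}
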