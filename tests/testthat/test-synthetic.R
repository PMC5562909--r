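two_state_spec <- function(kappa = 50, noise = 0.05) {
  synthetic_spec(
    transition_matrix = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
    state_centers = rbind(c(-60, 40), c(70, -120)),
    state_kappa = kappa,
    property_coeffs = list(a0 = 2.3, b = c(0.4, 0.25), c = c(-0.2, 0.35)),
    noise_sigma = noise
  )
}

test_that("simulation is reproducible and validates its inputs", {
  spec <- two_state_spec()
  d1 <- simulate_trajectories(spec, 3, 40, seed = 5)
  d2 <- simulate_trajectories(spec, 3, 40, seed = 5)
  expect_identical(d1$descriptors, d2$descriptors)
  expect_identical(d1$properties, d2$properties)
  d3 <- simulate_trajectories(spec, 3, 40, seed = 6)
  expect_false(identical(d1$descriptors, d3$descriptors))
  expect_error(
    synthetic_spec(matrix(c(0.9, 0.2, 0.2, 0.8), 2), rbind(c(0, 0), c(1, 1)),
                   property_coeffs = list(a0 = 0, b = c(0, 0), c = c(0, 0))),
    "summing to 1"
  )
})

test_that("an identity chain freezes each trajectory in its initial state", {
  spec <- synthetic_spec(
    transition_matrix = diag(2),
    state_centers = rbind(c(-60, 40), c(70, -120)),
    state_kappa = 50,
    property_coeffs = list(a0 = 2.3, b = c(0.4, 0.25), c = c(-0.2, 0.35))
  )
  ds <- simulate_trajectories(spec, 8, 30, seed = 2)
  per_traj <- tapply(ds$descriptors$state, ds$descriptors$trajectory_id,
                     function(s) length(unique(s)))
  expect_true(all(per_traj == 1))
})

test_that("empirical lag-1 transition probabilities match the planted matrix", {
  spec <- two_state_spec()
  ds <- simulate_trajectories(spec, 60, 400, seed = 11)
  labels <- dplyr::transmute(ds$descriptors, trajectory_id = .data$trajectory_id,
                             frame = .data$frame, pattern = .data$state)
  tm <- count_transitions(labels, k = 2)
  for (i in 1:2) {
    n_i <- sum(tm$counts[i, ])
    for (j in 1:2) {
      p <- spec$transition_matrix[i, j]
      se <- sqrt(p * (1 - p) / n_i)
      expect_lt(abs(tm$probabilities[i, j] - p), 3 * se + 1e-6)
    }
  }
})

test_that("long-run state frequencies match the stationary distribution", {
  spec <- two_state_spec()
  ds <- simulate_trajectories(spec, 30, 500, seed = 23)
  pi_star <- stationary_distribution(spec$transition_matrix)
  freq <- as.vector(table(ds$descriptors$state)) / nrow(ds$descriptors)
  expect_lt(max(abs(freq - pi_star)), 0.02)
})

test_that("higher kappa gives tighter circular emissions", {
  sd_at <- function(kappa) {
    withr::with_seed(9, x <- rvonmises_deg(4000, 100, kappa))
    rad <- x * pi / 180
    rbar <- sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
    sqrt(-2 * log(rbar)) * 180 / pi
  }
  s <- vapply(c(2, 8, 50, 200), sd_at, numeric(1))
  expect_true(all(diff(s) < 0))
  # kappa = 50: spread close to 1/sqrt(kappa) radians (~8.1 degrees)
  expect_equal(s[3], sqrt(1 / 50) * 180 / pi, tolerance = 0.05)
})

test_that("von Mises sampler matches circular-moment identities", {
  # E[cos(theta - mu)] = I1(kappa)/I0(kappa)
  kappa <- 5
  withr::with_seed(41, x <- rvonmises_deg(2e4, 30, kappa))
  rad <- (x - 30) * pi / 180
  expected_r <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_equal(mean(cos(rad)), expected_r, tolerance = 0.01)
  expect_equal(mean(sin(rad)), 0, tolerance = 0.01)
})

test_that("property residuals against the oracle have the configured sd", {
  spec <- two_state_spec(noise = 0.15)
  ds <- simulate_trajectories(spec, 60, 400, seed = 31) # 24k frames
  x <- as.matrix(ds$descriptors[spec$dihedral_names])
  resid <- ds$properties$excitation_energy - property_oracle(spec, x)
  expect_equal(sd(resid), 0.15, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 3 * 0.15 / sqrt(length(resid)))
})

test_that("the property oracle is periodic, constant-capable, and smooth", {
  spec <- two_state_spec()
  x <- c(37, -120)
  expect_equal(property_oracle(spec, x), property_oracle(spec, x + 360))
  expect_equal(property_oracle(spec, x), property_oracle(spec, x - 720))
  flat <- synthetic_spec(
    transition_matrix = diag(2),
    state_centers = rbind(c(0, 0), c(10, 10)), state_kappa = 10,
    property_coeffs = list(a0 = 1.7, b = c(0, 0), c = c(0, 0))
  )
  withr::with_seed(2, {
    for (i in 1:10) {
      expect_equal(property_oracle(flat, runif(2, -180, 180)), 1.7)
    }
  })
  # gradient matches central finite differences
  h <- 1e-4
  withr::with_seed(3, x0 <- runif(2, -180, 180))
  num_grad <- vapply(1:2, function(m) {
    e <- replace(numeric(2), m, h)
    (property_oracle(spec, x0 + e) - property_oracle(spec, x0 - e)) / (2 * h)
  }, numeric(1))
  rad <- x0 * pi / 180
  ana_grad <- (-spec$property_coeffs$b * sin(rad) +
                 spec$property_coeffs$c * cos(rad)) * pi / 180
  expect_equal(num_grad, ana_grad, tolerance = 1e-6)
})

test_that("per-frame synthetic charges sum exactly to the net charge", {
  bench <- make_benchmark("two_state_easy", n_traj = 3, n_frames = 30, seed = 7)
  q <- as.matrix(bench$dataset$properties[charge_columns(bench$dataset$properties)])
  expect_equal(max(abs(rowSums(q) - 0)), 0, tolerance = 1e-12)
})

test_that("benchmark presets expose machine-readable ground truth", {
  expect_error(make_benchmark("nope"), "two_state_easy")
  b2 <- make_benchmark("two_state_easy", n_traj = 2, n_frames = 20, seed = 1)
  expect_equal(b2$expected$k, 2L)
  expect_equal(dim(b2$expected$transition_matrix), c(2L, 2L))
  expect_equal(nrow(b2$expected$labels), 40L)
  bm <- make_benchmark("twelve_state_mirror", n_traj = 2, n_frames = 10, seed = 1)
  expect_equal(bm$expected$k, 12L)
  expect_equal(bm$expected$mirror_pairs, 6L)
  # the planted centers really are 6 mirror pairs
  cen <- bm$expected$state_centers
  expect_equal(wrap_angle(cen[7:12, ]), wrap_angle(-cen[1:6, ]))
  bn <- make_benchmark("noisy_overlap", n_traj = 2, n_frames = 10, seed = 1)
  expect_equal(bn$dataset$spec$state_kappa, rep(8, 3))
})

test_that("synthetic datasets round-trip through XYZ embedding and descriptors", {
  bench <- make_benchmark("two_state_easy", n_traj = 2, n_frames = 15, seed = 13)
  emb <- dataset_to_trajectories(bench$dataset)
  dir <- withr::local_tempdir()
  recovered <- purrr::map_dfr(emb$trajectories, function(tr) {
    f <- file.path(dir, paste0(tr$trajectory_id, ".xyz"))
    write_xyz_trajectory(tr, f, digits = 10)
    compute_descriptors(read_xyz_trajectory(f, tr$timestep, tr$trajectory_id),
                        emb$dihedrals)
  })
  orig <- bench$dataset$descriptors
  expect_equal(recovered$trajectory_id, orig$trajectory_id)
  expect_equal(
    as.matrix(recovered[bench$dataset$spec$dihedral_names]),
    as.matrix(orig[bench$dataset$spec$dihedral_names]),
    tolerance = 1e-6
  )
})
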