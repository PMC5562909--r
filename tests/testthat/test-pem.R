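test_that("general distance is Euclidean over wrapped differences", {
  expect_equal(general_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(general_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(general_distance(179, -179), 2)
  expect_equal(general_distance(179, -179, angular = FALSE), 358)
  expect_error(general_distance(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("shepard weights reproduce closed-form cases", {
  r1 <- small_refs(matrix(c(10, 20), 1), tvals = 5)
  expect_equal(pem_weights(c(0, 0), r1), 1)
  # two equidistant references: half weight each for any exponent
  r2 <- small_refs(rbind(c(10, 0), c(-10, 0)), tvals = c(1, 2))
  for (pw in c(1, 2, 4, 7)) {
    expect_equal(pem_weights(c(0, 0), r2, p_w = pw), c(0.5, 0.5))
  }
  # distances 1 and 2 with p_w = 4: weights 16/17 and 1/17
  r3 <- small_refs(rbind(c(1, 0), c(2, 0)), tvals = c(0, 0))
  expect_equal(pem_weights(c(0, 0), r3, p_w = 4), c(16 / 17, 1 / 17))
  # as-printed literal form
  w_ap <- pem_weights(c(0, 0), r3, mode = "as-printed")
  u <- c(1, 2)
  expect_equal(w_ap, (1 / u) / sum((1 / u)^4))
  expect_error(pem_weights(c(0, 0), small_refs(matrix(numeric(0), 0, 2), numeric(0))),
               "empty")
})

test_that("predictions match a naive direct-summation oracle on random sets", {
  withr::with_seed(202, {
    for (trial in 1:60) {
      p <- sample(2:6, 1)
      nref <- sample(2:40, 1)
      ref_mat <- matrix(runif(nref * p, -180, 180), nref, p)
      tvals <- rnorm(nref)
      x <- runif(p, -180, 180)
      refs <- small_refs(ref_mat, tvals)
      for (mode in c("shepard", "as-printed")) {
        expect_equal(pem_predict(x, refs, "energy", mode = mode),
                     oracle_pem(x, ref_mat, tvals, mode = mode),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("interpolation is exact at references, with equal-split ties", {
  withr::with_seed(33, {
    ref_mat <- matrix(runif(12, -170, 170), 4, 3)
    tvals <- rnorm(4)
  })
  refs <- small_refs(ref_mat, tvals)
  for (j in 1:4) {
    expect_equal(pem_predict(ref_mat[j, ], refs, "energy"), tvals[j])
  }
  # duplicated reference: equal split of the collapsed weight
  refs2 <- small_refs(ref_mat[c(1, 1, 2), ], tvals = c(1, 3, 100))
  expect_equal(pem_predict(ref_mat[1, ], refs2, "energy"), 2)
  # two equidistant references average their values
  r2 <- small_refs(rbind(c(10, 0), c(-10, 0)), tvals = c(1, 2))
  expect_equal(pem_predict(c(0, 0), r2, "energy"), 1.5)
  expect_error(pem_predict(c(0, 0), r2, "nope"), "unknown property")
})

test_that("shepard predictions are convex and continuous across a reference", {
  withr::with_seed(41, {
    ref_mat <- matrix(runif(30, -170, 170), 10, 3)
    tvals <- rnorm(10)
  })
  refs <- small_refs(ref_mat, tvals)
  withr::with_seed(42, {
    for (q in 1:200) {
      pred <- pem_predict(runif(3, -180, 180), refs, "energy")
      expect_gte(pred, min(tvals) - 1e-12)
      expect_lte(pred, max(tvals) + 1e-12)
    }
  })
  # scan one descriptor straight through reference 1: no jump at the match
  base <- ref_mat[1, ]
  eps <- c(-0.01, -1e-4, 0, 1e-4, 0.01)
  vals <- vapply(eps, function(e) {
    pem_predict(base + c(e, 0, 0), refs, "energy")
  }, numeric(1))
  expect_equal(vals[3], tvals[1])
  expect_lt(max(abs(vals - tvals[1])), 0.02 * diff(range(tvals)) + 1e-8)
})

test_that("growing the exponent concentrates weight on the nearest reference", {
  withr::with_seed(55, {
    ref_mat <- matrix(runif(16, -170, 170), 8, 2)
    tvals <- rnorm(8)
    x <- runif(2, -180, 180)
  })
  refs <- small_refs(ref_mat, tvals)
  u <- apply(ref_mat, 1, function(r) general_distance(x, r))
  nearest <- which.min(u)
  w4 <- pem_weights(x, refs, p_w = 4)
  w12 <- pem_weights(x, refs, p_w = 12)
  expect_gt(w12[nearest], w4[nearest])
  expect_equal(pem_predict(x, refs, "energy", p_w = 200), tvals[nearest],
               tolerance = 1e-6)
})

test_that("charge prediction is componentwise scalar PEM plus exact renormalization", {
  withr::with_seed(66, {
    ref_mat <- matrix(runif(20, -170, 170), 5, 4)
    charges <- matrix(rnorm(30, sd = 0.3), 5, 6)
    x <- runif(4, -180, 180)
  })
  refs <- small_refs(ref_mat, tvals = rnorm(5), charges = charges)
  got <- pem_predict_charges(x, refs)
  for (a in 1:6) {
    refs_a <- small_refs(ref_mat, tvals = charges[, a])
    expect_equal(unname(got[a]), pem_predict(x, refs_a, "energy"),
                 tolerance = 1e-12)
  }
  # identical charge vectors on all references come back unchanged
  same <- matrix(rep(charges[1, ], 5), 5, byrow = TRUE)
  refs_same <- small_refs(ref_mat, tvals = rnorm(5), charges = same)
  expect_equal(unname(pem_predict_charges(x, refs_same)), charges[1, ],
               tolerance = 1e-12)
  # renormalization pins the net charge exactly
  ren <- pem_predict_charges(x, refs, renormalize = TRUE, net_charge = 0)
  expect_equal(sum(ren), 0, tolerance = 1e-12)
  ren1 <- pem_predict_charges(x, refs, renormalize = TRUE, net_charge = -1)
  expect_equal(sum(ren1), -1, tolerance = 1e-12)
})

test_that("reference selection honours batch, stochastic, and mini-batch sizes", {
  withr::with_seed(10, {
    dataset <- tibble::tibble(
      trajectory_id = "t", frame = 0:36,
      pattern = rep(c(0L, 1L), c(12, 25)),
      dih_1 = runif(37, -180, 180), dih_2 = runif(37, -180, 180),
      energy = rnorm(37)
    )
  })
  dih <- c("dih_1", "dih_2")
  expect_equal(nrow(select_references(dataset, dih, mode = "batch")$refs), 37)
  st <- select_references(dataset, dih, mode = "stochastic", seed = 2)
  expect_equal(as.vector(table(st$refs$pattern)), c(1L, 1L))
  mb <- select_references(dataset, dih, mode = "mini-batch", n = 10, seed = 2)
  expect_equal(sum(mb$refs$pattern == 0), 10) # cluster of 12: sampled to 10
  expect_equal(sum(mb$refs$pattern == 1), 10) # cluster of 25: sampled to 10
  mb4 <- select_references(dataset[dataset$pattern == 1, ][1:4, ], dih,
                           mode = "mini-batch", n = 10)
  expect_equal(nrow(mb4$refs), 4) # cluster of 4: all used
  # determinism per seed
  mb2 <- select_references(dataset, dih, mode = "mini-batch", n = 10, seed = 2)
  expect_identical(mb$refs, mb2$refs)
  # patterns without property-bearing members are dropped with a warning
  dataset2 <- dataset
  dataset2$energy[dataset2$pattern == 0] <- NA
  expect_warning(r2 <- select_references(dataset2, dih), "dropped")
  expect_equal(r2$M, 1L)
  dataset2$energy <- NA_real_
  expect_error(suppressWarnings(select_references(dataset2, dih)), "every pattern")
})

test_that("validation reports ratio and deviation statistics", {
  pred <- c(1.0, 2.0, 3.0)
  rep_id <- validate_predictions(pred, pred, mode = "ratio")
  expect_equal(rep_id$fit$mu, 1)
  expect_equal(rep_id$fit$sigma, 0)
  dev <- validate_predictions(pred, pred, mode = "deviation")
  expect_equal(dev$data$value, c(0, 0, 0))
  expect_warning(
    r0 <- validate_predictions(c(1, 2), c(0, 2), mode = "ratio"),
    "zero reference"
  )
  expect_equal(nrow(r0$data), 1)
  g <- glance(r0)
  expect_equal(g$n_excluded, 1L)
})

test_that("framewise timeseries prediction equals per-frame pem_predict", {
  withr::with_seed(71, {
    ref_mat <- matrix(runif(24, -170, 170), 8, 3)
    tvals <- rnorm(8)
    queries <- matrix(runif(15, -180, 180), 5, 3)
  })
  refs <- small_refs(ref_mat, tvals)
  desc <- tibble::tibble(
    trajectory_id = "t", frame = 0:4, time = (0:4) * 0.5,
    dih_1 = queries[, 1], dih_2 = queries[, 2], dih_3 = queries[, 3]
  )
  out <- predict_timeseries(desc, refs, "energy")
  expect_equal(nrow(out), 5)
  expect_equal(out$time, desc$time)
  for (i in 1:5) {
    expect_equal(out$.pred[i], pem_predict(queries[i, ], refs, "energy"),
                 tolerance = 1e-12)
  }
  # a trajectory frozen at a reference geometry predicts that reference
  frozen <- desc[rep(1, 3), ]
  for (m in 1:3) frozen[[paste0("dih_", m)]] <- rep(ref_mat[2, m], 3)
  expect_equal(predict_timeseries(frozen, refs, "energy")$.pred,
               rep(tvals[2], 3))
})

test_that("reference sets survive a JSON round-trip", {
  withr::with_seed(5, {
    ref_mat <- matrix(runif(12, -170, 170), 4, 3)
    charges <- matrix(rnorm(8), 4, 2)
  })
  refs <- small_refs(ref_mat, tvals = rnorm(4), charges = charges)
  f <- withr::local_tempfile(fileext = ".json")
  write_reference_set(refs, f)
  back <- read_reference_set(f)
  expect_equal(back$dihedral_names, refs$dihedral_names)
  expect_equal(back$charge_cols, refs$charge_cols)
  expect_equal(as.data.frame(back$refs), as.data.frame(refs$refs),
               tolerance = 1e-12)
  x <- c(0, 10, -30)
  expect_equal(pem_predict(x, back, "energy"), pem_predict(x, refs, "energy"))
})

test_that("mini-batch PEM beats the global-mean baseline on a smooth surface", {
  bench <- make_benchmark("two_state_easy", n_traj = 12, n_frames = 150, seed = 90)
  ds <- bench$dataset
  dih <- ds$spec$dihedral_names
  dataset <- pem_dataset(
    dplyr::rename(bench$expected$labels, pattern = "state"),
    ds$descriptors[c("trajectory_id", "frame", "time", dih)],
    ds$properties[c("trajectory_id", "frame", "excitation_energy")]
  )
  n <- nrow(dataset)
  val_idx <- withr::with_seed(91, sample.int(n, 300))
  train <- dataset[-val_idx, ]
  val <- dataset[val_idx, ]
  refs <- select_references(train, dih, mode = "mini-batch", n = 10, seed = 92)
  pred <- predict_timeseries(val, refs, "excitation_energy")
  rmse <- sqrt(mean((pred$.pred - val$excitation_energy)^2))
  baseline <- sqrt(mean((mean(train$excitation_energy) - val$excitation_energy)^2))
  expect_lt(rmse, baseline)
  # error bounded by noise plus surface smoothness over the reference spacing
  sigma_n <- ds$spec$noise_sigma
  lipschitz <- sum(sqrt(ds$spec$property_coeffs$b^2 + ds$spec$property_coeffs$c^2)) * pi / 180
  qx <- as.matrix(val[dih])
  rx <- as.matrix(refs$refs[dih])
  nn <- apply(qx, 1, function(x) min(apply(rx, 1, function(r) general_distance(x, r))))
  expect_lt(rmse, 2 * sigma_n + lipschitz * mean(nn))
})
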