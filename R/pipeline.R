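#' Persist / restore a pattern model as JSON + TSV labels
#'
#' The model file holds embedding, k, seed, centroids (embedded and
#' back-mapped degrees) and descriptor names; labels are written beside it as
#' a delimited table keyed by `(trajectory_id, frame)`.
#'
#' @param model A `pattern_model`.
#' @param path JSON path; labels go to `<path without ext>_labels.tsv`.
#' @return `path` (write) or the restored `pattern_model` (read).
#' @export
write_pattern_model <- function(model, path) {
  stopifnot(inherits(model, "pattern_model"))
  labels_path <- paste0(sub("\\.[^.]*$", "", path), "_labels.tsv")
  payload <- list(
    k = model$k, embedding = model$embedding, seed = model$seed,
    dihedral_names = model$dihedral_names,
    centroids = unname(apply(model$centroids, 1, as.numeric, simplify = FALSE)),
    centroids_deg = unname(apply(model$centroids_deg, 1, as.numeric, simplify = FALSE)),
    inertia = model$inertia, sizes = model$sizes
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  readr::write_tsv(model$labels, labels_path)
  invisible(path)
}

#' @rdname write_pattern_model
#' @export
read_pattern_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels_path <- paste0(sub("\\.[^.]*$", "", path), "_labels.tsv")
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE)
  labels$trajectory_id <- as.character(labels$trajectory_id)
  as_mat <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else as.matrix(x)
  }
  centroids <- as_mat(payload$centroids)
  centroids_deg <- as_mat(payload$centroids_deg)
  structure(
    list(
      k = payload$k, embedding = payload$embedding, seed = payload$seed,
      centroids = centroids, centroids_deg = centroids_deg,
      dihedral_names = payload$dihedral_names,
      inertia = payload$inertia, sizes = payload$sizes,
      labels = tibble::as_tibble(labels)
    ),
    class = "pattern_model"
  )
}

#' Default pipeline configuration
#'
#' Protocol constants default to the values used throughout pemnet's
#' analyses: k = 12 patterns, lag 1 frame, mini-batch reference selection
#' with n = 10, Shepard kernel with exponent 4.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preset = "two_state_easy",   # synthetic input; or set xyz_paths etc.
    n_traj = NULL, n_frames = NULL,
    xyz_paths = NULL, timestep_fs = 0.5,
    dihedral_file = NULL, property_file = NULL,
    k = 12L, embedding = "circular", seed = 1L, n_init = 10L,
    lag = 1L, edge_threshold = 0,
    merge_mirrors = FALSE, merge_tolerance_deg = 10,
    selection_mode = "mini-batch", n_refs = 10L,
    kernel_mode = "shepard", p_w = 4,
    property = "excitation_energy",
    validation_fraction = 0.1,
    out_dir = "pemnet_run"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) && is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full pattern-mining and prediction pipeline
#'
#' Stages, in order: descriptors (simulate the configured preset, or read
#' XYZ + dihedral definitions + property tables), cluster, network, stats,
#' references, predict, validate. Every stage persists its artifact under
#' `config$out_dir` and is recorded in a manifest with the seed, a config
#' hash, and per-file MD5 hashes, so identical configs give identical
#' artifacts. With `resume = TRUE`, stages whose artifacts already exist are
#' loaded instead of recomputed.
#'
#' @param config A list from [pipeline_config()] (or a YAML/JSON file path).
#' @param resume Reuse existing artifacts (default FALSE).
#' @param quiet Suppress per-stage messages (default FALSE).
#' @return The manifest, invisibly: list with `config`, `config_hash`,
#'   `seed`, `stages` (7 entries, each with `files` and `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(), resume = FALSE,
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- pipeline_config(read_config_file(config))
  }
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- function(...) file.path(cfg$out_dir, ...)
  stages <- list()
  t_all <- Sys.time()

  run_stage <- function(name, files, compute, load) {
    paths <- art(files)
    t0 <- Sys.time()
    if (resume && all(file.exists(paths))) {
      say("[%s] reusing existing artifact(s)", name)
    } else {
      tryCatch(compute(paths), error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
      })
    }
    # downstream stages always consume the persisted representation, so a
    # fresh run and a resumed run are bit-identical
    value <- load(paths)
    stages[[name]] <<- list(
      files = files,
      md5 = unname(tools::md5sum(paths)),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    say("[%s] done (%.2fs)", name, stages[[name]]$seconds)
    value
  }

  # -- descriptors -----------------------------------------------------------
  desc_data <- run_stage(
    "descriptors", c("descriptors.tsv", "properties.tsv"),
    compute = function(paths) {
      if (!is.null(cfg$xyz_paths)) {
        dihedrals <- read_dihedral_spec(cfg$dihedral_file)
        descriptors <- purrr::map_dfr(cfg$xyz_paths, function(p) {
          compute_descriptors(read_xyz_trajectory(p, cfg$timestep_fs), dihedrals)
        })
        properties <- if (!is.null(cfg$property_file)) {
          read_property_table(cfg$property_file)
        } else {
          tibble::tibble(trajectory_id = character(), frame = integer())
        }
      } else {
        bench <- make_benchmark(cfg$preset, cfg$n_traj, cfg$n_frames,
                                seed = cfg$seed)
        descriptors <- dplyr::select(bench$dataset$descriptors, -"state")
        properties <- bench$dataset$properties
      }
      readr::write_tsv(descriptors, paths[1L])
      readr::write_tsv(properties, paths[2L])
      list(descriptors = descriptors, properties = properties)
    },
    load = function(paths) {
      d <- readr::read_tsv(paths[1L], show_col_types = FALSE)
      p <- readr::read_tsv(paths[2L], show_col_types = FALSE)
      d$trajectory_id <- as.character(d$trajectory_id)
      p$trajectory_id <- as.character(p$trajectory_id)
      list(descriptors = tibble::as_tibble(d), properties = tibble::as_tibble(p))
    }
  )
  descriptors <- desc_data$descriptors
  properties <- desc_data$properties
  dihedral_names <- setdiff(names(descriptors), c("trajectory_id", "frame", "time"))

  # -- cluster ---------------------------------------------------------------
  model <- run_stage(
    "cluster", c("model.json", "model_labels.tsv"),
    compute = function(paths) {
      m <- fit_patterns(descriptors, k = cfg$k, embedding = cfg$embedding,
                        seed = cfg$seed, n_init = cfg$n_init)
      write_pattern_model(m, paths[1L])
      m
    },
    load = function(paths) read_pattern_model(paths[1L])
  )
  labels <- model$labels
  pattern_col <- "pattern"
  if (isTRUE(cfg$merge_mirrors)) {
    merged <- merge_symmetric_pairs(model, cfg$merge_tolerance_deg)
    labels <- merged$labels
    pattern_col <- "merged"
  }

  # -- network ---------------------------------------------------------------
  network <- run_stage(
    "network", c("transitions.tsv", "populations.tsv"),
    compute = function(paths) {
      tm <- count_transitions(
        dplyr::select(labels, "trajectory_id", "frame",
                      pattern = dplyr::all_of(pattern_col)),
        k = cfg$k, lag = cfg$lag
      )
      readr::write_tsv(tidy(tm), paths[1L])
      pop <- population_timeseries(labels, k = cfg$k, pattern_col = pattern_col)
      readr::write_tsv(tibble::as_tibble(pop), paths[2L])
      graph <- build_graph(tm, cfg$edge_threshold)
      list(transitions = tm, populations = pop, graph = graph)
    },
    load = function(paths) {
      tt <- readr::read_tsv(paths[1L], show_col_types = FALSE)
      k <- max(tt$from, tt$to) + 1L
      counts <- matrix(0L, k, k)
      counts[cbind(tt$from + 1L, tt$to + 1L)] <- tt$count
      tm <- new_transition_model(counts, lag = cfg$lag)
      pop <- readr::read_tsv(paths[2L], show_col_types = FALSE)
      list(transitions = tm, populations = pop,
           graph = build_graph(tm, cfg$edge_threshold))
    }
  )

  # -- stats -----------------------------------------------------------------
  stats_tbl <- run_stage(
    "stats", "pattern_stats.tsv",
    compute = function(paths) {
      st <- per_pattern_stats(labels, properties, pattern_col = pattern_col)
      readr::write_tsv(st, paths)
      st
    },
    load = function(paths) readr::read_tsv(paths, show_col_types = FALSE)
  )

  # held-out validation frames, excluded from the reference pool
  dataset <- pem_dataset(labels, descriptors, properties)
  n_val <- max(1L, floor(cfg$validation_fraction * nrow(dataset)))
  val_idx <- with_local_seed(cfg$seed + 1L, sample.int(nrow(dataset), n_val))
  val <- dataset[val_idx, , drop = FALSE]
  train <- dataset[-val_idx, , drop = FALSE]

  # -- references ------------------------------------------------------------
  refs <- run_stage(
    "references", "references.json",
    compute = function(paths) {
      r <- select_references(train, dihedrals = dihedral_names,
                             mode = cfg$selection_mode, n = cfg$n_refs,
                             seed = cfg$seed, pattern_col = pattern_col)
      write_reference_set(r, paths)
      r
    },
    load = function(paths) read_reference_set(paths)
  )

  # -- predict ---------------------------------------------------------------
  predictions <- run_stage(
    "predict", "predictions.tsv",
    compute = function(paths) {
      pred <- predict_timeseries(val, refs, property = cfg$property,
                                 mode = cfg$kernel_mode, p_w = cfg$p_w)
      pred$reference <- val[[cfg$property]]
      readr::write_tsv(pred, paths)
      pred
    },
    load = function(paths) {
      p <- readr::read_tsv(paths, show_col_types = FALSE)
      p$trajectory_id <- as.character(p$trajectory_id)
      tibble::as_tibble(p)
    }
  )

  # -- validate --------------------------------------------------------------
  report <- run_stage(
    "validate", "report.json",
    compute = function(paths) {
      keep <- is.finite(predictions$reference)
      rep <- validate_predictions(predictions$.pred[keep],
                                  predictions$reference[keep], mode = "ratio")
      jsonlite::write_json(
        list(mode = rep$mode, n = nrow(rep$data),
             ratio_mu = rep$fit$mu, ratio_sigma = rep$fit$sigma,
             rmse = sqrt(mean((rep$data$predicted - rep$data$reference)^2))),
        paths, auto_unbox = TRUE, digits = NA
      )
      rep
    },
    load = function(paths) jsonlite::read_json(paths, simplifyVector = TRUE)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("pemnet")),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    config_hash = config_hash(cfg),
    stages = stages,
    total_seconds = as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  say("pipeline complete: %d stages, %.2fs", length(stages),
      manifest$total_seconds)
  invisible(manifest)
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# stable hash of the analytic configuration (output location excluded):
# serialize deterministically, md5 the text
config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  cfg <- cfg[order(names(cfg))]
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}
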