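#' Count lag transitions among meta-stable patterns
#'
#' Builds the transition count matrix of the kinetic network by counting
#' ordered label pairs `(t, t + lag)` along each trajectory's time series.
#' Pairs never straddle a trajectory boundary: an ensemble of uncoupled short
#' trajectories contributes only its own internal transitions.
#'
#' @param labels A label tibble with columns `trajectory_id`, `frame`, and
#'   `pattern` (integers in `0:(k-1)`), e.g. `fit_patterns(...)$labels`; or a
#'   plain integer vector (treated as one trajectory); or a list of such
#'   vectors.
#' @param k Number of patterns.
#' @param lag Lag in frames (default 1, counting along the raw series).
#' @return A `transition_model`: list with `counts` (k x k integer),
#'   `probabilities` (row-stochastic, zero rows left at zero), `zero_rows`
#'   (logical flags), `k`, `lag`, `n_pairs`.
#' @export
count_transitions <- function(labels, k, lag = 1L) {
  if (lag < 1L) abort("`lag` must be >= 1")
  series <- label_series_list(labels)
  counts <- matrix(0L, k, k)
  for (nm in names(series)) {
    s <- series[[nm]]
    if (any(s < 0L | s >= k)) {
      bad <- which(s < 0L | s >= k)[1L]
      abort(sprintf("trajectory '%s', position %d: label %d outside 0..%d",
                    nm, bad, s[bad], k - 1L))
    }
    n <- length(s)
    if (n <= lag) next
    from <- s[seq_len(n - lag)] + 1L
    to <- s[seq_len(n - lag) + lag] + 1L
    counts <- counts + matrix(tabulate(from + (to - 1L) * k, nbins = k * k), k, k)
  }
  new_transition_model(counts, lag)
}

label_series_list <- function(labels) {
  if (is.numeric(labels) && is.null(dim(labels))) {
    return(list(traj = as.integer(labels)))
  }
  if (is.list(labels) && !is.data.frame(labels)) {
    out <- purrr::map(labels, as.integer)
    if (is.null(names(out))) names(out) <- paste0("traj_", seq_along(out))
    return(out)
  }
  labels <- tibble::as_tibble(labels)
  if (!all(c("trajectory_id", "pattern") %in% names(labels))) {
    abort("label table needs `trajectory_id` and `pattern` columns")
  }
  if ("frame" %in% names(labels)) {
    labels <- dplyr::arrange(labels, .data$trajectory_id, .data$frame)
  }
  split(as.integer(labels$pattern), labels$trajectory_id)
}

new_transition_model <- function(counts, lag) {
  rs <- rowSums(counts)
  zero <- rs == 0
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(
    list(counts = counts, probabilities = probs, zero_rows = zero,
         k = nrow(counts), lag = as.integer(lag), n_pairs = sum(counts)),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model: k = %d, lag = %d, %d transition pairs>\n",
              x$k, x$lag, x$n_pairs))
  invisible(x)
}

#' Row-normalize a transition count matrix
#'
#' @param counts Non-negative k x k count matrix.
#' @return List with `probabilities` (rows summing to 1; all-zero rows are
#'   returned as zeros, never imputed) and `zero_rows` flags.
#' @export
transition_probabilities <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    abort("`counts` must be a square matrix")
  }
  if (any(counts < 0)) abort("negative transition count")
  m <- new_transition_model(counts, lag = 1L)
  list(probabilities = m$probabilities, zero_rows = m$zero_rows)
}

#' Time-dependent pattern populations across an ensemble
#'
#' At each time point, the population of pattern i is the fraction of
#' trajectories (among those defined at that time) currently in pattern i —
#' the ensemble-of-uncoupled-trajectories picture of kinetics. Populations at
#' every reported time are a probability simplex.
#'
#' @param labels Label tibble with `trajectory_id`, `time` (or `frame`), and
#'   a pattern column.
#' @param k Number of patterns.
#' @param pattern_col Which column holds the pattern ids (default
#'   `"pattern"`; use `"merged"` after [merge_symmetric_pairs()]).
#' @return A tibble of class `population_series`: `time`, `pattern`,
#'   `population`, `n_defined`.
#' @export
population_timeseries <- function(labels, k, pattern_col = "pattern") {
  labels <- tibble::as_tibble(labels)
  if (!"time" %in% names(labels)) {
    if (!"frame" %in% names(labels)) abort("labels need a `time` or `frame` column")
    labels$time <- as.numeric(labels$frame)
  }
  if (!pattern_col %in% names(labels)) {
    abort(sprintf("no `%s` column in labels", pattern_col))
  }
  pat <- as.integer(labels[[pattern_col]])
  if (any(pat < 0L | pat >= k)) abort("pattern id outside 0..k-1")
  ids <- sort(unique(pat))
  out <- labels |>
    dplyr::mutate(.pattern = pat) |>
    dplyr::count(.data$time, .data$.pattern, name = "n_in") |>
    tidyr::complete(time = unique(labels$time),
                    .pattern = 0:(k - 1L), fill = list(n_in = 0L)) |>
    dplyr::group_by(.data$time) |>
    dplyr::mutate(n_defined = sum(.data$n_in),
                  population = .data$n_in / .data$n_defined) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_defined > 0L) |>
    dplyr::transmute(time = .data$time, pattern = .data$.pattern,
                     population = .data$population,
                     n_defined = .data$n_defined) |>
    dplyr::arrange(.data$time, .data$pattern)
  class(out) <- c("population_series", class(out))
  out
}

#' Build the thresholded kinetic network graph
#'
#' Vertices are patterns; an undirected edge joins i and j (i != j) when the
#' larger of the two directed transition probabilities reaches
#' `edge_threshold`. Self-transitions never create edges. Returns the graph
#' together with its connected components and articulation (cut) vertices —
#' the obligatory intermediates whose removal disconnects the network.
#'
#' @param probabilities Square matrix of transition probabilities (or a
#'   `transition_model`).
#' @param edge_threshold Minimum probability for an edge, in `[0, 1]`.
#'   Default 0: any observed transition connects the patterns.
#' @return List: `graph` (igraph, weighted by the symmetrized probability),
#'   `components` (list of 0-based vertex-id vectors), `articulation`
#'   (0-based vertex ids), `edges` (tibble `from`, `to`, `weight`).
#' @export
build_graph <- function(probabilities, edge_threshold = 0) {
  if (inherits(probabilities, "transition_model")) {
    probabilities <- probabilities$probabilities
  }
  if (!is.matrix(probabilities) || nrow(probabilities) != ncol(probabilities)) {
    abort("`probabilities` must be a square matrix")
  }
  if (edge_threshold < 0 || edge_threshold > 1) {
    abort("`edge_threshold` must be in [0, 1]")
  }
  k <- nrow(probabilities)
  w <- pmax(probabilities, t(probabilities))
  diag(w) <- 0
  adj <- w
  if (edge_threshold > 0) {
    adj[adj < edge_threshold] <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- as.character(0:(k - 1L))
  comp <- igraph::components(g)
  components <- unname(split(0:(k - 1L), comp$membership))
  art <- sort(as.integer(names(igraph::articulation_points(g))))
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    from = as.integer(ed$from), to = as.integer(ed$to),
    weight = if (nrow(ed)) ed$weight else numeric(0)
  )
  list(graph = g, components = components, articulation = art, edges = edges)
}

#' Stationary distribution of a transition matrix
#'
#' Leading left eigenvector of a row-stochastic matrix, normalized to sum to
#' one. Used as the long-time reference for population time series.
#'
#' @param probabilities Row-stochastic k x k matrix.
#' @return Numeric length-k probability vector.
#' @export
stationary_distribution <- function(probabilities) {
  if (inherits(probabilities, "transition_model")) {
    probabilities <- probabilities$probabilities
  }
  e <- eigen(t(probabilities))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) abort("no non-negative stationary vector found")
  pmax(v, 0) / sum(pmax(v, 0))
}
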