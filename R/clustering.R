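# Percentile scaling, maximum-dissimilarity selection, and the
# self-organizing map
#
# Indicators are scaled so 0 is the minimum and 1 the 99.9th percentile
# (robust to outliers; values above the 99.9th percentile exceed 1). The SOM
# places k prototype vectors (neurons) on a 2-D lattice, initialized with a
# maximally dissimilar subset of rows, and trains them online with a
# Gaussian neighborhood kernel and linearly decaying radius and learning
# rate.

#' Fit the percentile scaler
#'
#' Per indicator, records the minimum and the 99.9th percentile of the
#' finite values. The transform maps `x` to `(x - min) / (p999 - min)`:
#' the minimum to 0, the 99.9th percentile to 1, and larger values above 1
#' (not clipped).
#'
#' @param table Data frame holding the indicators.
#' @param indicators Indicator column names to fit.
#' @return A `percentile_scaler` with a `params` data frame
#'   (`indicator`, `min`, `p999`).
#' @export
fit_scaler <- function(table, indicators) {
  params <- lapply(indicators, function(ind) {
    v <- table[[ind]]
    if (is.null(v)) stop(sprintf("indicator '%s' not in the table", ind))
    v <- v[is.finite(v)]
    if (length(v) == 0) stop(sprintf("indicator '%s' has no finite values", ind))
    if (length(v) < 2) stop(sprintf("indicator '%s' has fewer than 2 finite values", ind))
    data.frame(indicator = ind, min = min(v),
               p999 = unname(stats::quantile(v, 0.999, type = 7)))
  })
  params <- do.call(rbind, params)
  degenerate <- params$p999 == params$min
  if (any(degenerate)) {
    warning(sprintf("degenerate scale (p999 == min) for: %s; scaled values set to 0",
                    paste(params$indicator[degenerate], collapse = ", ")))
  }
  structure(list(params = params), class = "percentile_scaler")
}

#' Apply the percentile scaler
#'
#' @param scaler A [fit_scaler()] result.
#' @param data Data frame (or matrix with named columns) holding the fitted
#'   indicators.
#' @return Numeric matrix of scaled values, one column per fitted indicator.
#' @export
scale_indicators <- function(scaler, data) {
  stopifnot(inherits(scaler, "percentile_scaler"))
  p <- scaler$params
  out <- matrix(NA_real_, NROW(data), nrow(p),
                dimnames = list(NULL, p$indicator))
  for (i in seq_len(nrow(p))) {
    x <- if (is.data.frame(data)) data[[p$indicator[i]]] else data[, p$indicator[i]]
    rng <- p$p999[i] - p$min[i]
    out[, i] <- if (rng == 0) 0 else (x - p$min[i]) / rng
  }
  out
}

#' Greedy maximum-dissimilarity subset selection (MaxMin)
#'
#' The first selected row maximizes the total Euclidean distance to all
#' rows; each subsequent row maximizes the minimum distance to the
#' already-selected set. Deterministic; ties broken by ascending row index.
#' Used to initialize the SOM neurons so they span the parameter space.
#'
#' @param data Numeric matrix (rows = observations).
#' @param k Number of rows to select (`<= nrow(data)`).
#' @return Integer vector of `k` row indices, in selection order.
#' @export
maxdiss_select <- function(data, k) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (k > n) stop(sprintf("k = %d exceeds the number of rows (%d)", k, n))
  if (k < 1) stop("k must be >= 1")
  d <- as.matrix(stats::dist(data))
  sel <- which.max(rowSums(d))  # ties: which.max takes the lowest index
  mind <- d[, sel]
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  unname(sel)
}

#' Self-organizing map configuration
#'
#' @param rows,cols Lattice dimensions (k = rows x cols neurons).
#' @param n_epochs Training epochs (each epoch presents every row once, in
#'   seeded shuffled order).
#' @param sigma0,sigma1 Initial and final neighborhood radius (lattice
#'   units); default from `max(rows, cols)/2` down to 1, linear decay.
#' @param eta0,eta1 Initial and final learning rate, linear decay.
#' @param seed Integer seed for the per-epoch shuffles.
#' @return A `som_config` list.
#' @export
som_config <- function(rows = 13, cols = 13, n_epochs = 50,
                       sigma0 = max(rows, cols) / 2, sigma1 = 1,
                       eta0 = 0.5, eta1 = 0.01, seed = 1) {
  stopifnot(rows >= 1, cols >= 1, n_epochs >= 1,
            sigma0 >= sigma1, sigma1 > 0, eta0 >= eta1, eta1 > 0)
  structure(list(rows = rows, cols = cols, k = rows * cols,
                 n_epochs = n_epochs, sigma0 = sigma0, sigma1 = sigma1,
                 eta0 = eta0, eta1 = eta1, seed = as.integer(seed)),
            class = "som_config")
}

som_lattice <- function(config) {
  idx <- seq_len(config$k)
  cbind(row = (idx - 1) %/% config$cols + 1,
        col = (idx - 1) %% config$cols + 1)
}

#' Train a self-organizing map online
#'
#' Per sample, the best matching unit (BMU) `b` is the nearest neuron in
#' input space; every neuron `j` moves toward the sample by
#' `eta(t) exp(-d_lat(j, b)^2 / (2 sigma(t)^2)) (x - w_j)`, with `d_lat`
#' the Euclidean distance on integer lattice coordinates. Radius and
#' learning rate decay linearly per epoch; sample order is reshuffled each
#' epoch under the seed; quantization error is recorded per epoch.
#'
#' @param data Numeric matrix of scaled rows (finite).
#' @param init k x d matrix of initial neurons (e.g. the [maxdiss_select()]
#'   rows).
#' @param config A [som_config()].
#' @return A `som_model`: list with `neurons` (k x d), `lattice` (k x 2),
#'   `qe_history` (per epoch), `config`.
#' @export
train_som <- function(data, init, config = som_config()) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) {
    stop(sprintf("non-finite input row(s): %s",
                 paste(utils::head(which(!apply(is.finite(data), 1, all)), 5),
                       collapse = ", ")))
  }
  init <- as.matrix(init)
  if (nrow(init) != config$k || ncol(init) != ncol(data)) {
    stop(sprintf("init must be %d x %d (got %d x %d)",
                 config$k, ncol(data), nrow(init), ncol(init)))
  }
  lat <- som_lattice(config)
  lat_d2 <- as.matrix(stats::dist(lat))^2
  w <- unname(init)
  n <- nrow(data); d <- ncol(data); k <- config$k
  qe_history <- numeric(config$n_epochs)
  set.seed(config$seed)
  for (e in seq_len(config$n_epochs)) {
    frac <- if (config$n_epochs == 1) 0 else (e - 1) / (config$n_epochs - 1)
    sigma <- config$sigma0 + frac * (config$sigma1 - config$sigma0)
    eta <- config$eta0 + frac * (config$eta1 - config$eta0)
    for (i in sample.int(n)) {
      x <- data[i, ]
      d2 <- colSums((t(w) - x)^2)
      b <- which.min(d2)
      h <- eta * exp(-lat_d2[, b] / (2 * sigma^2))
      w <- w + h * (matrix(x, k, d, byrow = TRUE) - w)
    }
    qe_history[e] <- qe_of(w, data)
  }
  colnames(w) <- colnames(data)
  structure(list(neurons = w, lattice = lat, qe_history = qe_history,
                 config = config),
            class = "som_model")
}

# squared distances rows x neurons
cross_dist2 <- function(data, neurons) {
  dn <- rowSums(data^2)
  nn <- rowSums(neurons^2)
  d2 <- outer(dn, nn, "+") - 2 * data %*% t(neurons)
  pmax(d2, 0)
}

qe_of <- function(neurons, data) {
  mean(sqrt(apply(cross_dist2(data, neurons), 1, min)))
}

#' Assign rows to their best matching units
#'
#' @param model A [train_som()] result.
#' @param data Numeric matrix of scaled rows (same dimension as the
#'   neurons).
#' @return A `cluster_assignment`: list with `cluster` (neuron index per
#'   row; ties to the lowest index), `lattice` (row/col per neuron), and
#'   `members` (list of row indices per neuron, possibly empty).
#' @export
assign_clusters <- function(model, data) {
  stopifnot(inherits(model, "som_model"))
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$neurons)) {
    stop(sprintf("dimension mismatch: data has %d columns, neurons %d",
                 ncol(data), ncol(model$neurons)))
  }
  d2 <- cross_dist2(data, model$neurons)
  cl <- apply(d2, 1, which.min)
  members <- lapply(seq_len(nrow(model$neurons)),
                    function(j) which(cl == j))
  structure(list(cluster = cl, lattice = model$lattice, members = members),
            class = "cluster_assignment")
}

#' Quantization error of a SOM on a dataset
#'
#' Mean Euclidean distance of rows to their best matching units.
#'
#' @param model A [train_som()] result.
#' @param data Numeric matrix of scaled rows.
#' @return Mean distance (scaled units).
#' @export
quantization_error <- function(model, data) {
  stopifnot(inherits(model, "som_model"))
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$neurons)) {
    stop("dimension mismatch between data and neurons")
  }
  qe_of(model$neurons, data)
}
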