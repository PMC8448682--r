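#' Stratified train/validation splits
#'
#' Splits trials 70/30 within each anchor position (stratum), repeated
#' `n_repeats` times with disjoint train/validation sets per repeat.
#'
#' @param trial_ids Vector of trial ids.
#' @param strata Stratum label per trial (e.g. target position id).
#' @param train_frac Fraction of trials per stratum used for training.
#' @param n_repeats Number of independent splits (study condition: 50).
#' @param seed Seed; splits are reproducible.
#' @return List of length `n_repeats`; each element a list `train`,
#'   `validate` of trial ids.
#' @export
split_trials <- function(trial_ids, strata, train_frac = 0.7,
                         n_repeats = 50, seed = 1) {
  stopifnot(length(trial_ids) == length(strata),
            train_frac > 0, train_frac < 1)
  groups <- split(trial_ids, strata)
  if (any(vapply(groups, length, 1L) < 2))
    stop("need at least 2 trials per stratum")
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      tr <- unlist(lapply(groups, function(g) {
        k <- round(train_frac * length(g))
        k <- min(max(k, 1), length(g) - 1)
        sample(g, k)
      }), use.names = FALSE)
      list(train = sort(tr),
           validate = sort(setdiff(trial_ids, tr)))
    })
  })
}

#' Expected spike count of a neuron at a position and window
#'
#' Mean rate of the tuning field over the time window at the given
#' position (bilinear interpolation on the field grid) times the window
#' duration in seconds.
#'
#' @param field A `tuning_field` with a time axis.
#' @param position Length-2 numeric (x, y), deg; must lie within the grid.
#' @param window Length-2 numeric (t_lo, t_hi), ms.
#' @return Expected count (numeric scalar).
#' @export
expected_count <- function(field, position, window = c(-100, 100)) {
  gx <- field$grid_x; gy <- field$grid_y
  if (position[1] < min(gx) || position[1] > max(gx) ||
      position[2] < min(gy) || position[2] > max(gy))
    stop("position outside the field grid")
  m <- window_average(field, window[1], window[2])
  rate <- bilinear_interp(m, gx, gy, position[1], position[2])
  rate * (window[2] - window[1]) / 1000
}

# Poisson pseudo-trials from a stack of window-averaged spatial maps.
# maps_mat: (nx*ny) x n_neurons matrix of rates on the grid.
pseudo_trials_from_maps <- function(maps_mat, grid, duration_s, n,
                                    positions = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(positions)) {
      positions <- cbind(stats::runif(n, -4, 4), stats::runif(n, -4, 4))
    } else {
      positions <- as.matrix(positions)
      n <- nrow(positions)
    }
    if (n == 0) {
      return(list(counts = matrix(0L, 0, ncol(maps_mat)),
                  positions = positions))
    }
    nx <- length(grid$x)
    counts <- matrix(0L, n, ncol(maps_mat))
    for (j in seq_len(ncol(maps_mat))) {
      m <- matrix(maps_mat[, j], nx)
      lam <- pmax(bilinear_interp(m, grid$x, grid$y,
                                  positions[, 1], positions[, 2]), 0)
      counts[, j] <- stats::rpois(n, lam * duration_s)
    }
    list(counts = counts, positions = positions)
  })
}

#' Generate a Poisson pseudo-trial set
#'
#' Draws `n` pseudo-trials: a random saccade end-position uniform over the
#' +/-4 deg square (or the supplied `positions`), and for each neuron an
#' independent Poisson spike count with mean equal to the neuron's expected
#' count at that position in the window.
#'
#' @param fields List of `tuning_field` objects, one per neuron.
#' @param n Number of pseudo-trials (study condition: 100000).
#' @param window Length-2 time window, ms.
#' @param seed Seed.
#' @param positions Optional n x 2 matrix of fixed end-positions.
#' @return List of class `pseudo_trial_set`: `counts` (n x n_neurons
#'   integer matrix), `positions`, `window`, `seed`.
#' @export
generate_pseudo_trials <- function(fields, n = 100000,
                                   window = c(-100, 100), seed = 1,
                                   positions = NULL) {
  grid <- list(x = fields[[1]]$grid_x, y = fields[[1]]$grid_y)
  maps_mat <- vapply(fields, function(f)
    as.numeric(window_average(f, window[1], window[2])),
    numeric(length(grid$x) * length(grid$y)))
  ps <- pseudo_trials_from_maps(maps_mat, grid,
                                (window[2] - window[1]) / 1000,
                                n, positions, seed)
  structure(c(ps, list(window = window, seed = seed)),
            class = "pseudo_trial_set")
}

# ---- shallow feed-forward decoder -----------------------------------------

mlp_unpack <- function(par, sizes) {
  res <- list(); off <- 0
  for (l in seq_len(length(sizes) - 1)) {
    nin <- sizes[l]; nout <- sizes[l + 1]
    res[[paste0("W", l)]] <- matrix(par[off + seq_len(nin * nout)], nin, nout)
    off <- off + nin * nout
    res[[paste0("b", l)]] <- par[off + seq_len(nout)]
    off <- off + nout
  }
  res
}

mlp_forward <- function(wb, X) {
  A1 <- tanh(sweep(X %*% wb$W1, 2, wb$b1, "+"))
  A2 <- tanh(sweep(A1 %*% wb$W2, 2, wb$b2, "+"))
  Y <- sweep(A2 %*% wb$W3, 2, wb$b3, "+")
  list(A1 = A1, A2 = A2, Y = Y)
}

# MSE objective with analytic backprop gradient, shared between fn and gr
# via a one-slot cache (optim calls fn and gr with the same parameters).
mlp_objective <- function(X, T_, sizes) {
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  compute <- function(par) {
    wb <- mlp_unpack(par, sizes)
    fw <- mlp_forward(wb, X)
    R <- fw$Y - T_
    n <- nrow(X)
    loss <- sum(R^2) / (n * ncol(T_))
    dY <- 2 * R / (n * ncol(T_))
    dW3 <- crossprod(fw$A2, dY); db3 <- colSums(dY)
    dA2 <- tcrossprod(dY, wb$W3) * (1 - fw$A2^2)
    dW2 <- crossprod(fw$A1, dA2); db2 <- colSums(dA2)
    dA1 <- tcrossprod(dA2, wb$W2) * (1 - fw$A1^2)
    dW1 <- crossprod(X, dA1); db1 <- colSums(dA1)
    cache$par <- par
    cache$loss <- loss
    cache$grad <- c(dW1, db1, dW2, db2, dW3, db3)
    invisible(NULL)
  }
  list(
    fn = function(par) {
      if (is.null(cache$par) || !identical(par, cache$par)) compute(par)
      cache$loss
    },
    gr = function(par) {
      if (is.null(cache$par) || !identical(par, cache$par)) compute(par)
      cache$grad
    }
  )
}

#' Train the shallow network end-position decoder
#'
#' Feed-forward regressor with the fixed architecture
#' n_neurons -> 20 -> 20 -> 2 (tanh hidden units, linear output), trained
#' on mean squared error by full-batch quasi-Newton optimization (L-BFGS-B)
#' with analytic gradients. Inputs are standardized by training-set
#' mean/SD per neuron.
#'
#' @param counts n x n_neurons matrix of spike counts.
#' @param positions n x 2 matrix of generating end-positions, deg.
#' @param hidden Hidden layer sizes (default `c(20, 20)`).
#' @param maxit Maximum optimizer iterations.
#' @param seed Seed for weight initialization.
#' @return List of class `decoder_model`: weights, standardization
#'   parameters, architecture, final training MSE, convergence flag.
#' @export
train_decoder <- function(counts, positions, hidden = c(20, 20),
                          maxit = 200, seed = 1) {
  counts <- as.matrix(counts); positions <- as.matrix(positions)
  if (!all(is.finite(counts)) || !all(is.finite(positions)))
    stop("non-finite training inputs")
  mu <- colMeans(counts)
  sdv <- pmax(apply(counts, 2, stats::sd), 1e-8)
  X <- sweep(sweep(counts, 2, mu), 2, sdv, "/")
  sizes <- c(ncol(X), hidden, 2L)
  n_par <- sum((sizes[-length(sizes)] + 1) * sizes[-1])
  par0 <- with_seed(seed, {
    unlist(lapply(seq_len(length(sizes) - 1), function(l) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      c(stats::runif(sizes[l] * sizes[l + 1], -r, r), rep(0, sizes[l + 1]))
    }))
  })
  stopifnot(length(par0) == n_par)
  obj <- mlp_objective(X, positions, sizes)
  fit <- stats::optim(par0, obj$fn, obj$gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, lmm = 10))
  structure(list(weights = mlp_unpack(fit$par, sizes), sizes = sizes,
                 input_mean = mu, input_sd = sdv,
                 train_mse = fit$value,
                 converged = fit$convergence == 0,
                 seed = seed),
            class = "decoder_model")
}

#' Predict saccade end-positions from spike counts
#'
#' @param model A `decoder_model`.
#' @param counts n x n_neurons matrix (or a single count vector).
#' @return n x 2 matrix of predicted (x, y), deg; unclipped.
#' @export
predict_endpoints <- function(model, counts) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  if (ncol(counts) != model$sizes[1])
    stop("count vector length does not match the decoder input layer")
  X <- sweep(sweep(counts, 2, model$input_mean), 2, model$input_sd, "/")
  mlp_forward(model$weights, X)$Y
}

# ---- evaluation statistics -------------------------------------------------

#' Confusion matrix over the ring of tested positions
#'
#' Each predicted end-position is assigned to the nearest tested position
#' (minimal Euclidean distance; ties to the lowest index). Direct
#' neighbors are the two angularly adjacent positions on the 8-ring, so
#' chance levels are 12.5% correct and 37.5% correct-or-neighbor.
#'
#' @param predictions n x 2 matrix of predicted positions.
#' @param true_idx Integer vector (length n): index of the true tested
#'   position per trial.
#' @param tested_positions k x 2 matrix of tested positions (distinct).
#' @return List: `confusion` (k x k row-stochastic matrix, rows = true),
#'   `pct_correct`, `pct_correct_or_neighbor`, `assigned` (index per
#'   trial).
#' @export
confusion_matrix <- function(predictions, true_idx, tested_positions) {
  tp <- as.matrix(tested_positions)
  k <- nrow(tp)
  stopifnot(nrow(unique(tp)) == k)
  d2 <- outer(predictions[, 1], tp[, 1], "-")^2 +
    outer(predictions[, 2], tp[, 2], "-")^2
  assigned <- max.col(-d2, ties.method = "first")
  cm <- matrix(0, k, k)
  for (i in seq_len(k)) {
    sel <- true_idx == i
    if (any(sel)) cm[i, ] <- tabulate(assigned[sel], k) / sum(sel)
  }
  ang <- atan2(tp[, 2], tp[, 1])
  ord <- order(ang)
  rank_of <- match(seq_len(k), ord)
  neighbor <- function(i, j) {
    di <- abs(rank_of[i] - rank_of[j])
    min(di, k - di) <= 1
  }
  correct <- mean(assigned == true_idx) * 100
  corr_nb <- mean(mapply(neighbor, true_idx, assigned)) * 100
  list(confusion = cm, pct_correct = correct,
       pct_correct_or_neighbor = corr_nb, assigned = assigned)
}

#' Center bias of a prediction
#'
#' Difference between the intercept of the tested position and the
#' intercept of the prediction along the target-motion direction `alpha`;
#' positive values mean the prediction is compressed toward the screen
#' center.
#'
#' @param tested,predicted Length-2 vectors or n x 2 matrices, deg.
#' @param alpha Motion direction (deg); for stationary tested positions the
#'   direction from the center to the position.
#' @return Center bias in deg (vectorized).
#' @export
center_bias <- function(tested, predicted, alpha) {
  tested <- if (is.vector(tested)) matrix(tested, ncol = 2) else as.matrix(tested)
  predicted <- if (is.vector(predicted)) matrix(predicted, ncol = 2) else as.matrix(predicted)
  intercept(tested[, 1], tested[, 2], alpha) -
    intercept(predicted[, 1], predicted[, 2], alpha)
}

#' Convert a spatial center bias into a time lag on the target
#'
#' @param bias Center bias, deg.
#' @param speed Target speed, deg/s (> 0).
#' @return Lag in ms: `1000 * bias / speed`.
#' @export
bias_to_time_lag <- function(bias, speed) {
  if (any(speed <= 0)) stop("speed must be > 0")
  1000 * bias / speed
}
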