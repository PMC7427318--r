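# Regularized spatio-temporal receptive-field mapping from sparse-noise
# responses: ON/OFF indicator design with a running-speed filter,
# Laplacian-penalized least squares, 10-fold cross-validated selection of
# the regularization strengths, shift-test acceptance and field summaries.

#' Build the sparse-noise regression design
#'
#' Predictors are indicators of white squares (ON block) and black squares
#' (OFF block) at every spatial position and stimulus lag, plus
#' running-speed regressors at lags spanning -5 to +5 s around the modeled
#' response. The response must already be binned/resampled to the stimulus
#' frame times. For calcium traces the conventional lags are 1-3 frames
#' before the response; for spikes, 0-1.
#'
#' @param noise a `noise_movie`.
#' @param response response trace sampled at the noise frame times.
#' @param lags integer frame offsets of the stimulus blocks (stimulus
#'   `lag` frames before the response).
#' @param running optional running-speed trace at frame times.
#' @param run_lag_range numeric length-2, running-filter span in seconds.
#'
#' @return An object of class `rf_design`: list with `X` (n x p matrix,
#'   no intercept), `y`, and metadata (`grid`, `lags`, `run_lags`,
#'   `on_cols`, `off_cols`, `run_cols`, `square_edge`).
#' @export
build_rf_design <- function(noise, response, lags = c(1, 2, 3),
                            running = NULL, run_lag_range = c(-5, 5)) {
  fr <- noise$frames
  nf <- dim(fr)[3]
  if (length(response) != nf)
    stop_invalid("response length must match the number of stimulus frames")
  grid <- dim(fr)[1:2]
  npix <- prod(grid)
  S <- matrix(fr, npix, nf)
  on_m <- t(S == 1) * 1
  off_m <- t(S == -1) * 1

  shift_rows <- function(M, lag) {
    # predictor value at response frame t is the stimulus at frame t - lag
    out <- matrix(0, nrow(M), ncol(M))
    if (lag >= 0) {
      if (lag < nrow(M)) out[(lag + 1):nrow(M), ] <- M[1:(nrow(M) - lag), ]
    } else {
      if (-lag < nrow(M)) out[1:(nrow(M) + lag), ] <- M[(1 - lag):nrow(M), ]
    }
    out
  }
  on_blocks <- lapply(lags, function(l) shift_rows(on_m, l))
  off_blocks <- lapply(lags, function(l) shift_rows(off_m, l))

  run_cols <- integer(0)
  run_block <- NULL
  run_lags <- integer(0)
  if (!is.null(running)) {
    if (length(running) != nf) stop_invalid("running length mismatch")
    fr_rate <- noise$update_rate
    run_lags <- seq(round(run_lag_range[1] * fr_rate),
                    round(run_lag_range[2] * fr_rate))
    run_block <- vapply(run_lags, function(l) {
      as.numeric(shift_rows(matrix(running, ncol = 1), l))
    }, numeric(nf))
  }

  X <- do.call(cbind, c(on_blocks, off_blocks,
                        if (!is.null(run_block)) list(run_block)))
  n_stim <- npix * length(lags)
  structure(list(X = X, y = response, grid = grid, lags = lags,
                 update_rate = noise$update_rate,
                 run_lags = run_lags,
                 on_cols = seq_len(n_stim),
                 off_cols = n_stim + seq_len(n_stim),
                 run_cols = if (length(run_lags)) 2 * n_stim + seq_along(run_lags)
                            else integer(0),
                 square_edge = noise$square_edge),
            class = "rf_design")
}

# Sparse second-difference-squared (Laplacian) penalty for one spatial map.
spatial_penalty <- function(grid) {
  ny <- grid[1]; nx <- grid[2]
  npix <- ny * nx
  id <- function(y, x) (x - 1) * ny + y
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    nb <- rbind(if (y > 1) c(y - 1, x), if (y < ny) c(y + 1, x),
                if (x > 1) c(y, x - 1), if (x < nx) c(y, x + 1))
    rows <- c(rows, id(y, x), id(nb[, 1], nb[, 2]))
    cols <- c(cols, rep(id(y, x), 1 + nrow(nb)))
    vals <- c(vals, nrow(nb), rep(-1, nrow(nb)))
  }
  L <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(npix, npix))
  as.matrix(Matrix::crossprod(L))
}

# Temporal second-difference penalty for the running filter.
temporal_penalty <- function(m) {
  if (m < 3) return(diag(0, m))
  D <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  crossprod(D)
}

# Full penalty matrix (no intercept) for the given lambdas.
rf_penalty <- function(design, lambda_rf, lambda_run) {
  p <- ncol(design$X)
  P <- matrix(0, p, p)
  sp <- spatial_penalty(design$grid)
  npix <- prod(design$grid)
  for (l in seq_along(design$lags)) {
    ix <- design$on_cols[(l - 1) * npix + seq_len(npix)]
    P[ix, ix] <- lambda_rf * sp
    ix <- design$off_cols[(l - 1) * npix + seq_len(npix)]
    P[ix, ix] <- lambda_rf * sp
  }
  if (length(design$run_cols)) {
    P[design$run_cols, design$run_cols] <-
      lambda_run * temporal_penalty(length(design$run_cols))
  }
  P
}

# Solve the penalized normal equations given precomputed cross-products
# (intercept handled by centering).
rf_solve <- function(XtX, Xty, xbar, ybar, n, P) {
  A <- XtX - n * tcrossprod(xbar) + P
  diag(A) <- diag(A) + 1e-8
  b <- Xty - n * xbar * ybar
  beta <- solve(A, b)
  list(beta = as.numeric(beta),
       intercept = ybar - sum(xbar * beta))
}

#' Fit regularized ON/OFF receptive fields with a running filter
#'
#' Penalized least squares with penalty
#' \eqn{\lambda_{rf}(\|\Delta w_{ON}\|^2 + \|\Delta w_{OFF}\|^2) +
#' \lambda_{run}\|\Delta_t h\|^2}, where \eqn{\Delta} is the discrete
#' spatial Laplacian applied per lag and \eqn{\Delta_t} the temporal second
#' difference; solved in closed form via the normal equations with an
#' unpenalized intercept.
#'
#' @param design an `rf_design`.
#' @param lambda_rf spatial smoothness strength for both fields.
#' @param lambda_run temporal smoothness strength for the running filter.
#'
#' @return An object of class `spatio_temporal_rf`: `w_on`, `w_off`
#'   (arrays rows x cols x lags), `running_filter`, `intercept`,
#'   `lambda_rf`, `lambda_run`.
#' @export
fit_rf <- function(design, lambda_rf, lambda_run = lambda_rf) {
  X <- design$X; y <- design$y
  n <- nrow(X)
  sol <- rf_solve(crossprod(X), crossprod(X, y), colMeans(X), mean(y), n,
                  rf_penalty(design, lambda_rf, lambda_run))
  beta_to_rf(sol$beta, sol$intercept, design, lambda_rf, lambda_run)
}

beta_to_rf <- function(beta, intercept, design, lambda_rf, lambda_run) {
  grid <- design$grid
  nl <- length(design$lags)
  structure(list(
    w_on = array(beta[design$on_cols], dim = c(grid, nl)),
    w_off = array(beta[design$off_cols], dim = c(grid, nl)),
    running_filter = if (length(design$run_cols)) beta[design$run_cols]
                     else numeric(0),
    intercept = intercept, beta = beta,
    lambda_rf = lambda_rf, lambda_run = lambda_run,
    lags = design$lags, run_lags = design$run_lags, grid = grid),
    class = "spatio_temporal_rf")
}

# Contiguous-block fold assignment.
cv_blocks <- function(n, k) {
  rep(seq_len(k), each = ceiling(n / k), length.out = n)
}

# Precompute per-fold cross-products for fast repeated solves.
rf_cv_precompute <- function(design, k = 10) {
  X <- design$X; y <- design$y
  n <- nrow(X)
  fold <- cv_blocks(n, k)
  XtX_all <- crossprod(X)
  folds <- lapply(seq_len(k), function(f) {
    te <- which(fold == f); tr <- which(fold != f)
    Xte <- X[te, , drop = FALSE]
    list(test = te, train = tr,
         XtX_tr = XtX_all - crossprod(Xte),
         Xs_tr = colSums(X[tr, , drop = FALSE]),
         Xte = Xte)
  })
  list(folds = folds, k = k, n = n)
}

# Held-out explained variance of the complete model and of the
# stimulus-only component (the latter computed against the response minus
# the fitted running component and intercept).
rf_cv_ev <- function(design, pre, lambda_rf, lambda_run, y = design$y) {
  P <- rf_penalty(design, lambda_rf, lambda_run)
  stim_cols <- c(design$on_cols, design$off_cols)
  ev_full <- ev_stim <- numeric(pre$k)
  for (f in seq_len(pre$k)) {
    fo <- pre$folds[[f]]
    ntr <- length(fo$train)
    ytr <- y[fo$train]; yte <- y[fo$test]
    sol <- rf_solve(fo$XtX_tr, crossprod(design$X[fo$train, , drop = FALSE], ytr),
                    fo$Xs_tr / ntr, mean(ytr), ntr, P)
    pred <- sol$intercept + as.numeric(fo$Xte %*% sol$beta)
    sst <- sum((yte - mean(yte))^2)
    ev_full[f] <- if (sst > 0) 1 - sum((yte - pred)^2) / sst else 0
    run_part <- if (length(design$run_cols))
      as.numeric(fo$Xte[, design$run_cols, drop = FALSE] %*%
                   sol$beta[design$run_cols]) else 0
    yadj <- yte - run_part - sol$intercept
    stim_pred <- as.numeric(fo$Xte[, stim_cols, drop = FALSE] %*%
                              sol$beta[stim_cols])
    sst2 <- sum((yadj - mean(yadj))^2)
    ev_stim[f] <- if (sst2 > 0) 1 - sum((yadj - stim_pred)^2) / sst2 else 0
  }
  list(ev_full = mean(ev_full), ev_stim = mean(ev_stim))
}

#' Select regularization strengths by 10-fold cross-validation
#'
#' Contiguous-block k-fold cross-validation over a 2-D grid of
#' (lambda_rf, lambda_run); returns the pair maximizing the mean held-out
#' explained variance of the complete model, and the model refitted on all
#' data at that pair. The default grid spans six decades in seven
#' logarithmic steps per axis.
#'
#' @param design an `rf_design`.
#' @param grid_rf,grid_run candidate lambda values.
#' @param k number of folds.
#'
#' @return List with `lambda_rf`, `lambda_run`, `cv_ev` (best mean EV),
#'   `cv_ev_stimulus` (stimulus-only EV at the optimum), `model` (refit on
#'   all data), `cv_table`, and `precomputed` fold cross-products.
#' @export
select_lambdas <- function(design, grid_rf = 10^seq(0, 6, length.out = 7),
                           grid_run = 10^seq(0, 6, length.out = 7), k = 10) {
  if (length(grid_rf) == 0 || length(grid_run) == 0)
    stop_invalid("lambda grids must be non-empty")
  pre <- rf_cv_precompute(design, k)
  tab <- expand.grid(lambda_rf = grid_rf, lambda_run = grid_run)
  res <- t(vapply(seq_len(nrow(tab)), function(i) {
    ev <- rf_cv_ev(design, pre, tab$lambda_rf[i], tab$lambda_run[i])
    c(ev$ev_full, ev$ev_stim)
  }, numeric(2)))
  tab$cv_ev <- res[, 1]; tab$cv_ev_stimulus <- res[, 2]
  best <- which.max(tab$cv_ev)
  model <- fit_rf(design, tab$lambda_rf[best], tab$lambda_run[best])
  list(lambda_rf = tab$lambda_rf[best], lambda_run = tab$lambda_run[best],
       cv_ev = tab$cv_ev[best], cv_ev_stimulus = tab$cv_ev_stimulus[best],
       model = model, cv_table = tab, precomputed = pre)
}

#' Acceptance test for a fitted receptive field
#'
#' A unit has a genuine receptive field when (i) the held-out explained
#' variance of the stimulus component alone (not considering the running
#' filter) exceeds `ev_threshold` (0.01), (ii) that explained variance is
#' significant under a circular-shift test of the response (p < 0.05), and
#' (iii) the field is spatially confined: the half-height ellipse covers
#' less than `max_area_frac` of the stimulus area.
#'
#' @param selection result of [select_lambdas()].
#' @param design the `rf_design` used.
#' @param n_shifts number of circular response shifts.
#' @param seed integer seed.
#' @param ev_threshold stimulus-EV acceptance threshold.
#' @param max_area_frac maximal ellipse-to-stimulus area ratio.
#' @param min_shift minimum shift in seconds.
#'
#' @return List with `accepted`, `ev_stimulus`, `p`, `confined`, `summary`.
#' @export
accept_rf <- function(selection, design, n_shifts = 200, seed = 1L,
                      ev_threshold = 0.01, max_area_frac = 0.25,
                      min_shift = 30) {
  set.seed(as.integer(seed))
  pre <- selection$precomputed
  lrf <- selection$lambda_rf; lrun <- selection$lambda_run
  obs <- selection$cv_ev_stimulus
  n <- length(design$y)
  shifts <- random_shifts(n, n_shifts, round(min_shift * design$update_rate))
  null_ev <- vapply(shifts, function(s) {
    ys <- design$y[c((s + 1):n, 1:s)]
    rf_cv_ev(design, pre, lrf, lrun, y = ys)$ev_stim
  }, numeric(1))
  p <- (1 + sum(null_ev >= obs)) / (n_shifts + 1)

  summ <- try(summarize_rf(selection$model), silent = TRUE)
  confined <- if (inherits(summ, "try-error")) FALSE else {
    area_frac <- summ$ellipse$area / prod(design$grid)
    is.finite(area_frac) && area_frac < max_area_frac
  }
  list(accepted = obs > ev_threshold && p < 0.05 && confined,
       ev_stimulus = obs, p = p, confined = confined,
       summary = if (inherits(summ, "try-error")) NULL else summ)
}

#' Summarize a fitted receptive field
#'
#' Spatial ON and OFF maps are taken at the lag of maximum energy; the
#' peak pixel is the argmax of the mean of |ON| and |OFF|. The peak values
#' r_ON and r_OFF are read there with the sign rules for suppressed fields:
#' when both are negative their signs are inverted; when they have opposite
#' signs the weaker (absolute) one is set to zero and the remaining value
#' made positive. The ON/OFF index is (r_ON - r_OFF)/(r_ON + r_OFF), with
#' categories ON (> 0.5), OFF (< -0.5), otherwise ON+OFF. The field
#' outline is a two-dimensional Gaussian fitted (by moments) to the
#' half-height region of the summed ON+OFF map.
#'
#' @param model a `spatio_temporal_rf`.
#'
#' @return An object of class `rf_summary`: list with `on_off_index`,
#'   `category`, `r_on`, `r_off`, `best_lag`, `ellipse` (center, semi-axes
#'   at half height in square units, angle, area).
#' @export
summarize_rf <- function(model) {
  nl <- dim(model$w_on)[3]
  energy <- vapply(seq_len(nl), function(l) {
    sum(model$w_on[, , l]^2) + sum(model$w_off[, , l]^2)
  }, numeric(1))
  if (all(energy == 0)) stop_degenerate("all-zero fields: summary undefined")
  l <- which.max(energy)
  on <- model$w_on[, , l]; off <- model$w_off[, , l]
  mean_map <- (abs(on) + abs(off)) / 2
  peak <- which(mean_map == max(mean_map), arr.ind = TRUE)[1, ]
  r_on <- on[peak[1], peak[2]]; r_off <- off[peak[1], peak[2]]

  if (r_on < 0 && r_off < 0) {
    r_on <- -r_on; r_off <- -r_off
  } else if (r_on * r_off < 0) {
    if (abs(r_on) >= abs(r_off)) { r_on <- abs(r_on); r_off <- 0 }
    else { r_off <- abs(r_off); r_on <- 0 }
  }
  if (r_on + r_off == 0) stop_degenerate("zero peak values: index undefined")
  idx <- (r_on - r_off) / (r_on + r_off)
  category <- if (idx > 0.5) "ON" else if (idx < -0.5) "OFF" else "ON+OFF"

  s <- on + off
  pos <- pmax(s, 0)
  if (sum(pos) == 0) pos <- pmax(-s, 0)
  thr <- max(pos) / 2
  m <- pos * (pos >= thr)
  w <- m / sum(m)
  ys <- row(m); xs <- col(m)
  cy <- sum(w * ys); cx <- sum(w * xs)
  cyy <- sum(w * (ys - cy)^2); cxx <- sum(w * (xs - cx)^2)
  cxy <- sum(w * (ys - cy) * (xs - cx))
  C <- matrix(c(cyy, cxy, cxy, cxx), 2)
  ev <- eigen(C, symmetric = TRUE)
  axes <- sqrt(2 * log(2) * pmax(ev$values, 1e-12))
  angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  structure(list(on_off_index = idx, category = category,
                 r_on = r_on, r_off = r_off, best_lag = model$lags[l],
                 ellipse = list(center = c(y = cy, x = cx), axes = axes,
                                angle = angle, area = pi * prod(axes))),
            class = "rf_summary")
}
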