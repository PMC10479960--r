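#' Fit control settings for voxelwise relaxometry
#'
#' @param t1_bounds_ms Lower/upper bounds on fitted T1 (ms). Fits landing on
#'   a bound are flagged non-converged.
#' @param s0_max_factor Upper bound on s0 as a multiple of the voxel's
#'   maximum signal.
#' @param param_tol Relative parameter tolerance for convergence.
#' @param max_iter Iteration cap for the Gauss-Newton refinement.
#' @param grid_size Number of log-spaced T1 candidates for the
#'   variable-projection initial grid search.
#' @return List of control settings.
#' @export
fit_control <- function(t1_bounds_ms = c(5, 10000), s0_max_factor = 10,
                        param_tol = 1e-8, max_iter = 200L, grid_size = 60L) {
  stopifnot(length(t1_bounds_ms) == 2, t1_bounds_ms[1] > 0,
            diff(t1_bounds_ms) > 0, param_tol > 0, max_iter >= 1)
  list(t1_bounds_ms = t1_bounds_ms, s0_max_factor = s0_max_factor,
       param_tol = param_tol, max_iter = as.integer(max_iter),
       grid_size = as.integer(grid_size))
}

# Vectorised nonlinear least squares for the 2-parameter saturation-recovery
# model S = s0 * (1 - exp(-TR/T1)) over the columns of Y (one voxel per
# column). Variable projection over a log-spaced T1 grid supplies the start
# (s0 is linear given T1, so the grid search is exact in s0); damped
# Gauss-Newton with step halving refines both parameters simultaneously for
# all voxels.
fit_sr2_matrix <- function(Y, tr, control = fit_control()) {
  n_tr <- length(tr)
  V <- ncol(Y)
  lb <- control$t1_bounds_ms[1]
  ub <- control$t1_bounds_ms[2]
  ymax <- apply(Y, 2, max)
  degenerate <- ymax <= 0 | apply(Y, 2, function(y) max(y) - min(y)) == 0
  out <- list(t1 = rep(NA_real_, V), s0 = rep(NA_real_, V),
              rmse = rep(NA_real_, V), converged = rep(FALSE, V))
  act <- which(!degenerate)
  if (!length(act)) return(out)
  Ya <- Y[, act, drop = FALSE]

  # variable projection grid: for each candidate T1 the optimal s0 is
  # <f, y> / <f, f> with f = 1 - exp(-TR/T1)
  t1_grid <- exp(seq(log(lb), log(ub), length.out = control$grid_size))
  Fg <- 1 - exp(-outer(tr, 1 / t1_grid))            # n_tr x G
  den <- colSums(Fg^2)                              # G
  num <- crossprod(Fg, Ya)                          # G x V
  rss <- outer(rep(1, length(t1_grid)), colSums(Ya^2)) - num^2 / den
  best <- max.col(t(-rss), ties.method = "first")
  t1 <- t1_grid[best]
  s0 <- pmax(num[cbind(best, seq_along(act))] / den[best], 1e-12)

  rss_of <- function(t1, s0) {
    Fm <- 1 - exp(-outer(tr, 1 / t1))
    colSums((Fm * rep(s0, each = n_tr) - Ya)^2)
  }
  cur_rss <- rss_of(t1, s0)
  conv <- rep(FALSE, length(act))
  for (iter in seq_len(control$max_iter)) {
    E <- exp(-outer(tr, 1 / t1))                    # n_tr x V
    Fm <- 1 - E
    R <- Fm * rep(s0, each = n_tr) - Ya             # residuals
    J1 <- Fm                                        # d/ds0
    J2 <- -(E * outer(tr, s0 / t1^2))               # d/dT1
    a11 <- colSums(J1 * J1)
    a12 <- colSums(J1 * J2)
    a22 <- colSums(J2 * J2)
    b1 <- -colSums(J1 * R)
    b2 <- -colSums(J2 * R)
    det <- a11 * a22 - a12^2
    det[abs(det) < 1e-300] <- NA
    ds0 <- (a22 * b1 - a12 * b2) / det
    dt1 <- (a11 * b2 - a12 * b1) / det
    ds0[is.na(ds0)] <- 0
    dt1[is.na(dt1)] <- 0
    step <- rep(1, length(act))
    for (h in 1:12) {
      new_t1 <- pmin(pmax(t1 + step * dt1, lb), ub)
      new_s0 <- pmin(pmax(s0 + step * ds0, 1e-12),
                     control$s0_max_factor * ymax[act])
      new_rss <- rss_of(new_t1, new_s0)
      worse <- new_rss > cur_rss * (1 + 1e-14)
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    rel <- pmax(abs(new_t1 - t1) / pmax(t1, lb),
                abs(new_s0 - s0) / pmax(s0, 1e-12))
    t1 <- new_t1
    s0 <- new_s0
    cur_rss <- new_rss
    conv <- conv | rel < control$param_tol
    if (all(rel < control$param_tol)) break
  }
  on_bound <- t1 <= lb * (1 + 1e-9) | t1 >= ub * (1 - 1e-9)
  out$t1[act] <- t1
  out$s0[act] <- s0
  out$rmse[act] <- sqrt(pmax(cur_rss, 0) / n_tr)
  out$converged[act] <- conv & !on_bound & s0 > 0
  out
}

# 3-parameter recovery S = a + b * exp(-TR/T1): T1 is the only nonlinear
# parameter, so variable projection reduces each voxel to a 1-D profiled
# least-squares problem solved by grid search plus stats::optimize.
fit_sr3_matrix <- function(Y, tr, control = fit_control()) {
  n_tr <- length(tr)
  V <- ncol(Y)
  lb <- control$t1_bounds_ms[1]
  ub <- control$t1_bounds_ms[2]
  out <- list(t1 = rep(NA_real_, V), s0 = rep(NA_real_, V),
              offset = rep(NA_real_, V), rmse = rep(NA_real_, V),
              converged = rep(FALSE, V))
  t1_grid <- exp(seq(log(lb), log(ub), length.out = control$grid_size))
  for (v in seq_len(V)) {
    y <- Y[, v]
    if (max(y) <= 0 || max(y) - min(y) == 0) next
    prof_rss <- function(t1) {
      X <- cbind(1, exp(-tr / t1))
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }
    g_rss <- vapply(t1_grid, prof_rss, numeric(1))
    k <- which.min(g_rss)
    bracket <- c(t1_grid[max(1, k - 1)], t1_grid[min(length(t1_grid), k + 1)])
    opt <- stats::optimize(prof_rss, interval = bracket, tol = lb * 1e-6)
    t1 <- opt$minimum
    X <- cbind(1, exp(-tr / t1))
    cf <- stats::lm.fit(X, y)$coefficients
    a <- cf[1]; b <- cf[2]
    on_bound <- t1 <= lb * (1 + 1e-6) | t1 >= ub * (1 - 1e-6)
    out$t1[v] <- t1
    out$s0[v] <- a                  # S(Inf): recovered equilibrium signal
    out$offset[v] <- a + b          # S(0): residual saturation offset
    out$rmse[v] <- sqrt(opt$objective / n_tr)
    out$converged[v] <- !on_bound && a > 0
  }
  out
}

#' Fit the signal-recovery model to one voxel
#'
#' Nonlinear least-squares fit of either the 2-parameter saturation-recovery
#' model `S = s0 * (1 - exp(-TR/T1))` (`"sr2"`, the default) or the
#' 3-parameter exponential recovery `S = a + b * exp(-TR/T1)` (`"sr3"`,
#' reported as `s0 = a` and `offset = a + b`).
#'
#' @param signal Numeric vector of magnitudes, one per TR.
#' @param tr_list_ms Repetition times (ms), same length as `signal`,
#'   length >= number of model parameters + 1.
#' @param model `"sr2"` or `"sr3"`.
#' @param control A [fit_control()] list.
#' @return List with `t1_ms`, `s0`, `offset` (NA for sr2), `rmse`,
#'   `converged`. Degenerate (all-zero or constant) signals return
#'   `converged = FALSE` with NA estimates rather than an error.
#' @export
fit_voxel_recovery <- function(signal, tr_list_ms, model = c("sr2", "sr3"),
                               control = fit_control()) {
  model <- match.arg(model)
  n_par <- if (model == "sr2") 2L else 3L
  if (length(signal) != length(tr_list_ms))
    stop("signal and tr_list_ms lengths differ")
  if (length(signal) < n_par + 1)
    stop("need at least ", n_par + 1, " TR points for the ", model, " model")
  Y <- matrix(signal, ncol = 1)
  f <- if (model == "sr2") fit_sr2_matrix else fit_sr3_matrix
  r <- f(Y, tr_list_ms, control)
  list(t1_ms = r$t1[1], s0 = r$s0[1],
       offset = if (model == "sr3") r$offset[1] else NA_real_,
       rmse = r$rmse[1], converged = r$converged[1])
}

#' Fit a voxelwise T1 map to a multi-TR series
#'
#' Every masked voxel is fitted independently (no spatial regularisation);
#' voxels outside the mask, degenerate voxels, and fits landing on a T1
#' bound are marked non-converged and carry NA in the parameter maps.
#'
#' @param series A [vtr_series()].
#' @param mask Optional 3D logical array on the series grid; default fits
#'   every voxel.
#' @param model `"sr2"` or `"sr3"`.
#' @param control A [fit_control()] list.
#' @return An object of class `t1_map`: list of 3D arrays `t1_ms`, `s0`,
#'   `rmse`, logical `converged`, plus `model` and `voxel_size`.
#' @export
fit_t1_volume <- function(series, mask = NULL, model = c("sr2", "sr3"),
                          control = fit_control()) {
  stopifnot(inherits(series, "vtr_series"))
  model <- match.arg(model)
  dims <- dim(series$intensities)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dims)
  } else {
    if (!identical(as.integer(dim(mask)), as.integer(dims)))
      stop("mask grid ", paste(dim(mask), collapse = "x"),
           " does not match series grid ", paste(dims, collapse = "x"))
    mask <- array(as.logical(mask), dim = dims)
  }
  n_tr <- length(series$tr_list_ms)
  flat <- matrix(series$intensities, nrow = prod(dims), ncol = n_tr)
  idx <- which(mask)
  na_vol <- array(NA_real_, dim = dims)
  map <- list(t1_ms = na_vol, s0 = na_vol, rmse = na_vol,
              converged = array(FALSE, dim = dims),
              model = model, voxel_size = series$voxel_size)
  if (length(idx)) {
    Y <- t(flat[idx, , drop = FALSE])
    fitter <- if (model == "sr2") fit_sr2_matrix else fit_sr3_matrix
    r <- fitter(Y, series$tr_list_ms, control)
    map$t1_ms[idx] <- r$t1
    map$s0[idx] <- r$s0
    map$rmse[idx] <- r$rmse
    map$converged[idx] <- r$converged
  }
  class(map) <- "t1_map"
  map
}
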