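#' Sparse per-clone patient dataset
#'
#' Container for clinically-styled observations: per-clone differentiated
#' cell abundances (BCR-ABL1/GUS ratio or cells/ml) on a sparse day grid,
#' with missing values (late-emerging clones below the detection limit)
#' encoded as `NA`, plus an optional separately-recorded total-burden
#' series which may exceed the clone sum (unidentified clones) and is
#' never used for fitting.
#'
#' @param grid_days strictly increasing observation times in days.
#' @param observed numeric matrix, one column per clone, one row per grid
#'   day; `NA` marks censored/missing points. Column names are clone
#'   labels (defaults `clone1`, ...).
#' @param total_burden optional total-burden series on the same grid.
#' @param exclude character vector of clone labels to ignore during
#'   fitting (dataset-level flag).
#' @return object of class `cml_data`.
#' @export
cml_data <- function(grid_days, observed, total_burden = NULL,
                     exclude = character()) {
  observed <- as.matrix(observed)
  if (any(diff(grid_days) <= 0))
    stop("'grid_days' must be strictly increasing", call. = FALSE)
  if (nrow(observed) != length(grid_days))
    stop("'observed' must have one row per grid day", call. = FALSE)
  if (any(observed < 0, na.rm = TRUE))
    stop("observed abundances must be non-negative", call. = FALSE)
  if (is.null(colnames(observed)))
    colnames(observed) <- paste0("clone", seq_len(ncol(observed)))
  if (!is.null(total_burden) && length(total_burden) != length(grid_days))
    stop("'total_burden' must match the grid length", call. = FALSE)
  if (!all(exclude %in% colnames(observed)))
    stop("'exclude' names unknown clones", call. = FALSE)
  structure(list(grid_days = as.numeric(grid_days), observed = observed,
                 total_burden = total_burden, exclude = exclude),
            class = "cml_data")
}

#' @export
print.cml_data <- function(x, ...) {
  cat(sprintf("cml_data: %d clones x %d grid days [%g..%g]\n",
              ncol(x$observed), length(x$grid_days),
              min(x$grid_days), max(x$grid_days)))
  cat("  clones:", paste(colnames(x$observed), collapse = ", "), "\n")
  nmiss <- colSums(is.na(x$observed))
  if (any(nmiss > 0))
    cat("  censored points:",
        paste(sprintf("%s=%d", colnames(x$observed)[nmiss > 0],
                      nmiss[nmiss > 0]), collapse = ", "), "\n")
  if (length(x$exclude))
    cat("  excluded from fits:", paste(x$exclude, collapse = ", "), "\n")
  if (!is.null(x$total_burden)) cat("  total-burden series present\n")
  invisible(x)
}

#' Write / read a patient dataset as long-format CSV
#'
#' Columns `day`, `clone`, `value`, `mask` (1 = observed, 0 = censored);
#' the total burden is stored as pseudo-clone `"TOTAL"`.
#'
#' @param data a [cml_data()] object.
#' @param path file path.
#' @return `path` (write) or a `cml_data` object (read).
#' @export
write_patient_csv <- function(data, path) {
  rows <- do.call(rbind, lapply(colnames(data$observed), function(cl) {
    v <- data$observed[, cl]
    data.frame(day = data$grid_days, clone = cl,
               value = ifelse(is.na(v), 0, v),
               mask = as.integer(!is.na(v)))
  }))
  if (!is.null(data$total_burden))
    rows <- rbind(rows, data.frame(day = data$grid_days, clone = "TOTAL",
                                   value = data$total_burden, mask = 1L))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_csv
#' @export
read_patient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  clones <- setdiff(unique(df$clone), "TOTAL")
  days <- sort(unique(df$day))
  obs <- sapply(clones, function(cl) {
    sub <- df[df$clone == cl, ]
    v <- sub$value[match(days, sub$day)]
    v[sub$mask[match(days, sub$day)] == 0] <- NA
    v
  })
  obs <- matrix(obs, nrow = length(days),
                dimnames = list(NULL, clones))
  tot <- NULL
  if ("TOTAL" %in% df$clone) {
    sub <- df[df$clone == "TOTAL", ]
    tot <- sub$value[match(days, sub$day)]
  }
  cml_data(days, obs, tot)
}

# --- named scalar access into a parameter set / initial state -------------
# free-parameter names: alpha1.., delta1.., a1.., d1.., theta_s1..,
# theta_d (shared) or theta_d1.., nu2, nu3, nu_q1, nu_c1, theta_q1,
# xs1_0.., xd1_0.., xq1_0

par_get <- function(params, state0, name) {
  if (grepl("_0$", name)) {
    comp <- sub("_0$", "", name)
    return(unname(state0[comp]))
  }
  m <- regmatches(name, regexec("^(alpha|delta|a|d|theta_s|theta_d)([0-9])$", name))[[1]]
  if (length(m)) {
    v <- params[[m[2]]]
    return(v[as.integer(m[3])])
  }
  if (name %in% c("theta_d", "nu2", "nu3", "nu_q1", "nu_c1", "theta_q1"))
    return(params[[name]])
  stop(sprintf("unknown parameter name '%s'", name), call. = FALSE)
}

par_set <- function(params, state0, name, value) {
  if (grepl("_0$", name)) {
    comp <- sub("_0$", "", name)
    if (!comp %in% names(state0))
      stop(sprintf("unknown state component '%s'", comp), call. = FALSE)
    state0[comp] <- value
    return(list(params = params, state0 = state0))
  }
  m <- regmatches(name, regexec("^(alpha|delta|a|d|theta_s|theta_d)([0-9])$", name))[[1]]
  if (length(m)) {
    params[[m[2]]][as.integer(m[3])] <- value
  } else if (name %in% c("theta_d", "nu2", "nu3", "nu_q1", "nu_c1", "theta_q1")) {
    params[[name]] <- value
  } else stop(sprintf("unknown parameter name '%s'", name), call. = FALSE)
  list(params = params, state0 = state0)
}

apply_free <- function(params, state0, free_names, values) {
  for (k in seq_along(free_names)) {
    upd <- par_set(params, state0, free_names[k], values[k])
    params <- upd$params; state0 <- upd$state0
  }
  list(params = params, state0 = state0)
}

#' Residuals of a model against a patient dataset
#'
#' Integrates the model over the dataset span and returns the
#' concatenated `(model - observed)` differences over all fitted clones
#' and unmasked grid points, on the linear abundance scale. Censored
#' (`NA`) points and clones flagged in `data$exclude` contribute no
#' entries; the total-burden series is never included.
#'
#' @param params a [cml_params()] object.
#' @param state0 initial state.
#' @param data a [cml_data()] object; the first `n_clones` non-excluded
#'   columns are matched to model clones in order.
#' @param log_scale compare `log(model + eps)` to `log(obs + eps)` instead
#'   of linear differences (off by default; the fit statistic of record is
#'   linear).
#' @param rtol,atol solver tolerances (see [simulate_model()]).
#' @return numeric residual vector.
#' @export
cml_residuals <- function(params, state0, data, log_scale = FALSE,
                          rtol = 1e-8, atol = NULL) {
  keep <- setdiff(colnames(data$observed), data$exclude)
  if (length(keep) != params$n_clones)
    stop(sprintf("dataset has %d fitted clones but the model has %d",
                 length(keep), params$n_clones), call. = FALSE)
  grid <- data$grid_days
  times <- sort(unique(c(seq(min(grid), max(grid), length.out = 201), grid)))
  traj <- simulate_model(params, state0, times = times,
                         rtol = rtol, atol = atol)
  ig <- match(grid, traj$times)
  n <- params$n_clones
  model_xd <- traj$states[ig, n + seq_len(n), drop = FALSE]
  obs <- data$observed[, keep, drop = FALSE]
  res <- numeric(0)
  for (k in seq_len(n)) {
    ok <- !is.na(obs[, k])
    mk <- model_xd[ok, k]; yk <- obs[ok, k]
    if (log_scale) res <- c(res, log(mk + 1e-12) - log(yk + 1e-12))
    else res <- c(res, mk - yk)
  }
  res
}

#' Coefficient of determination of a fitted series
#'
#' `R^2 = sum_k (model_k - mean(obs))^2 / sum_k (obs_k - mean(obs))^2`,
#' the ratio of the model's squared deviations about the observed mean to
#' the observed squared deviations. Not clamped: values above 1 indicate
#' a model series spreading wider about the observed mean than the data
#' themselves.
#'
#' @param model_series model values at the observation times.
#' @param observed_series observed values (`NA` entries dropped pairwise).
#' @return the statistic.
#' @export
r_squared <- function(model_series, observed_series) {
  ok <- !is.na(observed_series) & !is.na(model_series)
  m <- model_series[ok]; o <- observed_series[ok]
  if (length(o) < 2) stop("need at least 2 observed points", call. = FALSE)
  om <- mean(o)
  denom <- sum((o - om)^2)
  if (denom == 0) stop("observed series has zero variance", call. = FALSE)
  sum((m - om)^2) / denom
}

#' Fit a model parameterization to a patient dataset
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, minpack.lm) on
#' the residuals of [cml_residuals()], from `n_starts` starting points:
#' the template itself plus log-normally jittered copies (free positive
#' quantities jittered multiplicatively, sign-indefinite ones
#' additively). Deterministic for a given `seed`.
#'
#' @param data a [cml_data()] object.
#' @param template a [cml_params()] object supplying every non-free
#'   parameter and the qualitative-simulation initial values of the free
#'   ones.
#' @param state0 template initial state; initial populations are fitted
#'   when named in `free` (e.g. `"xq1_0"`).
#' @param free character vector of free parameter names (see
#'   [cml_residuals()] naming: `alpha2`, `delta1`, `a1`, `theta_s2`,
#'   `nu_q1`, `xs1_0`, `xq1_0`, ...). Empty: the template is returned
#'   with residuals evaluated once.
#' @param lower,upper named bounds for the free parameters; defaults 0
#'   and `Inf`.
#' @param n_starts number of starting points (first = template).
#' @param seed RNG seed for the jittered starts.
#' @param jitter_sd standard deviation of the log-normal start jitter.
#' @param log_scale,rtol,atol passed to [cml_residuals()].
#' @return object of class `cml_fit` with the fitted parameters, initial
#'   state, per-clone R^2, residual norm and convergence diagnostics.
#' @export
cml_fit <- function(data, template, state0, free = character(),
                    lower = NULL, upper = NULL, n_starts = 1, seed = 1,
                    jitter_sd = 0.3, log_scale = FALSE,
                    rtol = 1e-8, atol = NULL) {
  keep <- setdiff(colnames(data$observed), data$exclude)
  p0 <- vapply(free, function(nm) par_get(template, state0, nm), numeric(1))
  lo <- rep(0, length(free)); hi <- rep(Inf, length(free))
  names(lo) <- names(hi) <- free
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  objective <- function(v) {
    upd <- apply_free(template, state0, free, v)
    tryCatch(cml_residuals(upd$params, upd$state0, data,
                           log_scale = log_scale, rtol = rtol, atol = atol),
             error = function(e) rep(1e6, 10L))
  }

  if (length(free) == 0) {
    res <- cml_residuals(template, state0, data, log_scale = log_scale,
                         rtol = rtol, atol = atol)
    return(finish_fit(template, state0, data, keep, res, 0L, TRUE,
                      rtol, atol))
  }

  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- p0
  if (n_starts > 1) {
    for (s in 2:n_starts) {
      jit <- p0 * exp(stats::rnorm(length(p0), 0, jitter_sd))
      flip <- p0 < 0  # sign-indefinite entries jittered around their value
      jit[flip] <- p0[flip] * exp(stats::rnorm(sum(flip), 0, jitter_sd))
      zero <- p0 == 0
      jit[zero] <- 0
      starts[[s]] <- pmin(pmax(jit, lo + 1e-300), hi)
    }
  }

  best <- NULL; best_ssq <- Inf; conv <- FALSE
  for (s in seq_len(n_starts)) {
    fitres <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]], lower = lo, upper = hi,
                         fn = objective,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fitres)) next
    ssq <- fitres$deviance
    if (is.finite(ssq) && ssq < best_ssq) {
      best_ssq <- ssq; best <- fitres
      conv <- fitres$info %in% 1:4
    }
  }
  if (is.null(best)) {
    return(finish_fit(template, state0, data, keep,
                      objective(p0), n_starts, FALSE, rtol, atol))
  }
  upd <- apply_free(template, state0, free, best$par)
  res <- cml_residuals(upd$params, upd$state0, data,
                       log_scale = log_scale, rtol = rtol, atol = atol)
  out <- finish_fit(upd$params, upd$state0, data, keep, res, n_starts,
                    conv, rtol, atol)
  out$free <- stats::setNames(as.numeric(best$par), free)
  out
}

finish_fit <- function(params, state0, data, keep, res, n_starts, conv,
                       rtol, atol) {
  grid <- data$grid_days
  times <- sort(unique(c(seq(min(grid), max(grid), length.out = 201), grid)))
  traj <- simulate_model(params, state0, times = times,
                         rtol = rtol, atol = atol)
  ig <- match(grid, traj$times)
  n <- params$n_clones
  model_xd <- traj$states[ig, n + seq_len(n), drop = FALSE]
  colnames(model_xd) <- keep
  r2 <- vapply(seq_len(n), function(k) {
    obs <- data$observed[, keep[k]]
    if (sum(!is.na(obs)) < 2 || stats::var(obs, na.rm = TRUE) == 0)
      return(NA_real_)
    r_squared(model_xd[, k], obs)
  }, numeric(1))
  names(r2) <- keep
  structure(list(params = params, state0 = state0, data = data,
                 fitted_xd = model_xd, r2_per_clone = r2,
                 residuals = res, residual_norm = sum(res^2),
                 n_starts = n_starts, converged = conv,
                 free = stats::setNames(numeric(0), character(0)),
                 solver = list(rtol = rtol, atol = atol)),
            class = "cml_fit")
}

#' @export
print.cml_fit <- function(x, ...) {
  cat(sprintf("cml_fit: model %s, %d clones; SSR = %.6g; %s\n",
              x$params$model_kind, x$params$n_clones, x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$free))
    cat("  fitted:", paste(sprintf("%s=%.6g", names(x$free), x$free),
                           collapse = ", "), "\n")
  cat("  R^2 per clone:",
      paste(sprintf("%s=%.4f", names(x$r2_per_clone), x$r2_per_clone),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cml_fit <- function(object, ...) {
  cat("Fit of CML clonal-competition model", object$params$model_kind, "\n")
  print(object)
  cat("\nParameters:\n")
  print(object$params)
  cat("Initial state:\n")
  print(object$state0)
  invisible(object)
}

#' @export
coef.cml_fit <- function(object, ...) object$free

#' @export
residuals.cml_fit <- function(object, ...) object$residuals

#' Predicted differentiated-cell series of a fit
#'
#' @param object a `cml_fit` object.
#' @param times day grid; default the observation grid.
#' @param ... unused.
#' @return matrix of per-clone differentiated populations at `times`.
#' @export
predict.cml_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted_xd)
  traj <- simulate_model(object$params, object$state0,
                         times = sort(unique(c(0, times))),
                         rtol = object$solver$rtol, atol = object$solver$atol)
  n <- object$params$n_clones
  out <- traj$states[match(times, traj$times), n + seq_len(n), drop = FALSE]
  colnames(out) <- colnames(object$fitted_xd)
  out
}

#' Plot a fit against the observations
#'
#' @param x a `cml_fit` object.
#' @param log axis specification.
#' @param ... further graphical arguments.
#' @export
plot.cml_fit <- function(x, log = "y", ...) {
  grid <- x$data$grid_days
  times <- seq(min(grid), max(grid), length.out = 200)
  pred <- predict(x, times)
  n <- ncol(pred)
  obs <- x$data$observed[, colnames(pred), drop = FALSE]
  pos <- function(v) { v[v <= 0] <- NA; v }
  graphics::matplot(times, pos(pred), type = "l", lty = 1, col = seq_len(n) + 1,
                    log = log, xlab = "time [days]",
                    ylab = "differentiated cells", ...)
  graphics::matpoints(grid, pos(obs), pch = 19, col = seq_len(n) + 1)
  graphics::legend("topright", bty = "n", lty = 1, col = seq_len(n) + 1,
                   legend = colnames(pred))
  invisible(x)
}

#' Simulate a synthetic dataset from a fitted model
#'
#' Wraps [generate_profile()] with the fitted parameters and state.
#'
#' @param object a `cml_fit` object.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param grid_days,noise_cv,lod,unknown_clone_fraction see
#'   [generate_profile()].
#' @param ... unused.
#' @return a [cml_data()] object, or a list of them when `nsim > 1`.
#' @export
simulate.cml_fit <- function(object, nsim = 1, seed = 1,
                             grid_days = NULL, noise_cv = 0.05, lod = 0,
                             unknown_clone_fraction = 0, ...) {
  if (is.null(grid_days)) grid_days <- object$data$grid_days
  out <- lapply(seq_len(nsim), function(k)
    generate_profile(object$params, object$state0, grid_days,
                     noise_cv = noise_cv, lod = lod,
                     unknown_clone_fraction = unknown_clone_fraction,
                     seed = seed + k - 1))
  if (nsim == 1) out[[1]] else out
}
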