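#' Exponential growth-function family
#'
#' The reduced two-clone analysis is formulated for any monotonically
#' increasing `g` with `g(0) = 0` through `f(u) = (1 + g0) / (1 + g(u))`;
#' the package ships the exponential member `g(u) = exp(u) - 1` (with
#' `g0 = 0`), whose `f` is the exponential feedback factor of the full
#' models. Alternative families (Hill, Tsallis) can be supplied as a
#' `list(g =, g_inv =)` pair wherever a `family` argument is accepted.
#'
#' @format a list with functions `g` and `g_inv`.
#' @export
exp_family <- list(g = function(u) exp(u) - 1,
                   g_inv = function(y) log1p(y))

#' Rescale a two-clone stem subsystem to canonical form
#'
#' After the primary clone is eliminated and mutation influx is switched
#' off, the stem-cell competition between two surviving clones reduces to
#' a planar system. Rescaling populations by `omega_ii / theta_si` brings
#' it to the canonical form with hatted birth/decay rates
#' `l_hat_i = (theta_si / omega_ii) alpha_i`,
#' `d_hat_i = (theta_si / omega_ii) delta_i` and cross-competition weights
#' `w_hat_1 = theta_s3 omega_23 / (theta_s2 omega_33)`,
#' `w_hat_2 = theta_s2 omega_32 / (theta_s3 omega_22)` (indices written
#' for the default pair, clones 2 and 3 of a three-clone system).
#'
#' @param params a [cml_params()] object.
#' @param clone_pair indices of the two clones kept, default `c(2, 3)`.
#' @return object of class `cml_rescaled2d` with fields `l_hat`, `d_hat`
#'   (length 2), `w_hat` (length 2) and the originating indices.
#' @export
rescale_2d <- function(params, clone_pair = c(2, 3)) {
  i <- clone_pair[1]; j <- clone_pair[2]
  if (any(!clone_pair %in% seq_len(params$n_clones)) || i == j)
    stop("'clone_pair' must name two distinct clones", call. = FALSE)
  om <- params$omega; th <- params$theta_s
  if (om[i, i] == 0 || om[j, j] == 0 || th[i] == 0 || th[j] == 0)
    stop("zero omega diagonal or theta_s: rescaling undefined", call. = FALSE)
  w_hat <- c(th[j] * om[i, j] / (th[i] * om[j, j]),
             th[i] * om[j, i] / (th[j] * om[i, i]))
  if (any(w_hat < 0))
    stop("negative cross-competition weights: the canonical form requires w_hat >= 0",
         call. = FALSE)
  structure(list(
    l_hat = th[clone_pair] / diag(om)[clone_pair] * params$alpha[clone_pair],
    d_hat = th[clone_pair] / diag(om)[clone_pair] * params$delta[clone_pair],
    w_hat = w_hat, clone_pair = clone_pair), class = "cml_rescaled2d")
}

#' @export
print.cml_rescaled2d <- function(x, ...) {
  cat(sprintf("rescaled 2D stem system (clones %d, %d)\n",
              x$clone_pair[1], x$clone_pair[2]))
  cat("  l_hat:", format(x$l_hat, digits = 6), "\n")
  cat("  d_hat:", format(x$d_hat, digits = 6), "\n")
  cat("  w_hat:", format(x$w_hat, digits = 6), "\n")
  invisible(x)
}

#' Selection parameters and characteristic equilibrium values
#'
#' The selection (bifurcation) parameter of each rescaled clone is
#' `gamma = (l_hat - d_hat) / d_hat`, which reduces to
#' `(alpha - delta) / delta` because the theta/omega factors cancel. The
#' characteristic value is the rescaled single-clone equilibrium
#' `g_inv(gamma)`; for the exponential family `log(1 + gamma)`, defined
#' for `gamma > -1` (reported as `NA` otherwise).
#'
#' @param rp a `cml_rescaled2d` object from [rescale_2d()].
#' @param family growth-function family, default [exp_family].
#' @return object of class `cml_equilibrium` with `gamma` (length 2),
#'   `char` (length-2 characteristic values), `w_hat`, `clone_pair`.
#' @export
characteristic_values <- function(rp, family = exp_family) {
  stopifnot(inherits(rp, "cml_rescaled2d"))
  gamma <- (rp$l_hat - rp$d_hat) / rp$d_hat
  char <- ifelse(gamma > -1, family$g_inv(gamma), NA_real_)
  structure(list(gamma = gamma, char = char, w_hat = rp$w_hat,
                 clone_pair = rp$clone_pair, regime = NULL,
                 discriminants = NULL),
            class = "cml_equilibrium")
}

#' Classify the asymptotic regime of the reduced two-clone system
#'
#' Applies inequality criteria on the characteristic values
#' `(xs_char, ys_char)` and the discriminant products
#' `w_hat_1 * ys_char`, `w_hat_2 * xs_char`. Each clone can invade the
#' other's axis equilibrium exactly when its own characteristic value
#' exceeds the competition pressure there (`xs_char > w_hat_1 ys_char`
#' for the first clone, `ys_char > w_hat_2 xs_char` for the second):
#' \itemize{
#'   \item both `gamma <= 0`: only the origin is stable (`"origin"`);
#'   \item `xs_char < w_hat_1 ys_char` and `ys_char > w_hat_2 xs_char`:
#'     stable line equilibrium on the y axis (second clone survives);
#'   \item `xs_char > w_hat_1 ys_char` and `ys_char < w_hat_2 xs_char`:
#'     stable line equilibrium on the x axis (first clone survives);
#'   \item both clones can invade (`xs_char > w_hat_1 ys_char` and
#'     `ys_char > w_hat_2 xs_char`): stable mixed-state (coexistence)
#'     equilibrium;
#'   \item neither can invade (both inequalities reversed): unstable
#'     mixed-state equilibrium — a saddle whose separatrix divides the
#'     basins of the two axis equilibria (bistability);
#'   \item equality (within `tol`, relative): `"boundary_neutral"` — the
#'     linearization has a neutral component and the parameter point is a
#'     bifurcation point.
#' }
#' At a mixed equilibrium the Jacobian determinant is proportional to
#' `1 - w_hat_1 w_hat_2`, so the mutual-invasion case (which forces
#' `w_hat_1 w_hat_2 < 1`) is the stable one; the package labels follow
#' this linearization (confirmed by integration in the test suite).
#'
#' @param rep a `cml_equilibrium` object from [characteristic_values()].
#' @param tol relative tolerance for the equality (boundary) tests.
#' @return the object with `regime` and `discriminants` filled in.
#' @export
classify_equilibria <- function(rep, tol = 1e-9) {
  stopifnot(inherits(rep, "cml_equilibrium"))
  gx <- rep$gamma[1]; gy <- rep$gamma[2]
  if (gx <= 0 && gy <= 0) {
    rep$regime <- "origin"
    rep$discriminants <- c(w1_ys = NA_real_, w2_xs = NA_real_)
    return(rep)
  }
  if (gx <= 0 || gy <= 0) {
    # one clone cannot persist at all: the other's axis equilibrium
    rep$regime <- if (gx <= 0) "line_equilibrium_y_axis" else "line_equilibrium_x_axis"
    rep$discriminants <- c(w1_ys = NA_real_, w2_xs = NA_real_)
    return(rep)
  }
  xs <- rep$char[1]; ys <- rep$char[2]
  if (any(is.na(c(xs, ys))))
    stop("characteristic values undefined (gamma <= -1)", call. = FALSE)
  d1 <- rep$w_hat[1] * ys   # compares against xs_char
  d2 <- rep$w_hat[2] * xs   # compares against ys_char
  rep$discriminants <- c(w1_ys = d1, w2_xs = d2)
  near <- function(u, v) abs(u - v) <= tol * max(abs(u), abs(v), 1e-300)
  rep$regime <-
    if (near(xs, d1) || near(ys, d2)) "boundary_neutral"
    else if (xs < d1 && ys > d2) "line_equilibrium_y_axis"
    else if (xs > d1 && ys < d2) "line_equilibrium_x_axis"
    else if (xs > d1 && ys > d2) "stable_mixed"
    else "unstable_mixed"
  rep
}

#' @export
print.cml_equilibrium <- function(x, ...) {
  cat(sprintf("reduced 2D equilibrium analysis (clones %d, %d)\n",
              x$clone_pair[1], x$clone_pair[2]))
  cat(sprintf("  gamma        : %.6g, %.6g\n", x$gamma[1], x$gamma[2]))
  cat(sprintf("  characteristic: %.6g, %.6g\n", x$char[1], x$char[2]))
  if (!is.null(x$discriminants))
    cat(sprintf("  discriminants : w1*ys = %.6g, w2*xs = %.6g\n",
                x$discriminants[1], x$discriminants[2]))
  if (!is.null(x$regime)) cat("  regime        :", x$regime, "\n")
  invisible(x)
}

#' Analyze a parameter set's reduced two-clone system in one call
#'
#' Convenience wrapper: [rescale_2d()], [characteristic_values()] and
#' [classify_equilibria()] chained.
#'
#' @inheritParams rescale_2d
#' @inheritParams characteristic_values
#' @inheritParams classify_equilibria
#' @return a classified `cml_equilibrium` object.
#' @export
analyze_2d <- function(params, clone_pair = c(2, 3), family = exp_family,
                       tol = 1e-9) {
  classify_equilibria(characteristic_values(rescale_2d(params, clone_pair),
                                            family), tol)
}

#' Bifurcation points of the reduced two-clone system along a parameter
#'
#' Solves the two regime-boundary equations
#' `xs_char = w_hat_1(p) ys_char` and `ys_char = w_hat_2(p) xs_char` for
#' the scanned parameter in closed form. Supported scan parameters enter
#' the hatted quantities monotonically: `theta_s2`, `theta_s3`,
#' `omega_23`, `omega_32` (indices relative to the chosen pair: the
#' first/second named clone's threshold and the two cross weights).
#'
#' @param params a [cml_params()] object.
#' @param scan_param one of `"theta_s2"`, `"theta_s3"`, `"omega_23"`,
#'   `"omega_32"` when `clone_pair = c(2, 3)`; in general the names refer
#'   to `theta_s[i]`, `theta_s[j]`, `omega[i, j]`, `omega[j, i]`.
#' @param clone_pair indices of the two clones, default `c(2, 3)`.
#' @param family growth-function family, default [exp_family].
#' @return sorted numeric vector of the real positive boundary values
#'   (deduplicated when the two boundaries coincide).
#' @export
bifurcation_points <- function(params, scan_param = "theta_s2",
                               clone_pair = c(2, 3), family = exp_family) {
  i <- clone_pair[1]; j <- clone_pair[2]
  rp <- rescale_2d(params, clone_pair)
  cv <- characteristic_values(rp, family)
  xs <- cv$char[1]; ys <- cv$char[2]
  if (any(is.na(c(xs, ys))) || xs <= 0 || ys <= 0)
    stop("bifurcation scan requires positive characteristic values",
         call. = FALSE)
  om <- params$omega; th <- params$theta_s
  allowed <- c(paste0("theta_s", c(i, j)),
               paste0("omega_", c(paste0(i, j), paste0(j, i))))
  if (!scan_param %in% allowed)
    stop(sprintf("scan parameter must be one of: %s",
                 paste(allowed, collapse = ", ")), call. = FALSE)
  # boundary 1: xs = w_hat_1 ys  with w_hat_1 = th_j om_ij / (th_i om_jj)
  # boundary 2: ys = w_hat_2 xs  with w_hat_2 = th_i om_ji / (th_j om_ii)
  pts <-
    if (scan_param == paste0("theta_s", i)) {
      c(th[j] * om[i, j] * ys / (om[j, j] * xs),
        th[j] * om[i, i] * ys / (om[j, i] * xs))
    } else if (scan_param == paste0("theta_s", j)) {
      c(th[i] * om[j, j] * xs / (om[i, j] * ys),
        th[i] * om[j, i] * xs / (om[i, i] * ys))
    } else if (scan_param == paste0("omega_", i, j)) {
      # enters boundary 1 only
      th[i] * om[j, j] * xs / (th[j] * ys)
    } else {
      # omega_ji enters boundary 2 only
      th[j] * om[i, i] * ys / (th[i] * xs)
    }
  pts <- pts[is.finite(pts) & pts > 0]
  sort(unique(round(pts, 12)))
}

#' Focal (co-dimension two) bifurcation point
#'
#' Characteristic values `(xs0_char, ys0_char)` at which both regime
#' boundaries intersect, i.e. `w_hat_2 xs0 = ys0 > 0` and
#' `xs0 = w_hat_1 ys0`, determined entirely by the growth-function
#' coefficients:
#' `xs0 = theta_s3 omega_23^2 omega_32 / (theta_s2 omega_33^2 omega_22)`,
#' `ys0 = omega_32 omega_23 / (omega_22 omega_33)` (indices for the
#' default pair).
#'
#' @param params a [cml_params()] object.
#' @param clone_pair indices of the two clones, default `c(2, 3)`.
#' @return named numeric vector `c(xs0_char, ys0_char)`.
#' @export
focal_point <- function(params, clone_pair = c(2, 3)) {
  i <- clone_pair[1]; j <- clone_pair[2]
  om <- params$omega; th <- params$theta_s
  if (om[i, i] == 0 || om[j, j] == 0 || th[i] == 0)
    stop("division by zero in the focal-point formula", call. = FALSE)
  c(xs0_char = th[j] * om[i, j]^2 * om[j, i] / (th[i] * om[j, j]^2 * om[i, i]),
    ys0_char = om[j, i] * om[i, j] / (om[i, i] * om[j, j]))
}

#' Scan a parameter and tabulate the regime classification
#'
#' Evaluates [analyze_2d()] on a grid of values of a scan parameter,
#' returning one row per value with the selection parameters,
#' discriminant products and regime label. Used by the `scan` command of
#' the command-line interface.
#'
#' @param params a [cml_params()] object (the scanned entry is replaced).
#' @param scan_param as in [bifurcation_points()].
#' @param values numeric grid of scan values.
#' @param clone_pair indices of the two clones, default `c(2, 3)`.
#' @return data frame with columns `value`, `gamma_x`, `gamma_y`,
#'   `xs_char`, `ys_char`, `w1_ys`, `w2_xs`, `regime`.
#' @export
scan_regimes <- function(params, scan_param = "theta_s2", values,
                         clone_pair = c(2, 3)) {
  i <- clone_pair[1]; j <- clone_pair[2]
  rows <- lapply(values, function(v) {
    p <- params
    if (scan_param == paste0("theta_s", i)) p$theta_s[i] <- v
    else if (scan_param == paste0("theta_s", j)) p$theta_s[j] <- v
    else if (scan_param == paste0("omega_", i, j)) p$omega[i, j] <- v
    else if (scan_param == paste0("omega_", j, i)) p$omega[j, i] <- v
    else stop(sprintf("unsupported scan parameter '%s'", scan_param),
              call. = FALSE)
    an <- analyze_2d(p, clone_pair)
    data.frame(value = v, gamma_x = an$gamma[1], gamma_y = an$gamma[2],
               xs_char = an$char[1], ys_char = an$char[2],
               w1_ys = an$discriminants[1], w2_xs = an$discriminants[2],
               regime = an$regime)
  })
  do.call(rbind, rows)
}
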