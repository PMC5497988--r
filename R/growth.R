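#' Stem-cell growth (negative feedback) function
#'
#' Evaluates the exponential feedback factor that down-regulates symmetric
#' division of clone `i`,
#' `zeta_i(xs) = exp(-sum_j omega[i, j] xs_j / theta_s[i])`.
#' The factor is 1 in an empty niche, decays as the weighted total stem
#' population exceeds the e-folding threshold `theta_s[i]`, and may exceed
#' 1 when negative competition weights make the weighted sum negative
#' (growth enhancement).
#'
#' @param i clone index.
#' @param xs stem-population vector (length `n_clones`).
#' @param params a [cml_params()] object.
#' @return dimensionless factor, strictly positive.
#' @export
stem_growth_factor <- function(i, xs, params) {
  n <- params$n_clones
  if (length(i) != 1L || i < 1L || i > n)
    stop("clone index out of range", call. = FALSE)
  if (length(xs) != n)
    stop("'xs' must have length n_clones", call. = FALSE)
  exp(-sum(params$omega[i, ] * xs) / params$theta_s[i])
}

#' Differentiation growth (negative feedback) function
#'
#' Evaluates the factor that down-regulates asymmetric division,
#' `p(xd) = exp(-sum_j xd_j / theta_d)`. With a single shared `theta_d`
#' the factor is clone-independent and `i` is ignored; with per-clone
#' thresholds each clone responds to the total differentiated population
#' through its own threshold.
#'
#' @param i clone index, or `NULL` with a shared threshold.
#' @param xd differentiated-population vector.
#' @param params a [cml_params()] object.
#' @return dimensionless factor in (0, 1] for non-negative populations.
#' @export
diff_growth_factor <- function(i = NULL, xd, params) {
  if (length(xd) != params$n_clones)
    stop("'xd' must have length n_clones", call. = FALSE)
  th <- params$theta_d
  if (length(th) == 1L) return(exp(-sum(xd) / th))
  if (is.null(i))
    stop("per-clone theta_d requires a clone index", call. = FALSE)
  if (i < 1L || i > params$n_clones)
    stop("clone index out of range", call. = FALSE)
  exp(-sum(xd) / th[i])
}

#' Burden-triggered quiescence switch (model C)
#'
#' The deactivation signal as a function of the total differentiated
#' burden: the hard step `H(y/theta_q1 - 1)` with `H(0) = 0`, or its
#' sigmoid approximation `sigma(y/theta_q1 - 1)` with
#' `sigma(x) = 1 / (1 + exp(-c1 (x - c2)))`.
#'
#' @param y_total total differentiated population (scalar, >= 0).
#' @param params a [cml_params()] object with `model_kind = "C"`.
#' @return factor in \code{[0, 1]}.
#' @export
quiescence_switch <- function(y_total, params) {
  if (params$model_kind != "C")
    stop("the quiescence switch is defined for model C only", call. = FALSE)
  x <- y_total / params$theta_q1 - 1
  if (params$switch_kind == "heaviside") return(as.numeric(x > 0))
  1 / (1 + exp(-params$c1 * (x - params$c2)))
}

#' Mutation influx into a descendant clone
#'
#' Rate of mutation influx from clone 1 (the only mutating clone) into
#' clone `j`: `r_{1 -> j} = nu_j zeta_1(xs) alpha_1 xs_1`.
#'
#' @param j target clone index (2 or 3).
#' @param xs stem-population vector.
#' @param params a [cml_params()] object.
#' @return influx rate, per day.
#' @export
mutation_influx <- function(j, xs, params) {
  if (!j %in% 2:3 || j > params$n_clones)
    stop("mutation targets are clones 2 and 3", call. = FALSE)
  nu <- if (j == 2) params$nu2 else params$nu3
  nu * params$alpha[1] * stem_growth_factor(1, xs, params) * xs[1]
}

#' Right-hand side of the coupled population ODE system
#'
#' Derivatives of all populations for models A, B and C. Clone 1's birth
#' term carries the mutation survival factor `(1 - nu2 - nu3)`; clones 2
#' and 3 receive the corresponding mutation influx. For models B/C the
#' quiescent pool feeds the cycling clone-1 pool at rate `nu_q1`; model C
#' additionally transfers cycling cells to quiescence at rate
#' `nu_c1 * switch`. Negative components introduced by integrator
#' round-off are clipped to zero before the growth functions are
#' evaluated.
#'
#' The signature matches the convention of the deSolve integrators, so
#' the function can be passed to them directly.
#'
#' @param t time (days); the system is autonomous, `t` is unused.
#' @param state state vector as built by [cml_state()].
#' @param params a [cml_params()] object.
#' @return a list whose first element is the derivative vector.
#' @export
cml_rhs <- function(t, state, params) {
  check_state(state, params)
  n <- params$n_clones
  sp <- split_state(state, params)
  xs <- sp$xs; xd <- sp$xd; xq1 <- sp$xq1

  zeta <- exp(-as.vector(params$omega %*% xs) / params$theta_s)
  th <- params$theta_d
  p_fac <- exp(-sum(xd) / th)            # length 1 (shared) or n (per clone)

  nu2 <- params$nu2
  nu3 <- if (n >= 3) params$nu3 else 0
  dxs <- numeric(n)
  dxs[1] <- (1 - nu2 - nu3) * zeta[1] * params$alpha[1] * xs[1] -
    params$delta[1] * xs[1]
  dxs[2] <- nu2 * params$alpha[1] * zeta[1] * xs[1] +
    zeta[2] * params$alpha[2] * xs[2] - params$delta[2] * xs[2]
  if (n >= 3)
    dxs[3] <- nu3 * params$alpha[1] * zeta[1] * xs[1] +
      zeta[3] * params$alpha[3] * xs[3] - params$delta[3] * xs[3]
  dxd <- p_fac * params$a * xs - params$d * xd

  if (params$model_kind == "A") return(list(c(dxs, dxd)))

  dxq1 <- -params$nu_q1 * xq1
  dxs[1] <- dxs[1] + params$nu_q1 * xq1
  if (params$model_kind == "C" && params$nu_c1 > 0) {
    deact <- params$nu_c1 * quiescence_switch(sum(xd), params) * xs[1]
    dxs[1] <- dxs[1] - deact
    dxq1 <- dxq1 + deact
  }
  list(c(dxs, dxd, dxq1))
}
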