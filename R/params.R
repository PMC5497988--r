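#' Model parameterization for CML clonal-competition dynamics
#'
#' Builds and validates the full parameter set of one model instance. Three
#' model variants are supported:
#' \describe{
#'   \item{`"A"`}{cycling stem cells and differentiated cells only;}
#'   \item{`"B"`}{adds a quiescent clone-1 stem cell pool `xq1` that drains
#'     into the cycling pool at rate `nu_q1` (spontaneous activation);}
#'   \item{`"C"`}{adds burden-triggered deactivation: cycling clone-1 stem
#'     cells convert back to quiescence at rate `nu_c1` whenever the total
#'     differentiated population exceeds `theta_q1` (hard step or steep
#'     sigmoid switch).}
#' }
#' All rate constants are per day. Stem-cell populations are in arbitrary
#' units; differentiated populations in cells/ml blood or BCR-ABL1/GUS
#' ratio units, fixed by the generation rates `a`.
#'
#' @param model_kind one of `"A"`, `"B"`, `"C"`.
#' @param alpha per-clone symmetric division (stem-cell birth) rate
#'   constants; length sets the number of clones (2 or 3).
#' @param delta per-clone net stem-cell decay rate constants.
#' @param a per-clone differentiated-cell generation rate constants
#'   (asymmetric division).
#' @param d per-clone net differentiated-cell decay rate constants.
#' @param theta_s per-clone stem-cell feedback thresholds (e-folding
#'   thresholds of the symmetric-division growth functions).
#' @param theta_d differentiated-cell feedback threshold: a single shared
#'   scalar, or one value per clone (each clone's differentiation then
#'   responds to the total differentiated population through its own
#'   threshold).
#' @param omega square clonal-competition weight matrix; entry `omega[i, j]`
#'   weights the effect of clone `j`'s stem population on clone `i`'s
#'   symmetric division. Diagonal entries must be positive; negative
#'   off-diagonal entries are allowed and act growth-enhancing.
#' @param nu2,nu3 mutation rate constants per division, clone 1 into clone
#'   2 and clone 1 into clone 3 (`nu3` only for three-clone systems).
#' @param nu_q1 activation rate constant of quiescent clone-1 stem cells
#'   (models B, C).
#' @param nu_c1 deactivation rate constant of cycling clone-1 stem cells
#'   (model C). `nu_c1 = 0` reduces model C to model B.
#' @param theta_q1 total-burden threshold that triggers deactivation
#'   (model C; may be omitted when `nu_c1 = 0`).
#' @param switch_kind `"heaviside"` for the hard step (with H(0) = 0) or
#'   `"sigmoid"` for the smooth approximation.
#' @param c1,c2 steepness and offset of the sigmoid switch
#'   `sigma(x) = 1 / (1 + exp(-c1 (x - c2)))` applied to
#'   `x = y / theta_q1 - 1`; the defaults `c1 = 100`, `c2 = 0` make it a
#'   close approximation to the hard step.
#'
#' @return an object of class `cml_params`.
#' @seealso [cml_state()], [cml_rhs()], [simulate_model()], [cml_fixture()]
#' @examples
#' p <- cml_params("A",
#'   alpha = c(1, 1, 1), delta = c(1, 0.8, 0.8),
#'   a = rep(1e6, 3), d = rep(1, 3),
#'   theta_s = c(100, 100, 100), theta_d = 1e10,
#'   omega = matrix(c(1, 1, 1, 0.5, 1, 1, 1, 0.5, 1), 3, 3, byrow = TRUE))
#' p
#' @export
cml_params <- function(model_kind = c("A", "B", "C"),
                       alpha, delta, a, d, theta_s, theta_d, omega,
                       nu2 = 0, nu3 = 0,
                       nu_q1 = NULL, nu_c1 = NULL, theta_q1 = NULL,
                       switch_kind = c("heaviside", "sigmoid"),
                       c1 = 100, c2 = 0) {
  model_kind <- match.arg(model_kind)
  switch_kind <- match.arg(switch_kind)
  n <- length(alpha)
  if (!n %in% 2:3)
    stop("number of clones (length of 'alpha') must be 2 or 3", call. = FALSE)
  omega <- as.matrix(omega)
  storage.mode(omega) <- "double"
  for (nm in c("delta", "a", "d", "theta_s")) {
    v <- get(nm)
    if (length(v) != n)
      stop(sprintf("'%s' must have one value per clone (%d)", nm, n),
           call. = FALSE)
  }
  if (!length(theta_d) %in% c(1L, n))
    stop("'theta_d' must be a single shared scalar or one value per clone",
         call. = FALSE)
  if (!all(dim(omega) == c(n, n)))
    stop("'omega' must be a square matrix of dimension n_clones", call. = FALSE)
  if (any(!is.finite(c(alpha, delta, a, d, theta_s, theta_d, omega))))
    stop("non-finite parameter value", call. = FALSE)
  if (any(alpha <= 0) || any(a <= 0) || any(theta_s <= 0) || any(theta_d <= 0))
    stop("alpha, a, theta_s and theta_d must be strictly positive", call. = FALSE)
  if (any(delta < 0) || any(d < 0))
    stop("delta and d must be non-negative", call. = FALSE)
  if (any(diag(omega) <= 0))
    stop("diagonal entries of 'omega' must be positive", call. = FALSE)
  if (n == 2 && nu3 != 0)
    stop("'nu3' requires a three-clone system", call. = FALSE)
  if (nu2 < 0 || nu3 < 0 || nu2 + nu3 >= 1)
    stop("mutation rates must satisfy 0 <= nu2 + nu3 < 1", call. = FALSE)

  if (model_kind %in% c("B", "C")) {
    if (is.null(nu_q1) || !is.finite(nu_q1) || nu_q1 < 0)
      stop(sprintf("model %s requires a non-negative 'nu_q1'", model_kind),
           call. = FALSE)
  }
  if (model_kind == "C") {
    if (is.null(nu_c1) || !is.finite(nu_c1) || nu_c1 < 0)
      stop("model C requires a non-negative 'nu_c1'", call. = FALSE)
    if (nu_c1 > 0 && (is.null(theta_q1) || !is.finite(theta_q1) || theta_q1 <= 0))
      stop("model C with nu_c1 > 0 requires a positive 'theta_q1'", call. = FALSE)
    if (is.null(theta_q1)) theta_q1 <- Inf   # deactivation structurally off
  }
  if (model_kind != "C") { nu_c1 <- NULL; theta_q1 <- NULL }
  if (model_kind == "A") nu_q1 <- NULL
  if (!is.null(nu_q1)) nu_q1 <- as.numeric(nu_q1)
  if (!is.null(nu_c1)) nu_c1 <- as.numeric(nu_c1)
  if (!is.null(theta_q1)) theta_q1 <- as.numeric(theta_q1)

  structure(list(
    model_kind = model_kind, n_clones = n,
    alpha = as.numeric(alpha), delta = as.numeric(delta),
    a = as.numeric(a), d = as.numeric(d),
    theta_s = as.numeric(theta_s), theta_d = as.numeric(theta_d),
    omega = omega, nu2 = as.numeric(nu2), nu3 = as.numeric(nu3),
    nu_q1 = nu_q1, nu_c1 = nu_c1, theta_q1 = theta_q1,
    switch_kind = switch_kind, c1 = as.numeric(c1), c2 = as.numeric(c2)
  ), class = "cml_params")
}

#' @export
print.cml_params <- function(x, ...) {
  cat(sprintf("CML clonal-competition model %s (%d clones)\n",
              x$model_kind, x$n_clones))
  cat("  alpha  :", format(x$alpha, digits = 4), "\n")
  cat("  delta  :", format(x$delta, digits = 4), "\n")
  cat("  a      :", format(x$a, digits = 4), "\n")
  cat("  d      :", format(x$d, digits = 4), "\n")
  cat("  theta_s:", format(x$theta_s, digits = 4), "\n")
  cat("  theta_d:", format(x$theta_d, digits = 4),
      if (length(x$theta_d) == 1) "(shared)" else "(per clone)", "\n")
  cat("  omega  :\n")
  print(x$omega)
  cat("  nu2/nu3:", x$nu2, "/", x$nu3, "\n")
  if (x$model_kind != "A")
    cat("  quiescence: nu_q1 =", x$nu_q1,
        if (x$model_kind == "C")
          sprintf("; nu_c1 = %g; theta_q1 = %g; switch = %s",
                  x$nu_c1, x$theta_q1, x$switch_kind), "\n")
  invisible(x)
}

#' System state vector
#'
#' Packs per-clone cycling stem (`xs`) and differentiated (`xd`)
#' populations, plus the quiescent clone-1 pool `xq1` for models B/C, into
#' the named state vector used by [cml_rhs()] and [simulate_model()].
#' State length is `2 n + 1` when `xq1` is given, else `2 n`.
#'
#' @param xs per-clone cycling stem-cell populations.
#' @param xd per-clone differentiated-cell populations.
#' @param xq1 quiescent clone-1 stem population (models B/C), or `NULL`.
#' @return named numeric vector `xs1.., xd1.., [xq1]`.
#' @export
cml_state <- function(xs, xd, xq1 = NULL) {
  n <- length(xs)
  if (length(xd) != n)
    stop("'xs' and 'xd' must have the same length", call. = FALSE)
  if (any(c(xs, xd, xq1) < 0))
    stop("populations must be non-negative", call. = FALSE)
  s <- as.numeric(c(xs, xd, xq1))
  names(s) <- c(paste0("xs", seq_len(n)), paste0("xd", seq_len(n)),
                if (!is.null(xq1)) "xq1")
  s
}

# expected state length for a parameter set
state_length <- function(params) {
  2L * params$n_clones + as.integer(params$model_kind != "A")
}

check_state <- function(state, params) {
  if (length(state) != state_length(params))
    stop(sprintf("state vector length %d does not match model %s with %d clones (expected %d)",
                 length(state), params$model_kind, params$n_clones,
                 state_length(params)), call. = FALSE)
  invisible(TRUE)
}

# split a state vector into components; round-off negatives are clipped to
# zero (populations are non-negative by construction, integrators can
# undershoot at the 1e-16 scale)
split_state <- function(state, params, clip = TRUE) {
  n <- params$n_clones
  state <- unname(state)
  xs <- state[seq_len(n)]
  xd <- state[n + seq_len(n)]
  xq1 <- if (params$model_kind != "A") state[2L * n + 1L] else NULL
  if (clip) {
    xs <- pmax(xs, 0); xd <- pmax(xd, 0)
    if (!is.null(xq1)) xq1 <- max(xq1, 0)
  }
  list(xs = xs, xd = xd, xq1 = xq1)
}

#' Serialize a parameter set (and optional initial state) to JSON
#'
#' Field names mirror the model symbols (`alpha`, `delta`, `a`, `d`,
#' `theta_s`, `theta_d`, `omega`, `nu2`, `nu3`, `nu_q1`, `nu_c1`,
#' `theta_q1`, `c1`, `c2`, `model_kind`); rates are per day.
#'
#' @param params a [cml_params()] object.
#' @param path file path to write; with `path = NULL` the JSON string is
#'   returned.
#' @param state0 optional state vector stored alongside under `"state0"`.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_params_json <- function(params, path = NULL, state0 = NULL) {
  x <- unclass(params)
  x$omega <- unname(as.matrix(x$omega))
  if (!is.null(x$theta_q1) && !is.finite(x$theta_q1)) x$theta_q1 <- NULL
  if (!is.null(state0)) {
    sp <- split_state(state0, params, clip = FALSE)
    x$state0 <- list(xs = unname(sp$xs), xd = unname(sp$xd))
    if (!is.null(sp$xq1)) x$state0$xq1 <- unname(sp$xq1)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a parameter set from JSON
#'
#' @param path file path or a literal JSON string produced by
#'   [write_params_json()].
#' @return a list with elements `params` ([cml_params()]) and `state0`
#'   (named state vector, or `NULL` when absent from the file).
#' @export
read_params_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  p <- cml_params(
    model_kind = x$model_kind,
    alpha = x$alpha, delta = x$delta, a = x$a, d = x$d,
    theta_s = x$theta_s, theta_d = x$theta_d,
    omega = matrix(unlist(x$omega), length(x$alpha), length(x$alpha),
                   byrow = FALSE),
    nu2 = x$nu2 %||% 0, nu3 = x$nu3 %||% 0,
    nu_q1 = x$nu_q1, nu_c1 = x$nu_c1, theta_q1 = x$theta_q1,
    switch_kind = x$switch_kind %||% "heaviside",
    c1 = x$c1 %||% 100, c2 = x$c2 %||% 0)
  s0 <- NULL
  if (!is.null(x$state0))
    s0 <- cml_state(x$state0$xs, x$state0$xd, x$state0$xq1)
  list(params = p, state0 = s0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
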