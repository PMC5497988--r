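#' Available parameter fixtures
#'
#' Names of the parameter fixtures shipped with the package: the
#' test-simulation set (`table2_default` and its `theta_s2` variants,
#' with the variation column applied: `delta_2 = delta_3 = 0.8`,
#' `omega_21 = omega_32 = 0.5`) and the five patient-simulation columns
#' (`fig10`..`fig14`). `fig14` is the reduced two-clone model C;
#' `fig12`/`fig13` have `nu_c1 = 0` (no deactivation). All fixture values
#' are the printed coefficients, verbatim.
#'
#' @return character vector of fixture names.
#' @export
cml_fixtures <- function() {
  sort(sub("\\.json$", "",
           list.files(system.file("extdata", "fixtures", package = "cmldyn"),
                      pattern = "\\.json$")))
}

#' Load a parameter fixture
#'
#' @param name fixture identifier, one of [cml_fixtures()].
#' @return object of class `cml_fixture`: list with `name`, `params`
#'   ([cml_params()]), `state0` (named state vector) and `notes`.
#' @examples
#' fx <- cml_fixture("table2_theta_s2_100")
#' fx$params
#' @export
cml_fixture <- function(name) {
  path <- system.file("extdata", "fixtures", paste0(name, ".json"),
                      package = "cmldyn")
  if (path == "")
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(cml_fixtures(), collapse = ", ")), call. = FALSE)
  raw <- jsonlite::fromJSON(path)
  px <- read_params_json(path)
  structure(list(name = name, params = px$params, state0 = px$state0,
                 notes = raw$notes %||% ""), class = "cml_fixture")
}

#' @export
print.cml_fixture <- function(x, ...) {
  cat(sprintf("fixture '%s': %s\n", x$name, x$notes))
  print(x$params)
  cat("  state0:", paste(sprintf("%s=%.4g", names(x$state0), x$state0),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic patient profile
#'
#' Emulates the structure of clinical BCR-ABL1/GUS follow-up series:
#' integrates the model, samples the per-clone differentiated populations
#' on a sparse day grid, applies multiplicative log-normal noise with a
#' given coefficient of variation, censors values below a detection
#' limit (`NA`, as for late-emerging clones), and records a total-burden
#' series inflated by a fixed fraction to emulate unidentified clones
#' contributing to the total but not to any monitored clone. Total
#' burden receives the same noise model. Deterministic per `seed`.
#'
#' @param params a [cml_params()] object.
#' @param state0 initial state.
#' @param grid_days observation day grid (clinical month grids convert at
#'   30 days/month).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise (0 = noise-free).
#' @param lod detection limit; sampled values strictly below it are
#'   censored to `NA`.
#' @param unknown_clone_fraction fraction by which the recorded total
#'   burden exceeds the clone sum.
#' @param seed RNG seed.
#' @param rtol,atol solver tolerances (see [simulate_model()]).
#' @return a [cml_data()] object.
#' @export
generate_profile <- function(params, state0, grid_days,
                             noise_cv = 0, lod = 0,
                             unknown_clone_fraction = 0, seed = 1,
                             rtol = 1e-9, atol = NULL) {
  grid_days <- sort(unique(grid_days))
  times <- sort(unique(c(seq(min(grid_days), max(grid_days),
                             length.out = 201), grid_days)))
  traj <- simulate_model(params, state0, times = times,
                         rtol = rtol, atol = atol)
  ig <- match(grid_days, traj$times)
  n <- params$n_clones
  xd <- traj$states[ig, n + seq_len(n), drop = FALSE]
  colnames(xd) <- paste0("clone", seq_len(n))
  total <- rowSums(xd) * (1 + unknown_clone_fraction)

  set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- function(m) m * exp(matrix(
      stats::rnorm(length(m), -sdlog^2 / 2, sdlog), nrow(m), ncol(m)))
    xd <- noise(xd)
    total <- total * exp(stats::rnorm(length(total), -sdlog^2 / 2, sdlog))
  }
  if (lod > 0) xd[xd < lod] <- NA
  cml_data(grid_days, xd, total_burden = total)
}
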