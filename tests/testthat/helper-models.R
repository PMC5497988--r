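# builders shared across the test files

# three-clone test-simulation parameter set (variation column applied),
# optionally promoted to model B or C
t2_params <- function(theta_s2 = 100, model_kind = "A", nu_q1 = NULL,
                      nu_c1 = NULL, theta_q1 = NULL,
                      switch_kind = "heaviside") {
  cml_params(model_kind,
    alpha = c(1, 1, 1), delta = c(1, 0.8, 0.8),
    a = rep(1e6, 3), d = rep(1, 3),
    theta_s = c(100, theta_s2, 100), theta_d = 1e10,
    omega = matrix(c(1, 1, 1, 0.5, 1, 1, 1, 0.5, 1), 3, 3, byrow = TRUE),
    nu_q1 = nu_q1, nu_c1 = nu_c1, theta_q1 = theta_q1,
    switch_kind = switch_kind)
}

t2_state <- function(xq1 = NULL) {
  cml_state(xs = c(100, 5, 1), xd = c(7e7, 0, 0), xq1 = xq1)
}

# small two-clone competition system used for fitting/recovery tests
two_clone_params <- function(alpha = c(1, 1), delta = c(1, 0.8)) {
  cml_params("A", alpha = alpha, delta = delta,
    a = c(1e6, 1e6), d = c(1, 1), theta_s = c(100, 100), theta_d = 1e10,
    omega = matrix(c(1, 1, 0.5, 1), 2, 2, byrow = TRUE))
}

# random positive state of the right length for a parameter set
rand_state <- function(params, scale = 50) {
  n <- params$n_clones
  cml_state(xs = stats::runif(n, 0, scale),
            xd = stats::runif(n, 0, scale * 1e6),
            xq1 = if (params$model_kind != "A") stats::runif(1, 0, scale))
}

# random two-clone parameter set with gamma > 0 for both clones
rand_2clone <- function() {
  alpha <- stats::runif(2, 0.5, 1.5)
  gamma <- stats::runif(2, 0.05, 1.5)
  delta <- alpha / (1 + gamma)
  omega <- matrix(c(1, stats::runif(1, 0, 2.5),
                    stats::runif(1, 0, 2.5), 1), 2, 2, byrow = TRUE)
  cml_params("A", alpha = alpha, delta = delta,
    a = c(1e6, 1e6), d = c(1, 1),
    theta_s = stats::runif(2, 20, 300), theta_d = 1e10, omega = omega)
}
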