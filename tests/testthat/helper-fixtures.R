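# Shared fixtures: the central reference parameter point (theta, mu, p) =
# (0.5, 16, 0.1) and reduced-scale simulation settings used by the module
# tests (the acceptance tests run at full scale).

ref_params <- function(theta = 0.5, q = 0.5, mu = 16, p = 0.1) {
  model_params(theta, mu, p, q)
}

ref_sigmoid <- function(mu = 16, theta = 0.5) sigmoid_params(mu, theta)

# reduced-scale front-speed estimate (module tests only)
fast_speed <- function(params, direction, J = 240, t_final = 60, ...) {
  estimate_speed(params, direction, J = J, t_final = t_final, ...)
}

# independent scalar sigmoid (plain closed form, no package code)
raw_S <- function(x, mu, theta) 1 / (1 + exp(-mu * (x - theta)))
raw_Sp <- function(x, mu, theta) {
  s <- raw_S(x, mu, theta)
  mu * s * (1 - s)
}
raw_Fp <- function(x, mu, theta, p) {
  (-x + raw_S(x, mu, theta)) * (1 - p - p * raw_Sp(x, mu, theta))
}
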