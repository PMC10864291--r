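#' Heavy-tailed Levy flight steps
#'
#' Draws one step of a Levy flight: a random vector whose entry magnitudes
#' follow a heavy-tailed stable law with tail exponent `beta = levy_lambda -
#' 1`, realized by the Mantegna construction `u / |v|^(1/beta)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and the Mantegna scale
#' `sigma_u = [Gamma(1+beta) sin(pi beta / 2) /
#' (Gamma((1+beta)/2) beta 2^((beta-1)/2))]^(1/beta)`.
#' The power-law tail density `t^(-lambda)` with `1 < lambda < 3` makes the
#' walk mix many small moves with rare long jumps, the exploration behaviour
#' cuckoo search relies on. Draws come from R's current RNG stream, so
#' results are deterministic under `set.seed()`.
#'
#' @param dim Number of entries.
#' @param levy_lambda Tail exponent of the step-length density, in `(1, 3)`;
#'   default 2.5 (stability index 1.5, the canonical cuckoo-search choice).
#' @return A numeric vector of length `dim`.
#' @examples
#' set.seed(1)
#' levy_step(4)
#' @export
levy_step <- function(dim, levy_lambda = 2.5) {
  check_number(dim, "dim", 1, Inf, integer = TRUE)
  check_number(levy_lambda, "levy_lambda", 1, 3, open_lower = TRUE, open_upper = TRUE)
  beta <- levy_lambda - 1
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(dim, 0, sigma_u)
  v <- rnorm(dim)
  u / abs(v)^(1 / beta)
}

#' Geometric step-size factor of the improved cuckoo search
#'
#' The deterministic part of the iteration-adaptive step size: `a_max *
#' (a_max / a_min)^(-t / T)`, equal to `a_max` at `t = 0` and decaying
#' geometrically to `a_min` at `t = T`. Large early steps favour global
#' exploration; small late steps refine around the optimum.
#'
#' @param t Iteration, `0 <= t <= T`.
#' @param a_max,a_min Largest and smallest step scales, `0 < a_min <= a_max`.
#' @param T Total iterations.
#' @return The positive factor.
#' @export
step_size_factor <- function(t, a_max, a_min, T) {
  check_number(a_max, "a_max", 0, Inf, open_lower = TRUE)
  check_number(a_min, "a_min", 0, a_max, open_lower = TRUE)
  check_number(T, "T", 1, Inf, integer = TRUE)
  check_number(t, "t", 0, T)
  a_max * (a_max / a_min)^(-t / T)
}

#' Iteration-adaptive step size
#'
#' One random draw of the improved cuckoo search step size
#' `alpha_t = a_max * (a_max/a_min)^(-t/T) * ran * 0.01` with `ran` uniform
#' on (0, 1). The 0.01 factor is kept verbatim from the schedule definition;
#' `a_max`/`a_min` can be raised to compensate when searching a unit cube
#' (see the methods vignette).
#'
#' @inheritParams step_size_factor
#' @param params A [cs_params()] list supplying `a_max`, `a_min` and `T`.
#' @return A positive scalar step size.
#' @export
adaptive_step_size <- function(t, params) {
  factor <- step_size_factor(t, params$a_max, params$a_min, params$T)
  factor * runif(1) * 0.01
}
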