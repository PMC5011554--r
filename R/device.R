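#' Thermal device parameters
#'
#' The resistance unit of the training device heats with work and cools
#' passively; its temperature rise above baseline follows the first-order
#' balance `d(delta)/dt = gain_alpha * P(t) - cooling_lambda * delta(t)`.
#' The high-sensitivity placement has a fast cooling rate so the trace
#' plateaus within a bout (plateau = alpha * P / lambda); the low-sensitivity
#' placement cools so slowly that the 30-minute rise is quasi-linear, which is
#' what makes the 30-minute temperature rise usable as an exercise dose.
#'
#' @param mode `"high"` or `"low"`; selects the calibrated defaults from
#'   [study_defaults()] for any parameter not given explicitly.
#' @param gain_alpha Heating gain, degC per work-unit per minute (> 0).
#' @param cooling_lambda Cooling rate per minute (>= 0). High mode requires a
#'   rate at least ten times the low-mode default; low mode requires
#'   `cooling_lambda * 30 < 0.5` (quasi-linearity over a 30-minute bout).
#' @param noise_sd Additive Gaussian sensor noise SD in degC.
#' @param euler_step Integration step in minutes, in (0, 1].
#' @return An object of class `device_params`.
#' @export
#' @examples
#' steady_state_delta(1.0, device_params("high"))  # 34.2 degC plateau
device_params <- function(mode = c("high", "low"), gain_alpha = NULL,
                          cooling_lambda = NULL, noise_sd = NULL,
                          euler_step = NULL) {
  mode <- match.arg(mode)
  def <- study_defaults()$device[[mode]]
  p <- list(
    mode = mode,
    gain_alpha = gain_alpha %||% def$gain_alpha,
    cooling_lambda = cooling_lambda %||% def$cooling_lambda,
    noise_sd = noise_sd %||% def$noise_sd,
    euler_step = euler_step %||% def$euler_step
  )
  if (p$gain_alpha <= 0) stop("gain_alpha must be > 0", call. = FALSE)
  if (p$cooling_lambda < 0) stop("cooling_lambda must be >= 0", call. = FALSE)
  if (p$euler_step <= 0 || p$euler_step > 1) {
    stop("euler_step must be in (0, 1]", call. = FALSE)
  }
  low_default <- study_defaults()$device$low$cooling_lambda
  if (mode == "high" && p$cooling_lambda < 10 * low_default) {
    stop("high-sensitivity mode requires cooling_lambda >= 10x the low-mode ",
         "default (trace must plateau within a bout)", call. = FALSE)
  }
  if (mode == "low" && p$cooling_lambda * 30 >= 0.5) {
    stop("low-sensitivity mode requires cooling_lambda * 30 < 0.5 ",
         "(quasi-linear rise over 30 minutes)", call. = FALSE)
  }
  class(p) <- "device_params"
  p
}

#' @export
print.device_params <- function(x, ...) {
  cat(sprintf("<device_params> %s-sensitivity: alpha=%.4g degC/(work-unit*min), lambda=%.4g /min, noise SD=%.3g degC\n",
              x$mode, x$gain_alpha, x$cooling_lambda, x$noise_sd))
  invisible(x)
}

#' Simulate the device temperature trace for a work-rate input
#'
#' Integrates `d(delta)/dt = gain_alpha * P(t) - cooling_lambda * delta` from
#' `delta(0) = 0` by explicit fixed-step (Euler) integration at
#' `params$euler_step` minutes, holding the work rate constant within each
#' 1-minute sample, then samples the result back onto the 1-minute sensor
#' grid and adds optional Gaussian sensor noise.
#'
#' @param power A [power_trace()] on the uniform 1-minute grid. `power[i]` is
#'   held over the minute starting at `times[i]`; the returned trace has one
#'   more sample than `power` has minutes of drive.
#' @param params A [device_params()] object.
#' @param noise_sd Sensor noise SD in degC; defaults to `params$noise_sd`.
#'   Use 0 for deterministic traces.
#' @param seed Optional integer seed for the noise draw.
#' @return A [sensor_trace()] in the device's mode.
#' @export
#' @examples
#' p <- power_trace(0:29, rep(1, 30))
#' tr <- simulate_temperature(p, device_params("low"), noise_sd = 0)
#' tail(tr$delta_t_c, 1)  # ~8.1 degC after 30 min at unit work rate
simulate_temperature <- function(power, params, noise_sd = params$noise_sd,
                                 seed = NULL) {
  stopifnot(inherits(params, "device_params"))
  if (!inherits(power, "power_trace")) {
    stop("power must be a power_trace", call. = FALSE)
  }
  if (any(power$power < 0)) stop("power must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  delta <- euler_integrate(power$power, params)
  times <- c(power$minute, power$minute[length(power$minute)] + 1)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(delta), 0, noise_sd))
    noise[1] <- 0  # keep the baseline-zeroed convention
    delta <- pmax(delta + noise, -0.5)
  }
  sensor_trace(times, delta, mode = params$mode)
}

# Core integrator: per-minute constant drive, fixed-step explicit midpoint
# stepping at euler_step substeps (second order; plain forward Euler leaves a
# ~1% early-trace bias at the high-mode cooling rate).
# Returns delta at minutes 0..length(P).
euler_integrate <- function(P, params, delta0 = 0) {
  h <- params$euler_step
  nsub <- max(1L, round(1 / h))
  h <- 1 / nsub
  a <- params$gain_alpha
  lam <- params$cooling_lambda
  d <- delta0
  out <- numeric(length(P) + 1)
  out[1] <- delta0
  for (m in seq_along(P)) {
    drive <- a * P[m]
    for (k in seq_len(nsub)) {
      d_mid <- d + (h / 2) * (drive - lam * d)
      d <- d + h * (drive - lam * d_mid)
    }
    out[m + 1] <- d
  }
  out
}

#' Steady-state temperature rise at a constant work rate
#'
#' Closed form of the thermal model: at constant drive `P` the trace
#' approaches `gain_alpha * P / cooling_lambda`.
#'
#' @param power_level Work rate in work-units/min (>= 0).
#' @param params A [device_params()] object with `cooling_lambda > 0`.
#' @return Plateau temperature rise in degC.
#' @export
steady_state_delta <- function(power_level, params) {
  stopifnot(inherits(params, "device_params"))
  if (any(power_level < 0)) stop("power_level must be >= 0", call. = FALSE)
  if (params$cooling_lambda == 0) {
    stop("no steady state: cooling_lambda is 0", call. = FALSE)
  }
  params$gain_alpha * power_level / params$cooling_lambda
}

#' Estimate the work-rate trace from a temperature trace
#'
#' Inverts the thermal model:
#' `P_hat(t) = (d(delta)/dt + cooling_lambda * delta) / gain_alpha`, with the
#' derivative taken as a centered moving-window least-squares slope. This is
#' the deconvolved leg-work-output signal that fatigue detection operates on;
#' on low-sensitivity traces the raw slope is nearly constant by design, so
#' the deconvolution is what exposes a work-rate decline.
#'
#' @param trace A [sensor_trace()] with at least 3 samples.
#' @param params The [device_params()] the trace was recorded with.
#' @param smooth_window Width of the slope window in minutes (samples).
#' @return A [power_trace()] clipped at zero. Estimates within half a window
#'   of the trace edges are boundary-biased.
#' @export
estimate_power <- function(trace, params, smooth_window = 3) {
  stopifnot(inherits(trace, "sensor_trace"), inherits(params, "device_params"))
  if (nrow(trace) < 3) stop("trace must have at least 3 samples", call. = FALSE)
  if (smooth_window > nrow(trace)) {
    stop("smoothing window larger than trace", call. = FALSE)
  }
  deriv <- moving_slope(trace$minute, trace$delta_t_c, smooth_window)
  p_hat <- (deriv + params$cooling_lambda * trace$delta_t_c) / params$gain_alpha
  power_trace(trace$minute, pmax(p_hat, 0))
}
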