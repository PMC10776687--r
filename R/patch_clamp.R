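#' Kinetic constants of the transport cycle
#'
#' Container for the rate constants probed by the electrophysiology and
#' uptake protocols: the flipping rate (relaxation of the capacitive peak at
#' 0 mV, i.e. binding + occlusion + inward opening), the association and
#' dissociation rate constants, the cumulative dissociation rate (release
#' from outward- and inward-facing states during transport), and the uptake
#' parameters.
#'
#' @param k_flip flipping rate, 1/s
#' @param K_on association rate constant, 1/(uM s)
#' @param K_off dissociation rate from the outward-open state, 1/s
#' @param K_off_cumulative cumulative dissociation rate, 1/s
#' @param IC50 uptake-inhibition potency, uM
#' @param Km Michaelis constant, uM
#' @param Vmax maximal uptake velocity, response units/min
#' @return object of class `transport_rates`
#' @export
transport_rates <- function(k_flip, K_on, K_off, K_off_cumulative = K_off,
                            IC50 = 1, Km = 1, Vmax = 100) {
  vals <- c(k_flip = k_flip, K_on = K_on, K_off = K_off,
            K_off_cumulative = K_off_cumulative, IC50 = IC50, Km = Km,
            Vmax = Vmax)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all transport rates must be finite and strictly positive")
  structure(as.list(vals), class = "transport_rates")
}

#' Patch-clamp protocol description
#'
#' @param mode one of "peak_0mV", "steady_state", "peak_recovery",
#'   "steady_recovery"
#' @param concentration_uM compound concentration, uM
#' @param compound label
#' @param duration_s trace length for single-pulse modes, s
#' @param dt_s sampling interval, s
#' @param pulse_start_s onset of the (first) pulse, s
#' @param pulse_length_s pulse length for recovery trains, s
#' @param wash_intervals_s wash times between pulses for recovery modes, s
#' @param amplitude peak amplitude scale, arbitrary current units
#' @param ss_amplitude steady-state amplitude scale
#' @return list of class `patch_protocol`
#' @export
patch_protocol <- function(mode = "peak_0mV", concentration_uM = 100,
                           compound = "5HT", duration_s = 0.2, dt_s = 1e-4,
                           pulse_start_s = 0.02, pulse_length_s = 0.1,
                           wash_intervals_s = c(0.5, 1, 2, 4, 8),
                           amplitude = 1, ss_amplitude = 0.3) {
  modes <- c("peak_0mV", "steady_state", "peak_recovery", "steady_recovery")
  if (!mode %in% modes)
    stopf("unknown protocol mode '%s' (valid: %s)", mode, paste(modes, collapse = ", "))
  if (concentration_uM < 0) stopf("concentration must be >= 0")
  structure(list(mode = mode, concentration_uM = concentration_uM,
                 compound = compound, duration_s = duration_s, dt_s = dt_s,
                 pulse_start_s = pulse_start_s, pulse_length_s = pulse_length_s,
                 wash_intervals_s = wash_intervals_s, amplitude = amplitude,
                 ss_amplitude = ss_amplitude),
            class = "patch_protocol")
}

#' Synthetic patch-clamp current traces
#'
#' Generates whole-cell current traces under the standard transporter
#' protocols with known ground-truth kinetics:
#' \itemize{
#'   \item `peak_0mV`: a capacitive peak relaxing mono-exponentially,
#'     `I(t) = A exp(-k_obs t)`, where the observed rate follows the
#'     saturating dose law `k_obs = Y0 + (Plateau - Y0)(1 - exp(-K c))` with
#'     `Y0 = 0`, `Plateau = k_flip` and `K = K_on / k_flip` (so the initial
#'     slope of the dose curve is K_on).
#'   \item `steady_state`: the peak plus a sustained transport current with
#'     plateau `I_ss c / (c + Km)`.
#'   \item `peak_recovery` / `steady_recovery`: a reference pulse followed by
#'     test pulses after increasing wash intervals `t_w`; successive
#'     amplitudes recover as `1 - exp(-K_off t_w)` (peak mode) or
#'     `1 - exp(-K_off_cumulative t_w)` (steady mode).
#' }
#' Zero concentration yields a flat zero trace.
#'
#' @param rates transport_rates (ground truth)
#' @param protocol patch_protocol
#' @param noise_sigma additive Gaussian noise as a fraction of the amplitude
#' @param seed integer seed
#' @return object of class `current_trace_set`: time_s, current, protocol,
#'   and for recovery modes the noise-free fractional amplitudes
#' @export
simulate_patch_clamp <- function(rates, protocol = patch_protocol(),
                                 noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(rates, "transport_rates"),
            inherits(protocol, "patch_protocol"))
  c_uM <- protocol$concentration_uM
  if (c_uM < 0) stopf("concentration must be >= 0")
  k_obs <- rates$k_flip * (1 - exp(-(rates$K_on / rates$k_flip) * c_uM))
  occupancy <- c_uM / (c_uM + rates$Km)
  A <- protocol$amplitude * occupancy

  mode <- protocol$mode
  amplitudes <- NULL
  if (mode %in% c("peak_0mV", "steady_state")) {
    time_s <- seq(0, protocol$duration_s, by = protocol$dt_s)
    current <- numeric(length(time_s))
    on <- time_s >= protocol$pulse_start_s
    if (c_uM > 0) {
      tt <- time_s[on] - protocol$pulse_start_s
      current[on] <- A * exp(-k_obs * tt)
      if (mode == "steady_state")
        current[on] <- current[on] + protocol$ss_amplitude * occupancy
    }
  } else {
    K <- if (mode == "peak_recovery") rates$K_off else rates$K_off_cumulative
    wash <- protocol$wash_intervals_s
    amplitudes <- 1 - exp(-K * wash)
    starts <- protocol$pulse_start_s +
      cumsum(c(0, protocol$pulse_length_s + wash))
    total <- utils::tail(starts, 1L) + protocol$pulse_length_s +
      protocol$pulse_start_s
    time_s <- seq(0, total, by = protocol$dt_s)
    current <- numeric(length(time_s))
    scales <- c(1, amplitudes)   # reference pulse first
    if (c_uM > 0) {
      for (i in seq_along(starts)) {
        on <- time_s >= starts[i] &
          time_s < starts[i] + protocol$pulse_length_s
        tt <- time_s[on] - starts[i]
        current[on] <- A * scales[i] * exp(-k_obs * tt)
      }
    }
  }
  if (noise_sigma > 0 && c_uM > 0)
    current <- current + with_seed(seed, rnorm(length(current),
                                               sd = noise_sigma * A))
  structure(list(time_s = time_s, current = current, protocol = protocol,
                 seed = seed, k_obs = k_obs, amplitudes = amplitudes),
            class = "current_trace_set")
}

#' @export
print.current_trace_set <- function(x, ...) {
  cat(sprintf("<current_trace_set> mode %s, %s at %g uM, %d samples over %.3g s\n",
              x$protocol$mode, x$protocol$compound,
              x$protocol$concentration_uM, length(x$time_s),
              max(x$time_s)))
  invisible(x)
}

#' Noisy recovery amplitudes with known dissociation rate
#'
#' Convenience generator for the recovery fits: fractional amplitudes
#' `1 - exp(-K t)` at the given wash times plus Gaussian noise.
#'
#' @param K dissociation rate, 1/s
#' @param wash_times_s wash intervals, s
#' @param noise_sigma additive Gaussian noise (fraction of full recovery)
#' @param seed integer seed
#' @return numeric vector of fractional amplitudes
#' @export
simulate_recovery_amplitudes <- function(K, wash_times_s, noise_sigma = 0,
                                         seed = NULL) {
  assert_scalar_num(K, "K", positive = TRUE)
  y <- 1 - exp(-K * wash_times_s)
  if (noise_sigma > 0)
    y <- y + with_seed(seed, rnorm(length(y), sd = noise_sigma))
  y
}

#' Write / read a current trace as delimited text plus a YAML sidecar
#'
#' The trace itself is two-column tab-delimited text (`time_s`, `current`);
#' the protocol block is written next to it as `<path>.yml`.
#'
#' @param x current_trace_set
#' @param path output path for the trace table
#' @return `path`, invisibly (writer); current_trace_set (reader)
#' @export
write_current_trace <- function(x, path) {
  write.table(data.frame(time_s = x$time_s, current = x$current), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(unclass(x$protocol), list(seed = x$seed)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_current_trace
#' @export
read_current_trace <- function(path) {
  df <- read.delim(path, sep = "\t")
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  seed <- meta$seed
  meta$seed <- NULL
  proto <- do.call(patch_protocol, meta[names(meta) %in% names(formals(patch_protocol))])
  structure(list(time_s = df$time_s, current = df$current, protocol = proto,
                 seed = seed, k_obs = NULL, amplitudes = NULL),
            class = "current_trace_set")
}
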