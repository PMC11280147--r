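#' Construct a flow waveform
#'
#' One cardiac cycle of flow sampled on the endpoint-exclusive uniform grid
#' t = 0, dt, ..., (n-1)*dt with n = cycle_length / dt. The waveform is
#' understood periodically: the value at t = cycle_length equals the value at
#' t = 0.
#'
#' @param flow Numeric vector of flow samples (L/min/m^2), length n >= 2.
#' @param cycle_length Cardiac cycle length l in seconds.
#' @return A `flow_waveform`: a tibble with columns `time` (s) and `flow`,
#'   carrying `cycle_length` and `dt` attributes.
#' @export
#' @examples
#' w <- flow_waveform(c(1, 3, 2, 0.5), cycle_length = 0.8)
#' time_average(w)
flow_waveform <- function(flow, cycle_length) {
  n <- length(flow)
  if (n < 2L) stop("a flow waveform needs at least 2 samples", call. = FALSE)
  if (!is.numeric(cycle_length) || length(cycle_length) != 1L ||
      !is.finite(cycle_length) || cycle_length <= 0) {
    stop("cycle_length must be a positive finite scalar", call. = FALSE)
  }
  if (any(!is.finite(flow))) {
    stop("flow samples must all be finite", call. = FALSE)
  }
  dt <- cycle_length / n
  out <- tibble::tibble(time = (seq_len(n) - 1) * dt, flow = as.numeric(flow))
  structure(out,
            cycle_length = cycle_length, dt = dt,
            class = c("flow_waveform", class(out)))
}

#' @rdname flow_waveform
#' @param w A `flow_waveform`.
#' @export
cycle_length <- function(w) attr(w, "cycle_length")

#' Synthesize a raised-sinusoid inlet waveform
#'
#' Emulates a cycle-periodic phase-contrast CMR flow curve as
#' `mean * (1 + pulsatility * sin(2*pi*t/l + phase))`. Over the
#' endpoint-exclusive uniform grid a full sinusoidal period averages exactly
#' to `mean`, so the prescribed cycle-averaged flow is honoured to machine
#' precision.
#'
#' @param mean Cycle-averaged flow, L/min/m^2 (> 0).
#' @param pulsatility Fractional amplitude in `[0, 1)`; values >= 1 would
#'   allow non-positive instantaneous inlet flow and are rejected.
#' @param cycle_length Cycle length l, seconds. Default 0.8 s.
#' @param dt Timestep, seconds. Default 0.001 s.
#' @param phase Phase offset, radians.
#' @return A [flow_waveform()].
#' @export
#' @examples
#' w <- synth_inlet_waveform(2, pulsatility = 0.3)
#' all.equal(time_average(w), 2)
synth_inlet_waveform <- function(mean, pulsatility = 0.3, cycle_length = 0.8,
                                 dt = 0.001, phase = 0) {
  if (!is.finite(mean) || mean <= 0) {
    stop("mean flow must be > 0", call. = FALSE)
  }
  if (!is.finite(pulsatility) || pulsatility < 0 || pulsatility >= 1) {
    stop("pulsatility must lie in [0, 1): values >= 1 allow non-positive flow",
         call. = FALSE)
  }
  n <- round(cycle_length / dt)
  if (n < 2L) stop("dt too coarse: fewer than 2 samples per cycle", call. = FALSE)
  t <- (seq_len(n) - 1) * (cycle_length / n)
  flow_waveform(mean * (1 + pulsatility * sin(2 * pi * t / cycle_length + phase)),
                cycle_length)
}

#' Resample a waveform by linear interpolation
#'
#' Re-grids one cycle onto a new uniform timestep. Values at coincident grid
#' points are preserved; between grid points the piecewise-linear interpolant
#' is used, with periodic wrap between t = l - dt and t = l (the final
#' segment interpolates toward the t = 0 sample).
#'
#' @param w A [flow_waveform()].
#' @param dt_new Target timestep, seconds; `0 < dt_new <= l/2`. The realized
#'   timestep is `l / round(l / dt_new)` so the new grid tiles the cycle
#'   exactly.
#' @return A [flow_waveform()] on the new grid.
#' @export
resample_linear <- function(w, dt_new) {
  l <- cycle_length(w)
  if (!is.finite(dt_new) || dt_new <= 0) {
    stop("dt_new must be > 0", call. = FALSE)
  }
  if (dt_new > l / 2) {
    stop("dt_new must be <= cycle_length / 2", call. = FALSE)
  }
  n_new <- round(l / dt_new)
  t_new <- (seq_len(n_new) - 1) * (l / n_new)
  flow_waveform(eval_waveform(w, t_new), l)
}

# Periodic piecewise-linear evaluation of one cycle at arbitrary times.
eval_waveform <- function(w, t) {
  l <- cycle_length(w)
  stats::approx(x = c(w$time, l), y = c(w$flow, w$flow[1L]),
                xout = t %% l, method = "linear", ties = "ordered")$y
}

#' Time average of a waveform over one cardiac cycle
#'
#' The arithmetic mean of the n samples on the uniform grid — the (1/n) sum
#' discretization used throughout flow/pressure target matching.
#'
#' @param w A [flow_waveform()].
#' @return Scalar cycle-averaged value.
#' @export
time_average <- function(w) {
  mean(w$flow)
}

#' Read / write a single-cycle waveform CSV
#'
#' Two columns, `time_s` and `flow_lpm_m2`, one cardiac cycle on a uniform
#' grid. Values round-trip at 12 significant digits.
#'
#' @param path CSV path.
#' @return `read_waveform_csv()`: a [flow_waveform()];
#'   `write_waveform_csv()`: `path`, invisibly.
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "flow_lpm_m2")
  if (!all(need %in% names(d))) {
    stop("waveform CSV must have columns time_s, flow_lpm_m2", call. = FALSE)
  }
  n <- nrow(d)
  dt <- if (n > 1) d$time_s[2L] - d$time_s[1L] else stop("waveform too short")
  flow_waveform(d$flow_lpm_m2, cycle_length = dt * n)
}

#' @rdname read_waveform_csv
#' @param w A [flow_waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  d <- data.frame(time_s = signif(w$time, 12), flow_lpm_m2 = signif(w$flow, 12))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
autoplot.flow_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$flow)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = time_average(object), linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "flow (L/min/m²)")
}
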