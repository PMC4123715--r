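# Synthetic inside-out patch generator.  Produces voltage-clamp sweeps with
# the structure of equilibrium heat-activation recordings: step and ramp
# command protocols, a slow linear temperature ramp registered simultaneously
# with the current, linear leak, Nernst reversal set by the bath/pipette
# solutions, a single-channel conductance with its own temperature
# coefficient, and additive Gaussian current noise.  Gating is evaluated at
# equilibrium at every sample; no kinetics are simulated.

#' Nernst reversal potential
#'
#' @param conc_in,conc_out Intracellular / extracellular concentration, mM.
#' @param valence Ion valence (integer, nonzero).
#' @param temp Temperature, degrees C (vectorised).
#' @return Reversal potential, mV: \eqn{(RT/zF)\ln(out/in)}.
#' @examples
#' nernst_reversal(130, 130, 1, 24)  # symmetric: 0 mV
#' nernst_reversal(130, 4, 1, 24)    # K+ gradient: about -89 mV
#' @export
nernst_reversal <- function(conc_in, conc_out, valence = 1, temp = 24) {
  if (any(conc_in <= 0) || any(conc_out <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (valence == 0) stop("valence must be nonzero", call. = FALSE)
  rt_over_f_mv(temp) / valence * log(conc_out / conc_in)
}

#' Channel population specification for synthesis
#'
#' @param model Gating model: `allosteric_params` or `thermo_transition`
#'   (e.g. from [channel_preset()]).
#' @param n_channels Number of channels in the patch (>= 1).
#' @param gamma_ref Single-channel conductance at `22` degrees C, pS.
#' @param gamma_q10 Temperature coefficient of the single-channel
#'   conductance (default 1.5).
#' @param ion_in,ion_out Permeant-ion concentrations, mM (monovalent).
#' @param csi Optional list `list(v_half=, q=)` describing steady-state
#'   closed-state-inactivation availability; defaults to the `csi`
#'   attribute of `model` if present.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(model, n_channels = 100, gamma_ref = 10,
                         gamma_q10 = 1.5, ion_in = 130, ion_out = 130,
                         csi = attr(model, "csi")) {
  if (!is_gating_model(model)) {
    stop("model must be an allosteric_params or thermo_transition", call. = FALSE)
  }
  stopifnot(n_channels >= 1, gamma_ref > 0, gamma_q10 > 0,
            ion_in > 0, ion_out > 0)
  structure(list(model = model, n_channels = n_channels, gamma_ref = gamma_ref,
                 gamma_q10 = gamma_q10, ion_in = ion_in, ion_out = ion_out,
                 csi = csi, channel_name = attr(model, "channel_name")),
            class = "channel_spec")
}

#' Single-channel conductance at temperature
#' @param spec A `channel_spec`.
#' @param temp Temperature, degrees C.
#' @return Conductance in pS: `gamma_ref * gamma_q10^((temp - 22)/10)`.
#' @export
gamma_at <- function(spec, temp) {
  spec$gamma_ref * spec$gamma_q10^((temp - 22) / 10)
}

#' Voltage-protocol constructors
#'
#' A protocol is an ordered list of command segments (`hold`, `step` or
#' `ramp`), a sampling interval and a temperature track.  `hold` and `step`
#' are constant-voltage segments (they differ only in intent/labelling);
#' `ramp` interpolates linearly from `v_start` to `v_end`.
#'
#' @param kind One of "hold", "step", "ramp".
#' @param v_start Command voltage at segment start, mV.
#' @param duration_ms Segment duration, ms (> 0).
#' @param v_end Command voltage at segment end, mV (defaults to `v_start`).
#' @param label Optional segment label (e.g. "test", "P1", "P2", "P3")
#'   used by the analysis stage to locate measurement windows.
#' @return `proto_segment`: one-row data.frame.
#' @export
proto_segment <- function(kind = c("hold", "step", "ramp"), v_start,
                          duration_ms, v_end = v_start, label = NA_character_) {
  kind <- match.arg(kind)
  check_finite(v_start, v_end, duration_ms)
  if (duration_ms <= 0) stop("segment duration must be positive", call. = FALSE)
  data.frame(kind = kind, v_start = v_start, v_end = v_end,
             duration_ms = duration_ms, label = label)
}

#' @rdname proto_segment
#' @param segments data.frame of segments (rbind of [proto_segment()] rows).
#' @param sample_interval_ms Sampling interval, ms (default 0.1, i.e. 10 kHz).
#' @param temp_start Temperature at sweep start, degrees C.
#' @param temp_rate Heating rate, degrees C per second (0 = constant
#'   temperature; the recordings emulated use about 0.3).
#' @param temp_max Ceiling on the temperature track, degrees C.
#' @param temp_delay_s Time before the ramp starts, s (temperature is held
#'   at `temp_start` until then).
#' @param id Protocol identifier string carried into sweep metadata.
#' @return `patch_protocol`: list with the segment table and track settings.
#' @export
patch_protocol <- function(segments, sample_interval_ms = 0.1,
                           temp_start = 24, temp_rate = 0, temp_max = Inf,
                           temp_delay_s = 0, id = "custom") {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1,
            sample_interval_ms > 0)
  structure(list(segments = segments, sample_interval_ms = sample_interval_ms,
                 temp_start = temp_start, temp_rate = temp_rate,
                 temp_max = temp_max, temp_delay_s = temp_delay_s, id = id),
            class = "patch_protocol")
}

# Sample times, commanded voltage and segment index for a protocol.  Each
# segment contributes round(duration/dt) samples; the last sample of a ramp
# lands exactly on v_end so commanded endpoints are reproduced exactly.
protocol_trace <- function(protocol) {
  dt <- protocol$sample_interval_ms
  seg <- protocol$segments
  n_per <- pmax(1L, as.integer(round(seg$duration_ms / dt)))
  v <- numeric(0); si <- integer(0)
  for (k in seq_len(nrow(seg))) {
    n <- n_per[k]
    vk <- if (seg$kind[k] == "ramp" && n > 1) {
      seq(seg$v_start[k], seg$v_end[k], length.out = n)
    } else {
      rep(if (seg$kind[k] == "ramp") seg$v_end[k] else seg$v_start[k], n)
    }
    v <- c(v, vk); si <- c(si, rep(k, n))
  }
  t_s <- (seq_along(v) - 1) * dt / 1000
  t_heat <- pmax(t_s - (protocol$temp_delay_s %||% 0), 0)
  temp <- pmin(protocol$temp_start + protocol$temp_rate * t_heat, protocol$temp_max)
  seg_t1 <- cumsum(n_per) * dt / 1000
  seg_t0 <- c(0, seg_t1[-length(seg_t1)])
  list(time_s = t_s, voltage_mV = v, temperature_C = temp, segment = si,
       segment_table = cbind(seg, t_start_s = seg_t0, t_end_s = seg_t1))
}

# Run code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

new_sweep_record <- function(data, meta) {
  stopifnot(all(c("time_s", "voltage_mV", "current_pA", "temperature_C")
                %in% names(data)))
  if (any(diff(data$time_s) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  structure(list(data = data, meta = meta), class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  d <- x$data
  cat(sprintf("<sweep_record> %d samples, %.3g s, V in [%g, %g] mV, T in [%.3g, %.3g] C\n",
              nrow(d), max(d$time_s), min(d$voltage_mV), max(d$voltage_mV),
              min(d$temperature_C), max(d$temperature_C)))
  cat(sprintf("  channel=%s protocol=%s seed=%s leak=%s nS\n",
              x$meta$channel %||% "?", x$meta$protocol %||% "?",
              format(x$meta$seed), format(x$meta$leak_nS)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize one voltage-clamp sweep
#'
#' At every sample the current is the equilibrium macroscopic channel
#' current plus linear leak plus Gaussian noise:
#' \deqn{I = N P_o(V,T)\,\gamma(T)\,(V - V_{rev}) + g_{leak} V + \epsilon,}
#' with \eqn{\gamma(T) = \gamma_{ref}\,{Q_{10,\gamma}}^{(T-22)/10}} and
#' \eqn{V_{rev}} from the Nernst relation at the sample temperature.  The
#' leak reverses at 0 mV.  Identical seed and configuration give a
#' byte-identical record.
#'
#' @param spec A [channel_spec()].
#' @param protocol A [patch_protocol()].
#' @param leak_g Leak conductance, nS.
#' @param noise_sd Current noise standard deviation, pA.
#' @param seed Integer RNG seed (required for reproducibility; `NULL` uses
#'   the current RNG state).
#' @param po_scale Internal per-sample open-probability scaling (used by the
#'   closed-state-inactivation protocol); recycled to the sample count.
#' @return A `sweep_record`: `$data` (data.frame `time_s`, `voltage_mV`,
#'   `current_pA`, `temperature_C`) and `$meta` (channel, seed, protocol id,
#'   leak conductance, segment table).
#' @export
synthesize_sweep <- function(spec, protocol, leak_g = 0, noise_sd = 0.5,
                             seed = 0, po_scale = 1) {
  stopifnot(inherits(spec, "channel_spec"), inherits(protocol, "patch_protocol"))
  tr <- protocol_trace(protocol)
  po <- open_probability(spec$model, tr$voltage_mV, tr$temperature_C)
  po <- po * rep_len(po_scale, length(po))
  v_rev <- nernst_reversal(spec$ion_in, spec$ion_out, 1, tr$temperature_C)
  gam <- gamma_at(spec, tr$temperature_C)
  i_chan <- spec$n_channels * po * gam * (tr$voltage_mV - v_rev) / 1000  # pA
  i_leak <- leak_g * tr$voltage_mV                                       # pA
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(po), 0, noise_sd))
  } else 0
  data <- data.frame(time_s = tr$time_s, voltage_mV = tr$voltage_mV,
                     current_pA = i_chan + i_leak + noise,
                     temperature_C = tr$temperature_C)
  new_sweep_record(data, meta = list(
    channel = spec$channel_name %||% "synthetic", seed = seed,
    protocol = protocol$id, leak_nS = leak_g,
    segments = tr$segment_table))
}

#' Step-family protocol for G-V determination
#'
#' Holding at a deep hyperpolarized voltage, one test step per sweep, then
#' back to holding.  Returns one protocol per test voltage; the test segment
#' is labelled `"test"`.
#'
#' @param test_voltages Test-step voltages, mV.
#' @param v_hold Holding voltage, mV (default -100).
#' @param hold_ms,step_ms Segment durations, ms.
#' @param ... Passed to [patch_protocol()] (sampling, temperature track).
#' @return List of `patch_protocol`, one per test voltage.
#' @export
gv_step_protocols <- function(test_voltages, v_hold = -100, hold_ms = 50,
                              step_ms = 100, ...) {
  lapply(test_voltages, function(vt) {
    segs <- rbind(proto_segment("hold", v_hold, hold_ms, label = "holding"),
                  proto_segment("step", vt, step_ms, label = "test"),
                  proto_segment("hold", v_hold, hold_ms / 2, label = "tail"))
    patch_protocol(segs, id = sprintf("gv_step_%+gmV", vt), ...)
  })
}

#' Heat-activation protocol: hold at a fixed voltage while heating
#'
#' @param v_test Test voltage, mV.
#' @param v_hold Holding voltage, mV.
#' @param t_start,t_end Temperature ramp endpoints, degrees C.
#' @param rate Heating rate, degrees C per second (default 0.3).
#' @param hold_ms Pre-heating holding duration, ms.
#' @param sample_interval_ms Sampling interval, ms.
#' @return A `patch_protocol` whose test segment spans the heating ramp.
#' @export
heat_hold_protocol <- function(v_test, v_hold = -100, t_start = 24,
                               t_end = 48, rate = 0.3, hold_ms = 2000,
                               sample_interval_ms = 1) {
  ramp_ms <- (t_end - t_start) / rate * 1000
  segs <- rbind(proto_segment("hold", v_hold, hold_ms, label = "holding"),
                proto_segment("step", v_test, ramp_ms + hold_ms, label = "test"))
  # temperature is held at t_start through the holding segment and the first
  # hold_ms of the test segment (pre-heating baseline), then ramps to t_end
  patch_protocol(segs, sample_interval_ms = sample_interval_ms,
                 temp_start = t_start, temp_rate = rate, temp_max = t_end,
                 temp_delay_s = 2 * hold_ms / 1000,
                 id = sprintf("heat_hold_%+gmV", v_test))
}

#' Voltage-ramp protocol
#'
#' @param v_from,v_to Ramp endpoints, mV.
#' @param ramp_ms Ramp duration, ms (the recordings emulated use 200 ms and
#'   1 s variants).
#' @param v_hold Holding voltage, mV.
#' @param hold_ms Holding duration, ms.
#' @param ... Passed to [patch_protocol()].
#' @return A `patch_protocol` with the ramp segment labelled `"test"`.
#' @export
ramp_protocol <- function(v_from = -100, v_to = 50, ramp_ms = 200,
                          v_hold = -100, hold_ms = 50, ...) {
  segs <- rbind(proto_segment("hold", v_hold, hold_ms, label = "holding"),
                proto_segment("ramp", v_from, ramp_ms, v_end = v_to, label = "test"))
  patch_protocol(segs, id = sprintf("ramp_%g_to_%gmV_%gms", v_from, v_to, ramp_ms), ...)
}

#' Synthesize a closed-state-inactivation triple-pulse family
#'
#' Emulates the P1/P2/P3 protocol: a test pulse (P1), a long conditioning
#' pulse (P2) at a varying voltage, and an identical second test pulse (P3).
#' Gating is equilibrated, so the conditioning effect is applied as the
#' steady-state availability at the P2 voltage scaling the P3 open
#' probability (P1 is approached from deep holding, availability ~ 1).
#' Channels without a configured `csi` availability give P3/P1 = 1.
#'
#' @param spec A [channel_spec()]; its `csi` field (v_half mV, q e0) defines
#'   the availability curve.
#' @param p2_voltages Conditioning voltages, mV.
#' @param p2_duration_s Conditioning duration, s (default 10).
#' @param v_test Test-pulse voltage, mV.
#' @param v_hold Holding voltage, mV.
#' @param test_ms Test-pulse duration, ms.
#' @param temp Bath temperature, degrees C.
#' @param sample_interval_ms Sampling interval, ms.
#' @param leak_g,noise_sd,seed As in [synthesize_sweep()]; each sweep uses
#'   `seed + index - 1`.
#' @return List of `sweep_record`, one per conditioning voltage, with
#'   segments labelled P1/P2/P3 and `meta$p2_voltage` set.
#' @export
synthesize_csi_family <- function(spec, p2_voltages, p2_duration_s = 10,
                                  v_test = 20, v_hold = -100, test_ms = 50,
                                  temp = 24, sample_interval_ms = 1,
                                  leak_g = 0, noise_sd = 0.5, seed = 0) {
  stopifnot(inherits(spec, "channel_spec"), p2_duration_s > 0)
  lapply(seq_along(p2_voltages), function(i) {
    v2 <- p2_voltages[i]
    avail <- if (is.null(spec$csi)) 1 else {
      csi_availability(v2, spec$csi$v_half, spec$csi$q, temp)
    }
    segs <- rbind(
      proto_segment("hold", v_hold, test_ms, label = "holding"),
      proto_segment("step", v_test, test_ms, label = "P1"),
      proto_segment("step", v2, p2_duration_s * 1000, label = "P2"),
      proto_segment("step", v_test, test_ms, label = "P3"),
      proto_segment("hold", v_hold, test_ms / 2, label = "tail"))
    proto <- patch_protocol(segs, sample_interval_ms = sample_interval_ms,
                            temp_start = temp,
                            id = sprintf("csi_P2_%+gmV", v2))
    tr <- protocol_trace(proto)
    scale <- ifelse(tr$segment == 4L, avail, 1)
    sw <- synthesize_sweep(spec, proto, leak_g = leak_g, noise_sd = noise_sd,
                           seed = if (is.null(seed)) NULL else seed + i - 1,
                           po_scale = scale)
    sw$meta$p2_voltage <- v2
    sw
  })
}
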