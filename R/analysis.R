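# Measurement pipeline: leak subtraction, G-V extraction and single-Boltzmann
# fitting, single-channel-conductance temperature correction, Q10 measurement
# with activation-threshold detection, voltage-resolved Q10 profiles,
# Van't Hoff enthalpy/entropy estimation, gating free-energy shifts, and
# closed-state-inactivation availability curves.

#' Conductance-voltage data container
#'
#' @param voltages Voltages, mV.
#' @param conductances Leak-subtracted conductances, nS (same length).
#' @param temperature Recording temperature, degrees C.
#' @param normalized Logical: have conductances been divided by G_max?
#' @return A `gv_curve` data.frame with columns `voltage_mV`,
#'   `conductance_nS` and attributes `temperature`, `normalized`.
#' @export
gv_curve <- function(voltages, conductances, temperature = NA_real_,
                     normalized = FALSE) {
  stopifnot(length(voltages) == length(conductances))
  check_finite(voltages)
  structure(data.frame(voltage_mV = voltages, conductance_nS = conductances),
            temperature = temperature, normalized = normalized,
            class = c("gv_curve", "data.frame"))
}

# samples in the holding segment at the leak reference voltage
.leak_samples <- function(sweep, leak_ref_v, tol = 0.25) {
  seg <- sweep$meta$segments
  d <- sweep$data
  idx <- which(abs(d$voltage_mV - leak_ref_v) < tol)
  if (!is.null(seg)) {
    hold <- seg[seg$kind == "hold" & abs(seg$v_start - leak_ref_v) < tol, , drop = FALSE]
    if (nrow(hold) > 0) {
      keep <- rep(FALSE, nrow(d))
      for (k in seq_len(nrow(hold))) {
        keep <- keep | (d$time_s >= hold$t_start_s[k] & d$time_s < hold$t_end_s[k])
      }
      idx <- which(keep & abs(d$voltage_mV - leak_ref_v) < tol)
    }
  }
  idx
}

#' Subtract linear leak from a sweep
#'
#' The leak conductance is the mean current at the reference voltage
#' (holding segment, channels closed) divided by that voltage; the leak
#' current `g_leak * V` is removed at every sample.  The estimated leak is
#' recorded in the output metadata as `leak_nS_estimated`.
#'
#' @param sweep A `sweep_record`.
#' @param leak_ref_v Reference voltage, mV (default -100); must be nonzero
#'   and visited by a holding segment of the protocol.
#' @return The sweep with leak-free current.
#' @export
subtract_leak <- function(sweep, leak_ref_v = -100) {
  stopifnot(inherits(sweep, "sweep_record"))
  if (leak_ref_v == 0) stop("leak reference voltage must be nonzero", call. = FALSE)
  idx <- .leak_samples(sweep, leak_ref_v)
  if (length(idx) == 0) {
    stop(sprintf(paste0("no holding samples at %g mV: the protocol needs a ",
                        "holding segment at the leak reference voltage"),
                 leak_ref_v), call. = FALSE)
  }
  g_leak <- mean(sweep$data$current_pA[idx]) / leak_ref_v  # pA/mV = nS
  sweep$data$current_pA <- sweep$data$current_pA - g_leak * sweep$data$voltage_mV
  sweep$meta$leak_nS_estimated <- g_leak
  sweep
}

# mean of x over a fractional window of a labelled segment
.segment_window <- function(sweep, label, window = c(0.5, 0.95)) {
  seg <- sweep$meta$segments
  if (is.null(seg)) stop("sweep carries no segment table", call. = FALSE)
  row <- seg[!is.na(seg$label) & seg$label == label, , drop = FALSE]
  if (nrow(row) == 0) stop(sprintf("no segment labelled '%s'", label), call. = FALSE)
  t0 <- row$t_start_s[1]; t1 <- row$t_end_s[1]
  lo <- t0 + window[1] * (t1 - t0); hi <- t0 + window[2] * (t1 - t0)
  which(sweep$data$time_s >= lo & sweep$data$time_s <= hi)
}

#' Extract a G-V curve from a family of step sweeps
#'
#' For each leak-subtracted sweep, the conductance at its test voltage is
#' the mean current in the measurement window divided by the driving force
#' `V - v_rev`.  Steps at the reversal potential are excluded with a
#' warning (conductance undefined there).
#'
#' @param step_sweeps List of `sweep_record`s, each with a segment labelled
#'   `"test"` (see [gv_step_protocols()]).
#' @param v_rev Reversal potential, mV.
#' @param window Fractional window within the test step over which current
#'   is averaged (inside the equilibrated portion).
#' @return A [gv_curve()] at the mean in-window temperature.
#' @export
extract_gv <- function(step_sweeps, v_rev = 0, window = c(0.5, 0.95)) {
  if (inherits(step_sweeps, "sweep_record")) step_sweeps <- list(step_sweeps)
  if (window[2] <= window[1]) stop("empty measurement window", call. = FALSE)
  rows <- lapply(step_sweeps, function(sw) {
    idx <- .segment_window(sw, "test", window)
    v <- stats::median(sw$data$voltage_mV[idx])
    if (abs(v - v_rev) < 1e-9) {
      warning(sprintf("step at %g mV equals the reversal potential; excluded", v))
      return(NULL)
    }
    data.frame(voltage_mV = v,
               conductance_nS = mean(sw$data$current_pA[idx]) / (v - v_rev),
               temperature_C = mean(sw$data$temperature_C[idx]))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rows <- rows[order(rows$voltage_mV), ]
  gv_curve(rows$voltage_mV, rows$conductance_nS,
           temperature = mean(rows$temperature_C))
}

#' Extract a G-V curve from a single voltage-ramp sweep
#'
#' Instantaneous conductance `I/(V - v_rev)` at every ramp sample,
#' voltage-binned (2 mV default).
#'
#' @param sweep Leak-subtracted `sweep_record` containing a ramp segment
#'   labelled `"test"`.
#' @param v_rev Reversal potential, mV.
#' @param bin_mV Voltage bin width, mV.
#' @param guard_mV Samples within this distance of `v_rev` are dropped
#'   (driving force too small for a stable quotient).
#' @return A [gv_curve()] on the bin centres.
#' @export
extract_gv_ramp <- function(sweep, v_rev = 0, bin_mV = 2, guard_mV = 5) {
  idx <- .segment_window(sweep, "test", c(0, 1))
  d <- sweep$data[idx, ]
  d <- d[abs(d$voltage_mV - v_rev) >= guard_mV, ]
  if (nrow(d) == 0) stop("no ramp samples outside the reversal guard band", call. = FALSE)
  bin <- round(d$voltage_mV / bin_mV) * bin_mV
  g <- tapply(d$current_pA / (d$voltage_mV - v_rev), bin, mean)
  tm <- tapply(d$temperature_C, bin, mean)
  v <- as.numeric(names(g))
  o <- order(v)
  gv_curve(v[o], as.numeric(g)[o], temperature = mean(tm))
}

#' Fit a single-Boltzmann function to a G-V curve
#'
#' Least-squares fit of \eqn{G = G_{max}/(1+\exp(-qF(V-V_{1/2})/(RT)))}
#' with all three parameters free.  Initialization is deterministic:
#' `v_half` from linear interpolation of the half-maximum crossing, `q`
#' from the maximal slope of the normalized curve
#' (\eqn{q = 4 (RT/F) \max dG/dV}), `g_max` from the top-plateau mean.
#' The fit is run twice, the second pass on conductances normalized by the
#' first-pass `g_max`.  Negative conductances are clipped to zero for
#' fitting.  Non-convergence (or a degenerate, transition-free curve)
#' returns a flagged result carrying the initialization values.
#'
#' @param gv A [gv_curve()] (>= 4 points spanning the transition).
#' @return `boltzmann_fit`: list with `v_half` (mV), `q` (e0), `g_max`
#'   (nS), `residual` (sum of squared residuals on normalized conductance),
#'   `converged`, `status`, `n`, `temperature`.
#' @export
fit_boltzmann <- function(gv) {
  stopifnot(inherits(gv, "gv_curve"))
  v <- gv$voltage_mV
  g <- pmax(gv$conductance_nS, 0)
  if (length(v) < 4) stop("need at least 4 G-V points", call. = FALSE)
  temp <- attr(gv, "temperature")
  if (!is.finite(temp)) temp <- 24
  kT <- rt_over_f_mv(temp)

  out <- function(vh, q, gm, res, ok, status) {
    structure(list(v_half = vh, q = q, g_max = gm, residual = res,
                   converged = ok, status = status, n = length(v),
                   temperature = temp), class = "boltzmann_fit")
  }

  if (diff(range(g)) <= 1e-9 * max(abs(g), 1e-12)) {
    return(out(NA_real_, NA_real_, max(g), NA_real_, FALSE, "no-transition"))
  }

  # deterministic initialization
  n_top <- max(2L, ceiling(length(g) * 0.2))
  gm0 <- mean(sort(g, decreasing = TRUE)[seq_len(n_top)])
  gn <- g / gm0
  above <- which(gn >= 0.5)
  vh0 <- if (length(above) == 0 || above[1] == 1) {
    v[which.min(abs(gn - 0.5))]
  } else {
    i <- above[1]
    v[i - 1] + (0.5 - gn[i - 1]) / (gn[i] - gn[i - 1]) * (v[i] - v[i - 1])
  }
  slope <- max(diff(gn) / diff(v))
  q0 <- max(4 * kT * slope, 0.05)

  one_pass <- function(gdat, gm_init) {
    df <- data.frame(v = v, g = gdat)
    tryCatch(
      minpack.lm::nlsLM(
        g ~ gm * stats::plogis(q * (v - vh) / kT), data = df,
        start = list(gm = gm_init, vh = vh0, q = q0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  f1 <- one_pass(g, gm0)
  if (is.null(f1)) return(out(vh0, q0, gm0, NA_real_, FALSE, "no-convergence"))
  gm1 <- stats::coef(f1)[["gm"]]
  if (gm1 <= 0) return(out(vh0, q0, gm0, NA_real_, FALSE, "no-convergence"))
  f2 <- one_pass(g / gm1, 1)
  if (is.null(f2)) f2 <- f1
  co <- stats::coef(f2)
  gm_final <- if (identical(f2, f1)) co[["gm"]] else gm1 * co[["gm"]]
  pred_n <- co[["gm"]] * stats::plogis(co[["q"]] * (v - co[["vh"]]) / kT)
  res_n <- if (identical(f2, f1)) sum((g / gm1 - pred_n / gm1)^2) else sum((g / gm1 - pred_n)^2)
  out(co[["vh"]], co[["q"]], gm_final, res_n, TRUE, "ok")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("<boltzmann_fit> V1/2 = %.4g mV, q = %.3g e0, Gmax = %.4g nS (n = %d, SSR = %.3g)\n",
                x$v_half, x$q, x$g_max, x$n, x$residual))
  } else {
    cat(sprintf("<boltzmann_fit> FAILED (%s); init V1/2 = %.4g mV, q = %.3g e0\n",
                x$status, x$v_half, x$q))
  }
  invisible(x)
}

#' Predict normalized open fraction from a Boltzmann fit
#' @param object A `boltzmann_fit`.
#' @param v Voltages, mV.
#' @param ... Unused.
#' @return Predicted G/Gmax; exactly 0.5 at `v = v_half`.
#' @export
predict.boltzmann_fit <- function(object, v, ...) {
  boltzmann_open_fraction(v, object$v_half, object$q, object$temperature)
}

#' Correct current for the single-channel conductance temperature dependence
#'
#' Divides the measured current by the conductance factor
#' \eqn{{Q_{10,\gamma}}^{(T - T_{ref})/10}} so that amplitudes at different
#' temperatures are expressed as if recorded at the reference temperature.
#'
#' @param current Current, pA (vectorised).
#' @param temp Temperature at which it was recorded, degrees C (vectorised).
#' @param gamma_q10 Single-channel conductance temperature coefficient
#'   (default 1.5).
#' @param t_ref Reference temperature, degrees C (default 22).
#' @return Corrected current, pA.
#' @export
correct_conductance <- function(current, temp, gamma_q10 = 1.5, t_ref = 22) {
  current / gamma_q10^((temp - t_ref) / 10)
}

#' Measure Q10 from a heating sweep at fixed voltage
#'
#' Detects the activation threshold temperature T1 as the first point (on a
#' temperature-binned, 0.5 degree-smoothed trace) at which the current
#' departs from the pre-heating baseline by more than 3 baseline standard
#' deviations; the current amplitude I1 is read there and I2 at a
#' temperature `dt` degrees higher, and
#' \eqn{Q_{10} = (I_2/I_1)^{10/(T_2-T_1)}}.  Amplitudes and the reported
#' T1/T2 are window means over `window_C`-wide temperature windows, so the
#' identity between the reported fields holds exactly.
#'
#' @param sweep Leak-subtracted `sweep_record` with a heating segment
#'   labelled `"test"` at constant voltage.  Apply [correct_conductance()]
#'   to `sweep$data$current_pA` first if conductance-corrected Q10 is
#'   wanted.
#' @param special_dt Temperature interval, degrees C (default 10; channels
#'   that inactivate on further heating use 5).
#' @param smooth_C Temperature bin width for threshold detection, degrees C.
#' @param window_C Width of the amplitude-averaging window, degrees C (may
#'   be made arbitrarily small for point sampling).
#' @return `q10_measurement`: list with `i1`, `i2` (pA), `t1`, `t2`
#'   (degrees C), `q10`, `voltage` (mV), `status` ("ok" or
#'   "no-activation").
#' @export
measure_q10 <- function(sweep, special_dt = NULL, smooth_C = 0.5,
                        window_C = 0.5) {
  stopifnot(inherits(sweep, "sweep_record"))
  dt <- special_dt %||% 10
  idx <- .segment_window(sweep, "test", c(0, 1))
  d <- sweep$data[idx, ]
  v_test <- stats::median(d$voltage_mV)

  fail <- function(status) {
    structure(list(i1 = NA_real_, i2 = NA_real_, t1 = NA_real_, t2 = NA_real_,
                   q10 = NA_real_, voltage = v_test, status = status),
              class = "q10_measurement")
  }
  t_rng <- range(d$temperature_C)
  if (diff(t_rng) < dt) return(fail("no-activation"))

  # pre-heating baseline: samples still within half a bin of the start temp
  base <- d$temperature_C <= t_rng[1] + smooth_C / 2
  mu0 <- mean(d$current_pA[base])
  sd0 <- max(stats::sd(d$current_pA[base]), 1e-9)
  if (!is.finite(sd0)) sd0 <- 1e-9

  bin <- factor(floor((d$temperature_C - t_rng[1]) / smooth_C))
  bin <- factor(bin, levels = levels(bin)[order(as.numeric(levels(bin)))])
  bmean <- tapply(d$current_pA, bin, mean)
  btemp <- tapply(d$temperature_C, bin, mean)
  dir <- sign(bmean[length(bmean)] - mu0)
  if (dir == 0) dir <- 1
  hit <- which(dir * (bmean - mu0) > 3 * sd0)
  hit <- hit[hit > 1]  # baseline bin itself cannot be the threshold
  if (length(hit) == 0) return(fail("no-activation"))
  t1_nominal <- btemp[[hit[1]]]
  if (t_rng[2] < t1_nominal + dt) return(fail("no-activation"))

  amp_at <- function(t_target) {
    w <- abs(d$temperature_C - t_target) <= window_C / 2
    if (!any(w)) w <- which.min(abs(d$temperature_C - t_target))
    c(i = abs(mean(d$current_pA[w])), t = mean(d$temperature_C[w]))
  }
  a1 <- amp_at(t1_nominal)
  a2 <- amp_at(a1[["t"]] + dt)
  if (a1[["i"]] <= 0) return(fail("invalid-amplitude"))
  q10 <- (a2[["i"]] / a1[["i"]])^(10 / (a2[["t"]] - a1[["t"]]))
  structure(list(i1 = a1[["i"]], i2 = a2[["i"]], t1 = a1[["t"]], t2 = a2[["t"]],
                 q10 = q10, voltage = v_test, status = "ok"),
            class = "q10_measurement")
}

#' @export
print.q10_measurement <- function(x, ...) {
  if (identical(x$status, "ok")) {
    cat(sprintf("<q10_measurement> Q10 = %.3g at %g mV (I %.3g -> %.3g pA, T %.3g -> %.3g C)\n",
                x$q10, x$voltage, x$i1, x$i2, x$t1, x$t2))
  } else {
    cat(sprintf("<q10_measurement> %s at %g mV\n", x$status, x$voltage))
  }
  invisible(x)
}

#' Voltage-resolved Q10 from two G-V curves
#'
#' Applies the Q10 definition to conductance ratios at matched voltages.
#' The second curve is linearly interpolated onto the first curve's
#' voltages; no extrapolation (voltages outside the overlap, and voltages
#' with nonpositive conductance in either curve, are undefined, `NA`).
#' Both curves should be conductance-corrected beforehand if the
#' single-channel temperature dependence is to be excluded.
#'
#' @param gv_t1,gv_t2 [gv_curve()]s at the lower / upper temperature (their
#'   `temperature` attributes supply T1, T2; `t2 > t1` required).
#' @return A `q10_profile` data.frame (`voltage_mV`, `q10`) with attributes
#'   `t1`, `t2`.
#' @export
q10_voltage_profile <- function(gv_t1, gv_t2) {
  t1 <- attr(gv_t1, "temperature"); t2 <- attr(gv_t2, "temperature")
  if (!is.finite(t1) || !is.finite(t2) || !(t2 > t1)) {
    stop("gv curves must carry temperatures with t2 > t1", call. = FALSE)
  }
  v <- gv_t1$voltage_mV
  g2 <- stats::approx(gv_t2$voltage_mV, gv_t2$conductance_nS, xout = v,
                      rule = 1)$y
  g1 <- gv_t1$conductance_nS
  ok <- is.finite(g2) & g1 > 0 & g2 > 0
  q10 <- rep(NA_real_, length(v))
  q10[ok] <- (g2[ok] / g1[ok])^(10 / (t2 - t1))
  structure(data.frame(voltage_mV = v, q10 = q10),
            t1 = t1, t2 = t2, class = c("q10_profile", "data.frame"))
}

#' Van't Hoff estimation of transition enthalpy and entropy
#'
#' Converts a current-versus-temperature series at fixed voltage into open
#' probabilities, forms the equilibrium constant
#' \eqn{K_{eq} = P_o/(1-P_o)} and fits \eqn{\ln K_{eq} = -\Delta H/(RT) +
#' \Delta S/R} by least squares, so \eqn{\Delta H = -slope \cdot R} and
#' \eqn{\Delta S = intercept \cdot R}.  Currents are conductance-corrected
#' to the reference temperature first.  The voltage should sit where the
#' channel opens only a few percent, so the fitted constants track the
#' heat-driven transition alone.
#'
#' @param temperature Temperatures, degrees C (>= 3 distinct values).
#' @param current Leak-subtracted currents at those temperatures, pA.
#' @param v Measurement voltage, mV.
#' @param v_rev Reversal potential, mV.
#' @param g_max_ref Maximal (fully open) conductance at the reference
#'   temperature, nS; the normalization that converts conductance to open
#'   probability.
#' @param gamma_q10,t_ref Conductance-correction settings
#'   (see [correct_conductance()]).
#' @return `vant_hoff_estimate`: list with `dH` (J/mol), `dS` (J/(mol K)),
#'   `r_squared`, `n_points`, `slope`, `intercept`.
#' @export
vant_hoff <- function(temperature, current, v, v_rev = 0, g_max_ref,
                      gamma_q10 = 1.5, t_ref = 22) {
  stopifnot(length(temperature) == length(current))
  if (length(unique(temperature)) < 3) {
    stop("need at least 3 temperatures", call. = FALSE)
  }
  if (abs(v - v_rev) < 1e-9) stop("no driving force at v_rev", call. = FALSE)
  i_corr <- correct_conductance(current, temperature, gamma_q10, t_ref)
  po <- (i_corr / (v - v_rev)) / g_max_ref
  if (any(po >= 1)) {
    stop("open probability >= 1: normalization reference g_max_ref too small",
         call. = FALSE)
  }
  keep <- po > 0
  if (sum(keep) < 3) stop("fewer than 3 usable points (Po must be positive)", call. = FALSE)
  x <- 1 / kelvin(temperature[keep])
  y <- log(po[keep] / (1 - po[keep]))
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(dH = -co[["x"]] * .R_GAS, dS = co[["(Intercept)"]] * .R_GAS,
                 r_squared = summary(fit)$r.squared, n_points = sum(keep),
                 slope = co[["x"]], intercept = co[["(Intercept)"]]),
            class = "vant_hoff_estimate")
}

#' @export
print.vant_hoff_estimate <- function(x, ...) {
  cat(sprintf("<vant_hoff_estimate> dH = %.4g kJ/mol, dS = %.4g J/(mol K), r^2 = %.4f (n = %d)\n",
              x$dH / 1000, x$dS, x$r_squared, x$n_points))
  invisible(x)
}

#' Gating free-energy change from a half-activation voltage shift
#'
#' \eqn{\Delta G = z F \Delta V_{1/2}} with the total gating charge `z`.
#'
#' @param z_total Total gating charge, e0.
#' @param delta_v_half Shift in half-activation voltage, mV.
#' @return `energy_shift`: list with `z_total`, `delta_v_half` (mV),
#'   `delta_g_J_mol` and `delta_g_kcal_mol`.
#' @export
delta_g_shift <- function(z_total, delta_v_half) {
  check_finite(z_total, delta_v_half)
  dg <- z_total * .FARADAY * delta_v_half / 1000
  structure(list(z_total = z_total, delta_v_half = delta_v_half,
                 delta_g_J_mol = dg, delta_g_kcal_mol = dg / 4184),
            class = "energy_shift")
}

#' @export
print.energy_shift <- function(x, ...) {
  cat(sprintf("<energy_shift> z = %g e0, dV1/2 = %g mV -> dG = %.4g kJ/mol (%.3g kcal/mol)\n",
              x$z_total, x$delta_v_half, x$delta_g_J_mol / 1000, x$delta_g_kcal_mol))
  invisible(x)
}

#' Closed-state-inactivation availability curve from triple-pulse families
#'
#' For each sweep, availability is the mean current amplitude in the P3
#' test pulse divided by that in the identical P1 pulse; the availabilities
#' are fitted with a falling Boltzmann of the conditioning (P2) voltage.
#' Sweeps with a vanishing P1 amplitude are excluded with a warning.  If no
#' inactivation is present (availability flat), the fit is returned with a
#' failure code rather than spurious parameters.
#'
#' @param sweeps List of `sweep_record`s from [synthesize_csi_family()] (or
#'   any sweeps with P1/P2/P3-labelled segments and `meta$p2_voltage`).
#' @param window Fractional window within P1/P3 over which the amplitude is
#'   averaged.
#' @return List with `table` (data.frame `p2_voltage_mV`, `availability`)
#'   and `fit` (a `boltzmann_fit`; its `v_half`/`q` describe the falling
#'   availability curve, `q` reported as a positive magnitude).
#' @export
csi_curve <- function(sweeps, window = c(0.5, 0.95)) {
  rows <- lapply(sweeps, function(sw) {
    i1 <- abs(mean(sw$data$current_pA[.segment_window(sw, "P1", window)]))
    i3 <- abs(mean(sw$data$current_pA[.segment_window(sw, "P3", window)]))
    if (i1 < 1e-9) {
      warning(sprintf("P1 amplitude ~ 0 at P2 = %g mV; triple excluded",
                      sw$meta$p2_voltage))
      return(NULL)
    }
    data.frame(p2_voltage_mV = sw$meta$p2_voltage, availability = i3 / i1)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  tab <- tab[order(tab$p2_voltage_mV), ]
  # fit the mirrored (rising) curve, then report the falling-curve midpoint
  fit <- if (nrow(tab) < 4) {
    structure(list(v_half = NA_real_, q = NA_real_, g_max = NA_real_,
                   residual = NA_real_, converged = FALSE,
                   status = "too-few-points", n = nrow(tab),
                   temperature = 24), class = "boltzmann_fit")
  } else {
    fit_boltzmann(gv_curve(-rev(tab$p2_voltage_mV), rev(tab$availability),
                           temperature = 24))
  }
  if (isTRUE(fit$converged)) {
    fit$v_half <- -fit$v_half
    fit$q <- abs(fit$q)
  }
  list(table = tab, fit = fit)
}
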