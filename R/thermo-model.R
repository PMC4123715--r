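# Equilibrium thermodynamic gating model: a two-state pore transition and a
# four-state allosteric scheme in which a voltage-sensor transition (C <-> C')
# is coupled to a pore-opening transition (C' <-> O') through a dimensionless
# allosteric factor D.  All equilibrium constants are evaluated in log space.

#' Thermodynamic description of a single gating transition
#'
#' A gating transition is parameterised by its enthalpy change, entropy change
#' and the gating charge it moves across the membrane electric field.  The
#' equilibrium constant at voltage `v` (mV) and temperature `T` (K) is
#' \deqn{K(V,T) = \exp\{-(\Delta H - T \Delta S - z F V)/(R T)\}.}
#' A heat-activated transition has \eqn{\Delta H > 0}; a heat-deactivated one
#' (the behaviour seen in decoupled mutants that close upon warming) has
#' \eqn{\Delta H < 0}.  No sign constraints are imposed.
#'
#' @param dH Enthalpy change, J/mol.
#' @param dS Entropy change, J/(mol K).
#' @param z Gating charge moved, elementary charges (per-mole convention:
#'   multiplied by the Faraday constant internally).
#' @return An object of class `thermo_transition`.
#' @examples
#' tr <- thermo_transition(dH = 418e3, dS = 1.34e3, z = 0)
#' two_state_open_probability(tr, v = 0, temp = 25)
#' @export
thermo_transition <- function(dH, dS, z = 0) {
  check_finite(dH, dS, z)
  stopifnot(length(dH) == 1, length(dS) == 1, length(z) == 1)
  structure(list(dH = dH, dS = dS, z = z), class = "thermo_transition")
}

#' @export
print.thermo_transition <- function(x, ...) {
  cat(sprintf("<thermo_transition> dH = %.4g kJ/mol, dS = %.4g J/(mol K), z = %.3g e0\n",
              x$dH / 1000, x$dS, x$z))
  invisible(x)
}

#' Build a transition whose midpoint and steepness match a Boltzmann fit
#'
#' Constructs an athermal (`dS = 0`) transition with `dH = z F V1/2`, so its
#' open probability at any temperature is exactly the single-Boltzmann
#' function with the given half-activation voltage and apparent charge.
#' Useful for generating synthetic data from published G-V fit values.
#'
#' @param v_half Half-activation voltage, mV.
#' @param q Apparent gating charge, e0.
#' @return A `thermo_transition`.
#' @export
boltzmann_transition <- function(v_half, q) {
  check_finite(v_half, q)
  thermo_transition(dH = q * .FARADAY * v_half / 1000, dS = 0, z = q)
}

# log equilibrium constant; vectorised over v and temp (recycled)
log_equilibrium_constant <- function(trans, v, temp) {
  tk <- kelvin(temp)
  -(trans$dH - tk * trans$dS - trans$z * .FARADAY * v / 1000) / (.R_GAS * tk)
}

#' Allosteric gating parameters (four-state scheme)
#'
#' Two coupled transitions: `J`, the voltage-sensor activation (C <-> C'),
#' and `L`, the pore opening (C <-> O), joined by the allosteric coupling
#' factor `D`.  The four states C, C', O, O' carry statistical weights
#' 1, J, L and J*L*D.  `D = 1` means sensor and gate are fully decoupled;
#' large `D` makes opening effectively obligatory upon sensor activation,
#' the classical strongly coupled Kv phenotype.
#'
#' @param J `thermo_transition` for the voltage-sensor movement.
#' @param L `thermo_transition` for pore opening.
#' @param D Coupling factor, dimensionless, must be >= 0.
#' @return An object of class `allosteric_params`.
#' @examples
#' p <- channel_preset("shaker_like")
#' open_probability(p, v = -54, temp = 24)
#' @export
allosteric_params <- function(J, L, D = 1) {
  stopifnot(inherits(J, "thermo_transition"), inherits(L, "thermo_transition"))
  check_finite(D)
  if (length(D) != 1 || D < 0) stop("coupling factor D must be a scalar >= 0", call. = FALSE)
  structure(list(J = J, L = L, D = D), class = "allosteric_params")
}

#' @export
print.allosteric_params <- function(x, ...) {
  cat("<allosteric_params>\n  J (voltage sensor): ")
  print(x$J)
  cat("  L (pore opening):   ")
  print(x$L)
  cat(sprintf("  D (coupling) = %.4g\n", x$D))
  invisible(x)
}

is_gating_model <- function(x) {
  inherits(x, "allosteric_params") || inherits(x, "thermo_transition")
}

#' Single-Boltzmann open fraction
#'
#' The normalized conductance of a voltage-gated channel as a function of
#' voltage: \eqn{G/G_{max} = 1/(1 + \exp(-q F (V - V_{1/2})/(R T)))}.
#'
#' @param v Membrane voltage, mV (vectorised).
#' @param v_half Half-activation voltage, mV.
#' @param q Apparent gating charge, e0.
#' @param temp Temperature, degrees C.
#' @return Open fraction in (0, 1), same length as `v`.
#' @export
boltzmann_open_fraction <- function(v, v_half, q, temp = 24) {
  check_finite(v, v_half, q, temp)
  stats::plogis(q * (v - v_half) / rt_over_f_mv(temp))
}

#' Two-state open probability of a single thermodynamic transition
#'
#' \eqn{P = K/(1+K)} with \eqn{K = \exp\{-(\Delta H - T\Delta S - zFV)/(RT)\}}.
#' With `z = 0` this is the textbook temperature-dependent occupancy of the
#' favoured state of an A <-> B equilibrium; the probability increases with
#' temperature exactly when \eqn{\Delta H > 0}.
#'
#' @param trans A `thermo_transition`.
#' @param v Membrane voltage, mV (vectorised).
#' @param temp Temperature, degrees C (vectorised, recycled against `v`).
#' @return Open probability in (0, 1).
#' @export
two_state_open_probability <- function(trans, v, temp) {
  stopifnot(inherits(trans, "thermo_transition"))
  check_finite(v, temp)
  stats::plogis(log_equilibrium_constant(trans, v, temp))
}

# log statistical weights of (C, C', O, O'); rows = samples
.log_weights <- function(params, v, temp) {
  n <- max(length(v), length(temp))
  v <- rep_len(v, n); temp <- rep_len(temp, n)
  lj <- log_equilibrium_constant(params$J, v, temp)
  ll <- log_equilibrium_constant(params$L, v, temp)
  ld <- log(params$D)
  cbind(C = 0, Cp = lj, O = ll, Op = lj + ll + ld)
}

# normalised occupancies via log-sum-exp (overflow safe up to |exponent| ~ 700)
.occupancies <- function(params, v, temp) {
  lw <- .log_weights(params, v, temp)
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

#' Occupancy distribution over the four allosteric states
#'
#' @param params An `allosteric_params` object.
#' @param v Membrane voltage, mV (scalar).
#' @param temp Temperature, degrees C (scalar).
#' @return An object of class `state_distribution` with fields `pC`, `pCp`,
#'   `pO`, `pOp` summing to one.
#' @export
state_distribution <- function(params, v, temp) {
  stopifnot(inherits(params, "allosteric_params"),
            length(v) == 1, length(temp) == 1)
  check_finite(v, temp)
  p <- .occupancies(params, v, temp)
  structure(list(pC = unname(p[1, "C"]), pCp = unname(p[1, "Cp"]),
                 pO = unname(p[1, "O"]), pOp = unname(p[1, "Op"])),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf("<state_distribution> C %.4g | C' %.4g | O %.4g | O' %.4g\n",
              x$pC, x$pCp, x$pO, x$pOp))
  invisible(x)
}

#' Equilibrium open probability
#'
#' For an allosteric model, \eqn{P_o = p_O + p_{O'}}; for a bare
#' `thermo_transition` it reduces to [two_state_open_probability()].
#'
#' @param model An `allosteric_params` or `thermo_transition`.
#' @param v Membrane voltage, mV (vectorised).
#' @param temp Temperature, degrees C (vectorised, recycled).
#' @return Open probability, same length as the longer of `v`/`temp`.
#' @export
open_probability <- function(model, v, temp) {
  if (inherits(model, "thermo_transition")) {
    return(two_state_open_probability(model, v, temp))
  }
  stopifnot(inherits(model, "allosteric_params"))
  check_finite(v, temp)
  p <- .occupancies(model, v, temp)
  unname(p[, "O"] + p[, "Op"])
}

#' Model conductance-voltage curve
#'
#' @param model Gating model (`allosteric_params` or `thermo_transition`).
#' @param v_grid Strictly increasing voltage grid, mV.
#' @param temp Temperature, degrees C.
#' @param g_max Maximal conductance, nS (scales the open probability).
#' @return A `gv_curve` object (see [gv_curve()]).
#' @export
model_gv_curve <- function(model, v_grid, temp, g_max = 1) {
  check_v_grid(v_grid)
  po <- open_probability(model, v_grid, temp)
  gv_curve(v_grid, po * g_max, temperature = temp)
}

check_v_grid <- function(v_grid) {
  if (length(v_grid) == 0) stop("voltage grid must be non-empty", call. = FALSE)
  check_finite(v_grid, .names = "v_grid")
  if (length(v_grid) > 1 && any(diff(v_grid) <= 0)) {
    stop("voltage grid must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Model gating-charge displacement (Q-V) curve
#'
#' Mean charge moved per channel as a function of voltage,
#' \eqn{\langle q \rangle(V) = z_J (p_{C'}+p_{O'}) + z_L (p_O+p_{O'})},
#' min-max normalized over the grid.  The Q-V reports voltage-sensor
#' movement and separates from the G-V when the sensor is decoupled from
#' the gate.
#'
#' @inheritParams model_gv_curve
#' @return data.frame with columns `voltage_mV`, `q_norm`.
#' @export
qv_curve <- function(model, v_grid, temp) {
  stopifnot(inherits(model, "allosteric_params"))
  check_v_grid(v_grid)
  p <- .occupancies(model, v_grid, temp)
  q <- model$J$z * (p[, "Cp"] + p[, "Op"]) + model$L$z * (p[, "O"] + p[, "Op"])
  rng <- range(q)
  qn <- if (diff(rng) > 0) (q - rng[1]) / diff(rng) else rep(0, length(q))
  data.frame(voltage_mV = v_grid, q_norm = unname(qn))
}

#' Voltage-resolved temperature coefficient of the model open probability
#'
#' Applies the Q10 definition to the model's equilibrium open probability
#' between two temperatures:
#' \eqn{Q_{10}(V) = (P_o(V,T_2)/P_o(V,T_1))^{10/(T_2-T_1)}}.
#' The single-channel conductance temperature factor is deliberately
#' excluded at model level; the measurement pipeline applies that correction
#' to currents instead.  Voltages where \eqn{P_o(T_1)} underflows below
#' 1e-12 are reported as `NA` (undefined), never as infinity.
#'
#' @param model Gating model.
#' @param t1,t2 Lower and upper temperature, degrees C (`t2 > t1`).
#' @param v_grid Strictly increasing voltage grid, mV.
#' @return A `q10_profile` data.frame with columns `voltage_mV`, `q10` and
#'   attributes `t1`, `t2`.
#' @export
model_q10_profile <- function(model, t1, t2, v_grid) {
  if (!(t2 > t1)) stop("t2 must exceed t1", call. = FALSE)
  check_v_grid(v_grid)
  p1 <- open_probability(model, v_grid, t1)
  p2 <- open_probability(model, v_grid, t2)
  q10 <- ifelse(p1 < 1e-12, NA_real_, (p2 / p1)^(10 / (t2 - t1)))
  structure(data.frame(voltage_mV = v_grid, q10 = q10),
            t1 = t1, t2 = t2, class = c("q10_profile", "data.frame"))
}

#' Steady-state availability of a channel with closed-state inactivation
#'
#' A decreasing Boltzmann of voltage: the fraction of channels not resident
#' in the closed-inactivated state after a long conditioning pulse at `v`.
#'
#' @param v Conditioning voltage, mV (vectorised).
#' @param v_half_csi Availability midpoint, mV.
#' @param q_csi Apparent charge of the inactivation transition, e0 (its
#'   magnitude is used; the curve always falls with depolarization).
#' @param temp Temperature, degrees C.
#' @return Availability in (0, 1).
#' @export
csi_availability <- function(v, v_half_csi, q_csi, temp = 24) {
  check_finite(v, v_half_csi, q_csi)
  stats::plogis(-abs(q_csi) * (v - v_half_csi) / rt_over_f_mv(temp))
}

#' Product of normalized activation and availability curves
#'
#' Multiplies the normalized activation Boltzmann by the normalized
#' closed-state-inactivation availability curve pointwise over a voltage
#' grid.  The product surges in the voltage window where channels are only
#' slightly activated yet substantially inactivation-prone -- the window in
#' which decoupling-dependent heat sensitivity is observed.  Setting
#' `use_inactivation = TRUE` multiplies by (1 - availability) instead.
#'
#' @param act_fit List or `boltzmann_fit` with fields `v_half`, `q`
#'   (activation, rising).
#' @param csi_fit List or `boltzmann_fit` with fields `v_half`, `q`
#'   (availability, falling).
#' @param v_grid Strictly increasing voltage grid, mV.
#' @param temp Temperature, degrees C.
#' @param use_inactivation Multiply by inactivation probability instead of
#'   availability.
#' @return data.frame with columns `voltage_mV`, `activation`,
#'   `availability`, `combined`.
#' @export
combined_probability <- function(act_fit, csi_fit, v_grid, temp = 24,
                                 use_inactivation = FALSE) {
  check_v_grid(v_grid)
  act <- boltzmann_open_fraction(v_grid, act_fit$v_half, abs(act_fit$q), temp)
  avail <- csi_availability(v_grid, csi_fit$v_half, csi_fit$q, temp)
  second <- if (use_inactivation) 1 - avail else avail
  data.frame(voltage_mV = v_grid, activation = act, availability = avail,
             combined = act * second)
}
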