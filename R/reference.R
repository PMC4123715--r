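# Headline reference computations: the parameter-recovery experiments and
# the bound-type temperature-coefficient quantities for the shipped
# parameterizations.  reference_quantities() regenerates all of them from
# the configs alone; the `reproduce` CLI subcommand and the repository's
# acceptance script are thin wrappers around it.

#' Synthetic G-V parameter-recovery experiment
#'
#' Generates replicate noisy step families from a channel whose open
#' probability is a single Boltzmann with the given midpoint and apparent
#' charge, runs each replicate through the full measurement pipeline (leak
#' subtraction, G-V extraction, Boltzmann fit) and collects the fitted
#' parameters.
#'
#' @param v_half,q Generating half-activation voltage (mV) and apparent
#'   charge (e0).
#' @param test_voltages Step voltages, mV (must avoid the reversal
#'   potential, 0 mV with the symmetric solutions used).
#' @param n_reps Number of replicate patches.
#' @param seed Base seed; replicate i uses `seed * 1000 + i`.
#' @param temp Bath temperature, degrees C.
#' @param noise_sd Current noise, pA.
#' @param leak_g True leak conductance, nS.
#' @return data.frame with one row per replicate: `v_half_mV`, `q_e0`,
#'   `g_max_nS`, `converged`.
#' @export
gv_recovery_experiment <- function(v_half, q, test_voltages, n_reps = 4,
                                   seed = 1, temp = 24, noise_sd = 0.5,
                                   leak_g = 0.05) {
  model <- boltzmann_transition(v_half, q)
  spec <- channel_spec(model, n_channels = 100, gamma_ref = 10)
  protos <- gv_step_protocols(test_voltages, temp_start = temp)
  rows <- lapply(seq_len(n_reps), function(r) {
    base <- seed * 1000 + r * length(protos)
    sweeps <- lapply(seq_along(protos), function(i) {
      subtract_leak(synthesize_sweep(spec, protos[[i]], leak_g = leak_g,
                                     noise_sd = noise_sd, seed = base + i))
    })
    fit <- fit_boltzmann(extract_gv(sweeps, v_rev = 0))
    data.frame(v_half_mV = fit$v_half, q_e0 = fit$q, g_max_nS = fit$g_max,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Recompute the package's reference quantities
#'
#' Runs, from the shipped configurations alone:
#' \itemize{
#'   \item the TRPV1-like and Shaker-like synthetic G-V recovery
#'     experiments (mean fitted half-activation voltage and apparent
#'     charge across replicates);
#'   \item the minimum voltage-resolved Q10 of the TRP-like two-state
#'     model between 36.6 and 46.0 degrees C (-100..+150 mV);
#'   \item the mean Q10 of the strongly coupled Shaker-like model between
#'     22.4 and 27.7 degrees C over the activated range (-40..+50 mV);
#'   \item the peak Q10 of the decoupled ILT-like model between 25 and 35
#'     degrees C (-100..+100 mV);
#'   \item the Q10 of the heat-deactivated V2-like model at the voltage
#'     where its 25 degree open probability is closest to 60\%.
#' }
#'
#' @param seed Integer seed controlling the stochastic recovery
#'   experiments.
#' @return Named list; each element is `list(value =, n =)`.
#' @export
reference_quantities <- function(seed = 1) {
  out <- list()

  trp <- gv_recovery_experiment(v_half = 114.9, q = 0.76,
                                test_voltages = seq(15, 235, by = 20),
                                n_reps = 4, seed = seed)
  out$trpv1_vhalf_mV <- list(value = mean(trp$v_half_mV), n = nrow(trp))
  out$trpv1_q_e0 <- list(value = mean(trp$q_e0), n = nrow(trp))

  shk <- gv_recovery_experiment(v_half = -54.2, q = 5.1,
                                test_voltages = setdiff(seq(-110, 10, by = 10), 0),
                                n_reps = 5, seed = seed + 7)
  out$shaker_vhalf_mV <- list(value = mean(shk$v_half_mV), n = nrow(shk))
  out$shaker_q_e0 <- list(value = mean(shk$q_e0), n = nrow(shk))

  grid_trp <- seq(-100, 150, by = 1)
  prof <- model_q10_profile(channel_preset("trpv1_like"), 36.6, 46.0, grid_trp)
  out$trp_q10_min <- list(value = min(prof$q10, na.rm = TRUE), n = length(grid_trp))

  grid_shk <- seq(-40, 50, by = 1)
  prof <- model_q10_profile(channel_preset("shaker_like"), 22.4, 27.7, grid_shk)
  out$shaker_q10_mean <- list(value = mean(prof$q10, na.rm = TRUE), n = length(grid_shk))

  grid_ilt <- seq(-100, 100, by = 1)
  prof <- model_q10_profile(channel_preset("ilt_like"), 25, 35, grid_ilt)
  out$ilt_q10_peak <- list(value = max(prof$q10, na.rm = TRUE), n = length(grid_ilt))

  v2 <- channel_preset("v2_like")
  po25 <- open_probability(v2, grid_ilt, 25)
  v_open <- grid_ilt[which.min(abs(po25 - 0.6))]
  prof <- model_q10_profile(v2, 25, 35, v_open)
  out$v2_q10_open <- list(value = prof$q10[1], n = 1)

  out
}
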