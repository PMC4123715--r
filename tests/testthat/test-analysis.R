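# Measurement pipeline: leak subtraction, G-V extraction and fitting,
# conductance correction, Q10 measurement, Van't Hoff estimation, energy
# shifts, profile concordance with the model.

make_manual_sweep <- function(voltage, current, temp = 24) {
  n <- length(voltage)
  seg <- data.frame(kind = "hold", v_start = voltage[1], v_end = voltage[1],
                    duration_ms = n, label = "holding",
                    t_start_s = 0, t_end_s = n / 1000)
  d <- data.frame(time_s = (seq_len(n) - 1) / 1000, voltage_mV = voltage,
                  current_pA = current, temperature_C = temp)
  structure(list(data = d, meta = list(channel = "manual", seed = NA,
                                       protocol = "manual", leak_nS = NA,
                                       segments = seg)),
            class = "sweep_record")
}

test_that("leak subtraction implements the reference-voltage rule", {
  # I(-100 mV) = -2 pA -> g_leak = 0.02 nS; leak at +50 mV = 1 pA
  v <- c(rep(-100, 100), rep(50, 100))
  i <- 0.02 * v
  sw <- make_manual_sweep(v, i)
  sub <- subtract_leak(sw)
  expect_equal(sub$meta$leak_nS_estimated, 0.02)
  expect_true(all(abs(sub$data$current_pA) < 1e-12))
  expect_error(subtract_leak(make_manual_sweep(rep(-80, 10), rep(1, 10))),
               "holding samples at -100")
})

test_that("pure-leak sweeps leave no residual current", {
  spec <- channel_spec(channel_preset("shaker_like"), n_channels = 1)
  spec$model <- thermo_transition(1e6, 0, 0)  # never opens
  proto <- gv_step_protocols(40)[[1]]
  sw <- synthesize_sweep(spec, proto, leak_g = 0.1, noise_sd = 0.3, seed = 2)
  sub <- subtract_leak(sw)
  expect_lt(abs(mean(sub$data$current_pA)), 0.05)   # no systematic residual
  expect_lt(max(abs(sub$data$current_pA)), 5 * 0.3) # only noise remains

})

test_that("G-V extraction returns driving-force-normalized conductance", {
  spec <- channel_spec(always_open_model(), n_channels = 100, gamma_ref = 10)
  protos <- gv_step_protocols(c(-80, -40, 40, 80), temp_start = 22)
  sweeps <- lapply(seq_along(protos), function(i) {
    synthesize_sweep(spec, protos[[i]], leak_g = 0, noise_sd = 0, seed = i)
  })
  gv <- extract_gv(sweeps, v_rev = 0)
  expect_equal(gv$conductance_nS, rep(1, 4), tolerance = 1e-9)
  expect_equal(gv$voltage_mV, c(-80, -40, 40, 80))
  expect_error(extract_gv(sweeps, v_rev = 0, window = c(0.9, 0.9)), "window")
})

test_that("Boltzmann fitting recovers generating parameters from noiseless curves", {
  for (par in list(c(-54.2, 5.1), c(114.9, 0.76))) {
    v <- seq(par[1] - 80 / par[2], par[1] + 80 / par[2], length.out = 15)
    g <- 0.9 * boltzmann_open_fraction(v, par[1], par[2], 24)
    fit <- fit_boltzmann(gv_curve(v, g, temperature = 24))
    expect_true(fit$converged)
    expect_equal(fit$v_half, par[1], tolerance = 1e-4 * abs(par[1]))
    expect_equal(fit$q, par[2], tolerance = 1e-4 * par[2])
    expect_equal(fit$g_max, 0.9, tolerance = 1e-4)
    # predicted normalized conductance at the midpoint is one half, exactly
    expect_equal(predict(fit, fit$v_half), 0.5)
  }
  flat <- fit_boltzmann(gv_curve(1:10, rep(0.5, 10), temperature = 24))
  expect_false(flat$converged)
  expect_equal(flat$status, "no-transition")
})

test_that("conductance correction rescales to the reference temperature", {
  expect_equal(correct_conductance(10, 22), 10)
  expect_equal(correct_conductance(15, 32), 10)
  expect_equal(correct_conductance(10, 17), 10 * 1.5^0.5, tolerance = 1e-12)
  expect_equal(correct_conductance(10, 17), 12.247, tolerance = 1e-4)
})

test_that("Q10 measurement reproduces the closed form on noiseless currents", {
  proto <- heat_hold_protocol(v_test = -60, t_start = 24, t_end = 48,
                              hold_ms = 500, sample_interval_ms = 2)
  sw <- synthesize_sweep(channel_spec(always_open_model()), proto,
                         leak_g = 0, noise_sd = 0, seed = 0)
  # overwrite with an exponential in 1/T (van't Hoff form), sign of driving
  tk <- sw$data$temperature_C + 273.15
  sw$data$current_pA <- -exp(40 - 13000 / tk)
  m <- measure_q10(sw, window_C = 1e-9)   # point sampling
  expect_equal(m$status, "ok")
  closed_form <- (exp(40 - 13000 / (m$t2 + 273.15)) /
                    exp(40 - 13000 / (m$t1 + 273.15)))^(10 / (m$t2 - m$t1))
  expect_equal(m$q10, closed_form, tolerance = 1e-12)
  # the reported fields satisfy the defining identity exactly
  expect_equal(m$q10, (m$i2 / m$i1)^(10 / (m$t2 - m$t1)), tolerance = 1e-15)

  # constant-Q10 exponential: measured value equals the generating Q10
  sw$data$current_pA <- 2 * 3^((sw$data$temperature_C - 24) / 10)
  m2 <- measure_q10(sw, window_C = 1e-9)
  expect_equal(m2$q10, 3, tolerance = 1e-12)

  # Shaker-exception arithmetic: 5-degree interval
  m3 <- measure_q10(sw, special_dt = 5, window_C = 1e-9)
  expect_equal(m3$q10, 3, tolerance = 1e-12)
  expect_equal(m3$t2 - m3$t1, 5, tolerance = 0.01)
})

test_that("no activation is reported when the sweep never heats", {
  proto <- patch_protocol(proto_segment("step", -60, 200, label = "test"),
                          temp_start = 24, sample_interval_ms = 1)
  sw <- synthesize_sweep(channel_spec(channel_preset("trpv1_like")), proto,
                         leak_g = 0, noise_sd = 0.2, seed = 1)
  m <- measure_q10(sw)
  expect_equal(m$status, "no-activation")
  expect_true(is.na(m$q10))
})

test_that("measured heating-sweep Q10 agrees with the model profile", {
  spec <- channel_spec(channel_preset("trpv1_like"), n_channels = 500,
                       gamma_ref = 10)
  proto <- heat_hold_protocol(v_test = -60, t_start = 24, t_end = 56,
                              hold_ms = 1000, sample_interval_ms = 2)
  sw <- subtract_leak(synthesize_sweep(spec, proto, leak_g = 0.05,
                                       noise_sd = 0.5, seed = 9))
  sw$data$current_pA <- correct_conductance(sw$data$current_pA,
                                            sw$data$temperature_C)
  m <- measure_q10(sw)
  expect_equal(m$status, "ok")
  model_prof <- model_q10_profile(channel_preset("trpv1_like"),
                                  m$t1, m$t2, -60)
  expect_equal(m$q10, model_prof$q10[1], tolerance = 0.15 * model_prof$q10[1])
})

test_that("voltage-resolved Q10 from G-V pairs matches the model profile", {
  spec <- channel_spec(channel_preset("shaker_like"), n_channels = 1000,
                       gamma_ref = 10)
  volts <- setdiff(seq(-90, 30, by = 10), 0)  # 0 mV sits at the reversal
  gv_at <- function(temp) {
    protos <- gv_step_protocols(volts, temp_start = temp)
    sweeps <- lapply(protos, function(p) {
      synthesize_sweep(spec, p, leak_g = 0, noise_sd = 0, seed = 0)
    })
    gv <- extract_gv(sweeps, v_rev = 0)
    gv$conductance_nS <- correct_conductance(gv$conductance_nS,
                                             attr(gv, "temperature"))
    gv
  }
  prof <- q10_voltage_profile(gv_at(22.4), gv_at(27.7))
  model_prof <- model_q10_profile(channel_preset("shaker_like"),
                                  22.4, 27.7, volts)
  ok <- is.finite(prof$q10)
  expect_true(all(ok))
  expect_equal(prof$q10, model_prof$q10, tolerance = 0.10)
  # identical curves give a flat unit profile
  g1 <- gv_at(22.4); g2 <- g1; attr(g2, "temperature") <- 27.7
  expect_equal(q10_voltage_profile(g1, g2)$q10, rep(1, length(volts)))
})

test_that("a pure conductance-factor pair corrects back to unit Q10", {
  v <- seq(-60, 40, 10)
  g1 <- boltzmann_open_fraction(v, -20, 2, 22)
  gv1 <- gv_curve(v, g1 * 1.5^((22 - 22) / 10), temperature = 22)
  gv2 <- gv_curve(v, g1 * 1.5^((32 - 22) / 10), temperature = 32)
  gv1$conductance_nS <- correct_conductance(gv1$conductance_nS, 22)
  gv2$conductance_nS <- correct_conductance(gv2$conductance_nS, 32)
  expect_equal(q10_voltage_profile(gv1, gv2)$q10, rep(1, length(v)),
               tolerance = 1e-12)
})

test_that("Van't Hoff estimation inverts noiseless synthetic series exactly", {
  tr <- thermo_transition(dH = 418e3, dS = 1340, z = 0)
  temps <- seq(24, 44, length.out = 30)
  po <- two_state_open_probability(tr, 100, temps)
  i_raw <- po * 10 * 100 * 1.5^((temps - 22) / 10)  # gamma-inflated, pA
  est <- vant_hoff(temps, i_raw, v = 100, v_rev = 0, g_max_ref = 10)
  expect_equal(est$dH, 418e3, tolerance = 1e-9 * 418e3)
  expect_equal(est$dS, 1340, tolerance = 1e-9 * 1340)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  # temperature-independent equilibrium: zero enthalpy
  flatK <- vant_hoff(temps, rep(50, 30) * 1.5^((temps - 22) / 10),
                     v = 100, v_rev = 0, g_max_ref = 1)
  expect_equal(flatK$dH, 0, tolerance = 1e-6)
  expect_error(vant_hoff(temps, po * 2e5, v = 100, v_rev = 0, g_max_ref = 10),
               "g_max_ref")
  expect_error(vant_hoff(c(20, 30), c(1, 2), v = 100, v_rev = 0, g_max_ref = 1),
               "3 temperatures")
})

test_that("noisy Van't Hoff series recover the generating enthalpy within 5%", {
  tr <- thermo_transition(dH = 418e3, dS = 1340, z = 0)
  temps <- seq(24, 44, length.out = 50)
  po <- two_state_open_probability(tr, 100, temps)
  i_raw <- po * 10 * 100 * 1.5^((temps - 22) / 10)
  set.seed(0)
  est <- vant_hoff(temps, i_raw + rnorm(50, 0, 0.5), v = 100, v_rev = 0,
                   g_max_ref = 10)
  expect_equal(est$dH, 418e3, tolerance = 0.05 * 418e3)
  expect_equal(est$dS, 1340, tolerance = 0.05 * 1340)
})

test_that("free-energy shifts follow z F dV", {
  expect_equal(delta_g_shift(13, 0)$delta_g_J_mol, 0)
  sh <- delta_g_shift(13, -10)
  expect_equal(sh$delta_g_J_mol, -12543, tolerance = 1e-3 * 12543)
  expect_equal(sh$delta_g_kcal_mol, -12543.05 / 4184, tolerance = 1e-4)
  expect_equal(delta_g_shift(13, 10)$delta_g_J_mol,
               -delta_g_shift(13, -10)$delta_g_J_mol)
})

test_that("the pipeline recovers generating G-V parameters end to end within 3%", {
  shaker <- run_gv_recovery(-54.2, 5.1, setdiff(seq(-110, 10, 10), 0),
                            n_reps = 3, seed = 21)
  expect_equal(shaker$v_half, -54.2, tolerance = 0.03 * 54.2)
  expect_equal(shaker$q, 5.1, tolerance = 0.03 * 5.1)
  trp <- run_gv_recovery(114.9, 0.76, seq(15, 235, by = 20),
                         n_reps = 3, seed = 22)
  expect_equal(trp$v_half, 114.9, tolerance = 0.03 * 114.9)
  expect_equal(trp$q, 0.76, tolerance = 0.03 * 0.76)
})

test_that("pipeline Van't Hoff on heating sweeps recovers the pore-transition enthalpy", {
  # decoupled channel held where the sensor is saturated but opening stays
  # below ~10%, so the equilibrium constant tracks the pore transition
  spec <- channel_spec(channel_preset("ilt_like"), n_channels = 5000,
                       gamma_ref = 10)
  proto <- heat_hold_protocol(v_test = 40, t_start = 25, t_end = 31.5,
                              sample_interval_ms = 2)
  sw <- subtract_leak(synthesize_sweep(spec, proto, leak_g = 0.05,
                                       noise_sd = 0.5, seed = 3))
  d <- sw$data[sw$data$temperature_C >= 27, ]  # open probability ~1-10%
  est <- vant_hoff(d$temperature_C, d$current_pA, v = 40, v_rev = 0,
                   g_max_ref = 5000 * 10 / 1000)
  expect_equal(est$dH, 418e3, tolerance = 0.05 * 418e3)
  expect_equal(est$dS, 1340, tolerance = 0.05 * 1340)
  expect_gt(est$r_squared, 0.999)
})
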