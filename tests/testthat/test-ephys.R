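test_that("QC filter applies the strict inclusion thresholds", {
  expect_true(qc_filter(-60, 20)$pass)
  f1 <- qc_filter(-50, 20)
  expect_false(f1$pass)
  expect_match(f1$reason, "V_rest")
  f2 <- qc_filter(-60, 45)
  expect_false(f2$pass)
  expect_match(f2$reason, "R_S")
  # boundary values are exclusions, not inclusions
  expect_false(qc_filter(-55, 20)$pass)
  expect_false(qc_filter(-60, 40)$pass)
  expect_error(qc_filter(NA, 20), "missing")
})

test_that("spike detection finds each rendered spike once", {
  flat <- rep(-65, 5000)
  expect_equal(nrow(detect_spikes(flat, 1e-4)), 0)

  p <- wt_neuron_params()
  fi <- simulate_current_clamp(p, protocol_spec("fi"), seed = 1)
  in_win <- function(s) s$time_ms[s$time_ms >= fi$onset_s * 1000 &
                                    s$time_ms < fi$offset_s * 1000]
  counts <- vapply(fi$ground_truth$spikes,
                   function(s) length(in_win(s)), integer(1))
  k <- which.max(counts)  # busiest sweep of the F-I family
  expect_gte(counts[k], 5)
  ev <- thalaquant:::spikes_in_window(fi$voltage[, k], fi$dt_s,
                                      fi$onset_s, fi$offset_s)
  expect_equal(nrow(ev), counts[k])
  # detected threshold indices match the generator's spike times exactly
  expect_equal((ev$threshold_index - 1) * fi$dt_s * 1000,
               in_win(fi$ground_truth$spikes[[k]]))
})

test_that("spike detection is noise-robust up to 1 mV", {
  p0 <- wt_neuron_params()
  ref <- simulate_current_clamp(p0, protocol_spec("fi"), seed = 1)
  counts0 <- vapply(seq_along(ref$current_pA), function(k) {
    nrow(detect_spikes(ref$voltage[, k], ref$dt_s))
  }, integer(1))
  for (s in 1:10) {
    sw <- simulate_current_clamp(wt_neuron_params(noise_sd = 1),
                                 protocol_spec("fi"), seed = s)
    counts <- vapply(seq_along(sw$current_pA), function(k) {
      nrow(detect_spikes(sw$voltage[, k], sw$dt_s))
    }, integer(1))
    expect_equal(counts, counts0)
  }
})

test_that("passive properties recover an ideal RC membrane exactly", {
  sw <- rc_sweep_set(R_Mohm = 100, tau_ms = 20)
  pp <- measure_passive(sw)
  expect_equal(pp$R_in, 100, tolerance = 1e-6)
  expect_equal(pp$tau_m, 20, tolerance = 1e-3)
  expect_equal(pp$sag_percent, 0, tolerance = 1e-6)
  expect_equal(pp$V_rest, -65, tolerance = 1e-9)
  expect_false(pp$rheobase_defined)
})

test_that("passive recovery from the simulator at programmed R_in", {
  # a = 0 so the programmed R_in/tau are the pure leak values
  p <- sim_neuron_params(leak_conductance = 1000 / 150, a = 0,
                         membrane_capacitance = 150,
                         T_current_gain = 0)
  sw <- simulate_current_clamp(p, protocol_spec("passive"), seed = 1)
  pp <- measure_passive(sw)
  expect_lt(abs(pp$R_in / sw$ground_truth$R_in_Mohm - 1), 0.05)
  expect_lt(abs(pp$tau_m / sw$ground_truth$tau_m_ms - 1), 0.05)
})

test_that("sag is larger in the wild-type-like than td-like preset", {
  swt <- simulate_current_clamp(wt_neuron_params(),
                                protocol_spec("passive"), seed = 1)
  std <- simulate_current_clamp(td_neuron_params(),
                                protocol_spec("passive"), seed = 1)
  sag_wt <- measure_passive(swt)$sag_percent
  sag_td <- measure_passive(std)$sag_percent
  expect_gt(sag_wt, sag_td)
  expect_gt(sag_wt, 10)
  expect_lt(sag_td, sag_wt)
})

test_that("AP features match constructed waveforms", {
  # stylized spike: threshold -40, peak +40 -> amplitude 80; the approach
  # to threshold ramps slowly (2 mV/ms) so the derivative criterion fires
  # exactly at -40
  dt <- 1e-4
  v <- rep(-65, 3000)
  base <- 1500
  ramp_n <- 125
  v[(base - ramp_n):(base - 1)] <- seq(-65, -40.2, length.out = ramp_n)
  rise <- seq(-40, 40, length.out = 6)
  fall <- seq(40, -55, length.out = 12)
  v[base:(base + 5)] <- rise
  v[(base + 6):(base + 17)] <- fall
  ap <- ap_features(v, dt, onset_s = 0.1, offset_s = 0.25)
  expect_equal(ap$amplitude, 80, tolerance = 1e-9)
  expect_equal(ap$threshold, -40, tolerance = 1e-9)

  # symmetric triangular spike of total width 1 ms -> half-width 0.5 ms
  v2 <- rep(-40, 3000)
  tri <- c(seq(-40, 40, length.out = 6), seq(40, -40, length.out = 6)[-1])
  v2[1500:(1500 + length(tri) - 1)] <- tri
  ap2 <- ap_features(v2, dt, onset_s = 0.1, offset_s = 0.25)
  expect_equal(ap2$half_width, 0.5, tolerance = 1e-9)
  expect_error(ap_features(rep(-65, 100), dt, 0, 0.01), "no spikes")
})

test_that("waveform features recover simulator ground truth under noise", {
  errs <- vapply(1:25, function(s) {
    p <- td_neuron_params(noise_sd = 0.5)
    sw <- simulate_current_clamp(p, protocol_spec("passive"), seed = s)
    pp <- measure_passive(sw)
    k <- which(sw$current_pA == pp$rheobase)[1]
    ap <- ap_features(sw$voltage[, k], sw$dt_s, sw$onset_s, sw$offset_s)
    tr <- sw$ground_truth$spikes[[k]]
    thr_true <- tr$threshold_mV[tr$time_ms >= sw$onset_s * 1000][1]
    c(thr = abs(ap$threshold - thr_true),
      hw = abs(ap$half_width -
                 spike_halfwidth_true(td_neuron_params(), thr_true)),
      lat = abs(ap$latency -
                  (tr$time_ms[tr$time_ms >= sw$onset_s * 1000][1] -
                     sw$onset_s * 1000)))
  }, numeric(3))
  expect_lt(median(errs["thr", ]), 1)
  expect_lt(median(errs["hw", ]), 0.05)
  expect_lt(median(errs["lat", ]), 0.2)  # within 2 samples
})

test_that("F-I curve slope and flags", {
  # constructed counts 0,5,10,15 at 25 pA spacing -> slope 0.2 Hz/pA
  mk <- function(counts, amps) {
    # synthetic sweep set with `counts` rendered spikes per sweep
    dt <- 1e-4; n <- 14000
    V <- sapply(counts, function(cnt) {
      v <- rep(-65, n)
      if (cnt > 0) {
        at <- round(seq(2500, 11500, length.out = cnt))
        for (i in at) {
          v[i:(i + 3)] <- c(-40, 10, 40, 5)
          v[(i + 4):(i + 9)] <- seq(-20, -55, length.out = 6)
        }
      }
      v
    })
    structure(list(time_s = (seq_len(n) - 1) * dt, voltage = V,
                   current_pA = amps, onset_s = 0.2, offset_s = 1.2,
                   dt_s = dt, V_rest = -65, R_S = 10,
                   ground_truth = NULL), class = "sweep_set")
  }
  fi <- fi_curve(mk(c(0, 5, 10, 15), c(0, 25, 50, 75)))
  expect_equal(fi$max_frequency, 15)
  expect_equal(fi$fi_slope, 0.2, tolerance = 1e-9)

  fi0 <- fi_curve(mk(c(0, 0, 0), c(0, 25, 50)))
  expect_equal(fi0$max_frequency, 0)
  expect_false(fi0$slope_defined)

  # simulator F-I gain is positive and stable across noise seeds
  sim <- simulate_current_clamp(wt_neuron_params(),
                                protocol_spec("fi"), seed = 1)
  g0 <- fi_curve(sim)$fi_slope
  expect_gt(g0, 0)
  gn <- fi_curve(simulate_current_clamp(wt_neuron_params(noise_sd = 0.5),
                                        protocol_spec("fi"),
                                        seed = 3))$fi_slope
  expect_lt(abs(gn / g0 - 1), 0.1)
})

test_that("rebound analysis contract", {
  expect_error(rebound_analysis(rep(-65, 100), 1e-4, 0.2, 1.2, 50),
               "hyperpolarizing")
  sw <- simulate_current_clamp(wt_neuron_params(),
                               protocol_spec("rebound"), seed = 1)
  rb <- rebound_analysis(sw$voltage[, 1], sw$dt_s, sw$onset_s,
                         sw$offset_s, -50)
  truth <- sw$ground_truth$spikes[[1]]
  post <- truth[truth$time_ms >= sw$offset_s * 1000 &
                  truth$time_ms < sw$offset_s * 1000 + 300, ]
  expect_equal(rb$n_spikes, nrow(post))
  expect_equal(rb$duration_ms, diff(range(post$time_ms)),
               tolerance = 0.2)
})

test_that("voltage offset shifts potentials and preserves shape features", {
  p <- td_neuron_params()
  sw <- simulate_current_clamp(p, protocol_spec("passive"), seed = 1)
  pp1 <- measure_passive(sw)
  k <- which(sw$current_pA == pp1$rheobase)[1]
  ap1 <- ap_features(sw$voltage[, k], sw$dt_s, sw$onset_s, sw$offset_s)

  sw2 <- sw
  sw2$voltage <- sw$voltage + 7
  pp2 <- measure_passive(sw2)
  ap2 <- ap_features(sw2$voltage[, k], sw2$dt_s, sw2$onset_s, sw2$offset_s)
  expect_equal(pp2$V_rest, pp1$V_rest + 7, tolerance = 1e-9)
  expect_equal(ap2$threshold, ap1$threshold + 7, tolerance = 1e-9)
  expect_equal(pp2$R_in, pp1$R_in, tolerance = 1e-9)
  expect_equal(pp2$tau_m, pp1$tau_m, tolerance = 1e-6)
  expect_equal(ap2$amplitude, ap1$amplitude, tolerance = 1e-9)
  expect_equal(ap2$half_width, ap1$half_width, tolerance = 1e-9)
  expect_equal(ap2$AHP_amplitude, ap1$AHP_amplitude, tolerance = 1e-9)
})

test_that("full feature extraction returns one QC-verdicted row", {
  p <- wt_neuron_params()
  row <- extract_cell_features(
    simulate_current_clamp(p, protocol_spec("passive"), seed = 1),
    simulate_current_clamp(p, protocol_spec("fi"), seed = 1),
    simulate_current_clamp(p, protocol_spec("rebound"), seed = 1))
  expect_true(row$qc_pass)
  expect_gt(row$rheobase, 0)
  expect_gt(row$ap_amplitude, 0)
  expect_gte(row$rebound_n_spikes, 2)
  expect_equal(row$junction_potential_mV, -15.8)
})
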