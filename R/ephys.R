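#' Recording-quality inclusion filter
#'
#' A cell enters the analysis only with a stable resting potential below
#' -55 mV and a series resistance below 40 MOhm (strict inequalities).
#' Missing values are an error, never a silent pass.
#'
#' @param V_rest resting membrane potential, mV.
#' @param R_S series resistance, MOhm.
#' @return list with `pass` (logical) and `reason` (character vector of
#'   violated criteria, empty on pass).
#' @export
qc_filter <- function(V_rest, R_S) {
  if (is.null(V_rest) || is.na(V_rest)) stop("V_rest is missing")
  if (is.null(R_S) || is.na(R_S)) stop("R_S is missing")
  reason <- character(0)
  if (!(V_rest < -55)) reason <- c(reason, "V_rest not below -55 mV")
  if (!(R_S < 40)) reason <- c(reason, "R_S not below 40 MOhm")
  list(pass = length(reason) == 0, reason = reason)
}

#' Detect action potentials in a voltage trace
#'
#' An event is a run of samples whose voltage derivative exceeds the
#' criterion, confirmed by the trace crossing 0 mV within `confirm_ms`
#' of the run start; the threshold sample is the first sample of the
#' run. On noisy recordings the run criterion is raised to six robust
#' standard deviations of the sample-to-sample derivative noise
#' (estimated by the MAD), which anchors the run start on the fast spike
#' upstroke instead of on noise excursions during the slow approach to
#' threshold; for clean traces the MAD is zero and the user criterion
#' applies unchanged. Events closer than `refractory_ms` are merged.
#'
#' @param v voltage trace, mV.
#' @param dt_s sample interval, s.
#' @param dvdt_crit derivative criterion, mV/ms (convention: 20; 10 and 50
#'   are common alternatives).
#' @param confirm_ms window after the criterion crossing within which the
#'   trace must cross 0 mV.
#' @param refractory_ms minimum inter-event interval.
#' @return data.frame with `threshold_index` and `peak_index` (1-based),
#'   possibly empty.
#' @export
detect_spikes <- function(v, dt_s, dvdt_crit = 20, confirm_ms = 2,
                          refractory_ms = 1) {
  dt_ms <- dt_s * 1000
  d <- diff(v) / dt_ms
  run_crit <- max(dvdt_crit, 6 * stats::mad(d, center = 0))
  cand <- d >= run_crit
  starts <- which(cand & !c(FALSE, cand[-length(cand)]))
  if (length(starts) == 0) {
    return(data.frame(threshold_index = integer(0),
                      peak_index = integer(0)))
  }
  n_confirm <- max(1L, round(confirm_ms / dt_ms))
  n_refr <- max(1L, round(refractory_ms / dt_ms))
  thr_idx <- integer(0); peak_idx <- integer(0)
  last <- -Inf
  for (i in starts) {
    if (i - last < n_refr) next
    hi <- min(length(v), i + n_confirm)
    seg <- v[i:hi]
    if (!any(seg >= 0)) next
    # peak: local maximum from the crossing until repolarization below 0
    above <- which(seg >= 0)
    end_above <- above[length(above)]
    pk <- i - 1 + which.max(v[i:(i - 1 + end_above)])
    # extend the peak search while still rising
    while (pk < length(v) && v[pk + 1] > v[pk]) pk <- pk + 1
    thr_idx <- c(thr_idx, i)
    peak_idx <- c(peak_idx, pk)
    last <- pk
  }
  data.frame(threshold_index = thr_idx, peak_index = peak_idx)
}

# spike table for one sweep restricted to a time window [t0, t1) in s
spikes_in_window <- function(v, dt_s, t0, t1, ...) {
  ev <- detect_spikes(v, dt_s, ...)
  if (nrow(ev) == 0) return(ev)
  t <- (ev$threshold_index - 1) * dt_s
  ev[t >= t0 & t < t1, , drop = FALSE]
}

#' Passive intrinsic properties from a subthreshold step family
#'
#' Input resistance is the least-squares slope of the steady-state voltage
#' deflection against injected current over all subthreshold sweeps; the
#' membrane time constant is a single-exponential fit to the 5-95% onset
#' transient of the smallest hyperpolarizing step (avoiding sag
#' contamination); sag is measured on the largest hyperpolarizing sweep
#' (default -50 pA) as 100 * (peak - steady) / (peak - baseline); the
#' rheobase is the smallest step amplitude that evokes at least one spike.
#'
#' @param sweeps a `sweep_set` from [simulate_current_clamp()] or
#'   [read_sweep_csv()].
#' @param dvdt_crit spike-detection derivative criterion, mV/ms.
#' @param sag_step_pA sweep used for the sag measurement.
#' @return list with `V_rest` (mV), `R_in` (MOhm), `tau_m` (ms),
#'   `sag_percent`, `rheobase` (pA; NA with a flag when no sweep spikes).
#' @export
measure_passive <- function(sweeps, dvdt_crit = 20, sag_step_pA = -50) {
  stopifnot(inherits(sweeps, "sweep_set"))
  dt <- sweeps$dt_s
  on_i <- round(sweeps$onset_s / dt) + 1
  off_i <- round(sweeps$offset_s / dt)
  n_base <- max(1, round(0.1 / dt))
  base_win <- max(1, on_i - n_base):(on_i - 1)
  ss_win <- (off_i - n_base + 1):off_i

  amps <- sweeps$current_pA
  nsw <- length(amps)
  baseline <- colMeans(sweeps$voltage[base_win, , drop = FALSE])
  steady <- colMeans(sweeps$voltage[ss_win, , drop = FALSE])
  n_spk <- vapply(seq_len(nsw), function(k) {
    nrow(spikes_in_window(sweeps$voltage[, k], dt, sweeps$onset_s,
                          sweeps$offset_s, dvdt_crit = dvdt_crit))
  }, integer(1))

  sub <- n_spk == 0
  if (!any(amps < 0)) stop("need at least one hyperpolarizing step")
  if (sum(sub) < 2) stop("need >= 2 subthreshold sweeps for R_in")
  dV <- steady[sub] - baseline[sub]
  R_in <- unname(coef(lm(dV ~ amps[sub]))[2]) * 1000  # mV/pA -> MOhm

  # tau_m: smallest-|I| hyperpolarizing sweep, log-linear fit over the
  # 5-95% band of the onset transient. The fraction is smoothed with a
  # centred running mean first: for an exact exponential this multiplies
  # (1 - frac) by a constant and leaves the log-slope (hence tau)
  # untouched, while making the band selection robust to recording noise.
  hyp <- which(amps < 0 & sub)
  k_tau <- hyp[which.max(amps[hyp])]
  v <- sweeps$voltage[, k_tau]
  defl <- v[on_i:off_i] - baseline[k_tau]
  dss <- steady[k_tau] - baseline[k_tau]
  frac <- defl / dss
  kw <- max(3, 2 * round(0.001 / dt) + 1)  # ~2 ms centred window
  frac_s <- as.numeric(stats::filter(frac, rep(1 / kw, kw), sides = 2))
  t95 <- which(frac_s >= 0.95)[1]
  if (is.na(t95)) t95 <- length(frac_s)
  band <- which(frac_s >= 0.05 & frac_s <= 0.95)
  band <- band[band <= t95]
  if (length(band) >= 5) {
    tt <- (band - 1) * dt * 1000
    y <- log(1 - frac_s[band])
    tau_m <- -1 / unname(coef(lm(y ~ tt))[2])
  } else {
    tau_m <- NA_real_
  }

  # sag on the requested hyperpolarizing sweep; the peak deflection is
  # read from a ~5 ms smoothed trace, otherwise the minimum over 10^4
  # noisy samples carries an extreme-value bias that inflates the sag
  k_sag <- which(amps == sag_step_pA)
  sag <- NA_real_
  if (length(k_sag) == 1) {
    vs <- sweeps$voltage[on_i:off_i, k_sag]
    ks <- max(3, 2 * round(0.0025 / dt) + 1)
    vs_s <- as.numeric(stats::filter(vs, rep(1 / ks, ks), sides = 2))
    v_peak <- min(vs_s, na.rm = TRUE)
    v_ss <- steady[k_sag]
    sag <- 100 * (v_peak - v_ss) / (v_peak - baseline[k_sag])
  }

  rheo <- NA_real_
  spiking <- amps[n_spk > 0]
  if (length(spiking)) rheo <- min(spiking)

  list(V_rest = mean(baseline), R_in = R_in, tau_m = tau_m,
       sag_percent = sag, rheobase = rheo,
       rheobase_defined = length(spiking) > 0)
}

#' Action-potential waveform features of the first spike
#'
#' Computed on the first spike of the supplied (rheobase) sweep:
#' threshold = voltage at the derivative-criterion crossing; amplitude =
#' peak - threshold; half-width = width at threshold + amplitude/2 with
#' sub-sample linear interpolation at both crossings; latency = step onset
#' to threshold crossing; AHP amplitude = threshold minus the post-spike
#' minimum before the next spike (or step end).
#'
#' @param v voltage trace of the rheobase sweep, mV.
#' @param dt_s sample interval, s.
#' @param onset_s,offset_s step window, s.
#' @param events optional precomputed [detect_spikes()] table.
#' @param dvdt_crit derivative criterion, mV/ms.
#' @return list with `threshold`, `amplitude`, `half_width`, `latency`,
#'   `AHP_amplitude` (mV / ms as appropriate).
#' @export
ap_features <- function(v, dt_s, onset_s, offset_s, events = NULL,
                        dvdt_crit = 20) {
  if (is.null(events)) {
    events <- spikes_in_window(v, dt_s, onset_s, offset_s,
                               dvdt_crit = dvdt_crit)
  }
  if (nrow(events) == 0) stop("no spikes in sweep: AP features undefined")
  i_thr <- events$threshold_index[1]
  i_pk <- events$peak_index[1]
  thr <- v[i_thr]
  peak <- v[i_pk]
  amp <- peak - thr
  half_level <- thr + amp / 2

  cross_time <- function(i0, i1) {
    # linear interpolation of the half-level crossing between samples
    (i0 - 1 + (half_level - v[i0]) / (v[i1] - v[i0])) * dt_s * 1000
  }
  up <- i_thr
  while (up < i_pk && v[up + 1] < half_level) up <- up + 1
  t_up <- cross_time(up, up + 1)
  dn <- i_pk
  while (dn < length(v) && v[dn + 1] > half_level) dn <- dn + 1
  if (dn >= length(v)) stop("spike not repolarized within the trace")
  t_dn <- cross_time(dn, dn + 1)
  half_width <- t_dn - t_up

  next_thr <- if (nrow(events) > 1) events$threshold_index[2] else
    round(offset_s / dt_s)
  trough <- min(v[i_pk:next_thr])
  list(threshold = thr, amplitude = amp, half_width = half_width,
       latency = (i_thr - 1) * dt_s * 1000 - onset_s * 1000,
       AHP_amplitude = thr - trough)
}

#' Frequency-current curve and gain
#'
#' Firing frequency is the spike count over the step duration per sweep.
#' The F-I slope is the least-squares slope over the rising segment, from
#' the rheobase step up to the first step reaching 90% of the maximum
#' frequency (excluding the saturation plateau). Fewer than 3 spiking
#' sweeps leave the slope flagged undefined.
#'
#' @param sweeps a `sweep_set` recorded with the `fi` protocol.
#' @param dvdt_crit derivative criterion, mV/ms.
#' @return list with `frequencies` (Hz, one per step), `max_frequency`,
#'   `fi_slope` (Hz/pA or NA), `slope_defined`.
#' @export
fi_curve <- function(sweeps, dvdt_crit = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  dt <- sweeps$dt_s
  dur <- sweeps$offset_s - sweeps$onset_s
  amps <- sweeps$current_pA
  counts <- vapply(seq_along(amps), function(k) {
    nrow(spikes_in_window(sweeps$voltage[, k], dt, sweeps$onset_s,
                          sweeps$offset_s, dvdt_crit = dvdt_crit))
  }, integer(1))
  freq <- counts / dur
  fmax <- max(freq)
  spiking <- which(counts > 0)
  if (length(spiking) < 3 || fmax == 0) {
    return(list(frequencies = freq, max_frequency = fmax,
                fi_slope = NA_real_, slope_defined = FALSE))
  }
  i0 <- spiking[1]
  i1 <- which(freq >= 0.9 * fmax)[1]
  seg <- i0:max(i1, i0 + 2)  # need >= 3 points for a slope
  seg <- seg[seg <= length(amps)]
  slope <- unname(coef(lm(freq[seg] ~ amps[seg]))[2])
  list(frequencies = freq, max_frequency = fmax, fi_slope = slope,
       slope_defined = TRUE)
}

#' Rebound burst after release from hyperpolarization
#'
#' Counts spikes within a post-offset window of a hyperpolarizing step
#' sweep; the burst duration is the first-to-last spike interval (0 when
#' fewer than two spikes).
#'
#' @param v voltage trace, mV.
#' @param dt_s sample interval, s.
#' @param onset_s,offset_s step window, s.
#' @param step_pA injected amplitude; depolarizing steps are refused
#'   (rebound analysis is defined for release from hyperpolarization).
#' @param window_ms post-offset analysis window, default 300 ms.
#' @param dvdt_crit derivative criterion, mV/ms.
#' @return list with `n_spikes` and `duration_ms`.
#' @export
rebound_analysis <- function(v, dt_s, onset_s, offset_s, step_pA,
                             window_ms = 300, dvdt_crit = 20) {
  if (step_pA >= 0) {
    stop("rebound analysis requires a hyperpolarizing step (got ",
         step_pA, " pA)")
  }
  ev <- spikes_in_window(v, dt_s, offset_s, offset_s + window_ms / 1000,
                         dvdt_crit = dvdt_crit)
  if (nrow(ev) <= 1) {
    return(list(n_spikes = nrow(ev), duration_ms = 0))
  }
  t <- (ev$threshold_index - 1) * dt_s * 1000
  list(n_spikes = nrow(ev), duration_ms = max(t) - min(t))
}

#' Full intrinsic-property extraction for one cell
#'
#' Convenience wrapper running the QC filter, passive properties, first
#' spike waveform features at rheobase, the F-I curve and the rebound
#' analysis, as one feature row per cell.
#'
#' @param passive_sweeps,fi_sweeps,rebound_sweeps `sweep_set`s recorded
#'   with the corresponding protocols (any may be NULL).
#' @param V_rest,R_S QC quantities; default taken from `passive_sweeps`.
#' @param dvdt_crit derivative criterion, mV/ms.
#' @param junction_potential_mV reported as an annotation column; it is
#'   never applied to the measured values (the study reports uncorrected
#'   potentials; the calculated correction is -15.8 mV).
#' @return one-row data.frame of all extracted features + QC verdict.
#' @export
extract_cell_features <- function(passive_sweeps, fi_sweeps = NULL,
                                  rebound_sweeps = NULL,
                                  V_rest = NULL, R_S = NULL,
                                  dvdt_crit = 20,
                                  junction_potential_mV = -15.8) {
  pp <- measure_passive(passive_sweeps, dvdt_crit = dvdt_crit)
  if (is.null(V_rest)) V_rest <- pp$V_rest
  if (is.null(R_S)) R_S <- passive_sweeps$R_S
  qc <- qc_filter(V_rest, R_S)

  ap <- list(threshold = NA_real_, amplitude = NA_real_,
             half_width = NA_real_, latency = NA_real_,
             AHP_amplitude = NA_real_)
  if (isTRUE(pp$rheobase_defined)) {
    k <- which(passive_sweeps$current_pA == pp$rheobase)[1]
    ap <- ap_features(passive_sweeps$voltage[, k], passive_sweeps$dt_s,
                      passive_sweeps$onset_s, passive_sweeps$offset_s,
                      dvdt_crit = dvdt_crit)
  }
  fi <- if (!is.null(fi_sweeps)) fi_curve(fi_sweeps, dvdt_crit) else
    list(max_frequency = NA_real_, fi_slope = NA_real_)
  rb <- list(n_spikes = NA_integer_, duration_ms = NA_real_)
  if (!is.null(rebound_sweeps)) {
    k <- which.min(rebound_sweeps$current_pA)
    rb <- rebound_analysis(rebound_sweeps$voltage[, k],
                           rebound_sweeps$dt_s, rebound_sweeps$onset_s,
                           rebound_sweeps$offset_s,
                           rebound_sweeps$current_pA[k],
                           dvdt_crit = dvdt_crit)
  }
  data.frame(qc_pass = qc$pass,
             qc_reason = paste(qc$reason, collapse = "; "),
             V_rest = V_rest, R_S = R_S,
             R_in = pp$R_in, tau_m = pp$tau_m,
             sag_percent = pp$sag_percent, rheobase = pp$rheobase,
             ap_threshold = ap$threshold, ap_amplitude = ap$amplitude,
             ap_half_width = ap$half_width, ap_latency = ap$latency,
             ahp_amplitude = ap$AHP_amplitude,
             max_frequency = fi$max_frequency, fi_slope = fi$fi_slope,
             rebound_n_spikes = rb$n_spikes,
             rebound_duration_ms = rb$duration_ms,
             junction_potential_mV = junction_potential_mV)
}
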