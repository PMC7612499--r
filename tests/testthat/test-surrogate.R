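test_that("a default beat has four phases and plausible haemodynamics", {
  beat <- simulate_beat(surrogate_lv_config(), tanh_params())
  m <- beat$markers
  expect_true(m$av_open < m$av_close)
  expect_true(m$av_close < m$mv_open)
  bm <- beat_biomarkers(beat)
  expect_gt(bm$Pmax, 60); expect_lt(bm$Pmax, 200)
  expect_gt(bm$SV, 20)
  expect_gt(bm$tauVD, 0); expect_gt(bm$tauVR, 0)
})

test_that("near-zero active stress yields a degenerate beat", {
  expect_error(
    simulate_beat(surrogate_lv_config(), tanh_params(Smax_ref = 1e-6)),
    "degenerate beat")
})

test_that("peak pressure increases with the stress scale (paired runs)", {
  b1 <- simulate_beat(surrogate_lv_config(), tanh_params(Smax_ref = 38))
  b2 <- simulate_beat(surrogate_lv_config(), tanh_params(Smax_ref = 76))
  expect_gt(max(b2$P$values), max(b1$P$values))
})

test_that("parameter-to-biomarker dependencies are monotone", {
  # the property that makes the fixed-point updates contract
  bm_of <- function(tp = tanh_params(), vv = valve_params())
    beat_biomarkers(simulate_beat(surrogate_lv_config(), tp, vv))
  b0 <- bm_of()
  up <- bm_of(tanh_params(Smax_ref = 45))
  expect_gt(up$Pmax, b0$Pmax)
  up <- bm_of(tanh_params(tauSR_ref = 140))
  expect_lt(up$dPdt_max, b0$dPdt_max)          # slower rise, flatter upstroke
  up <- bm_of(tanh_params(tauSD = 60))
  expect_gt(up$dPdt_min, b0$dPdt_min)          # slower decay, less steep
  up <- bm_of(tanh_params(tCR = 580))
  expect_gt(up$PTD90, b0$PTD90)
  up <- bm_of(vv = valve_params(R_AVf = 90))
  expect_gt(up$tauVD, b0$tauVD)
  up <- bm_of(vv = valve_params(R_MVf = 60))
  expect_gt(up$tauVR, b0$tauVR)
})

test_that("volume is conserved over a periodic beat and leak stays bounded", {
  beat <- simulate_beat(surrogate_lv_config(), tanh_params(),
                        max_beats = 30, beat_tol = 1e-4)
  bm <- beat_biomarkers(beat)
  # net volume change over the full cycle below 0.5% of stroke volume
  expect_lt(abs(beat$net_volume_change), 0.005 * bm$SV)
  # during isovolumetric phases only the finite backward-resistance leak
  # moves volume: |dV/dt| <= (P range across closed valves) / R_b
  v <- beat$V$values; p <- beat$P$values; dt <- beat$V$dt
  m <- beat$markers
  ivc <- which(trace_times(beat$V) > 2 & trace_times(beat$V) < m$av_open)
  if (length(ivc) > 3) {
    dv <- abs(diff(v[ivc]) / dt)
    bound <- (max(p) + 100) / 1000  # generous leak bound, mL/ms
    expect_true(all(dv <= bound))
  }
})

test_that("nodal ensembles degenerate correctly and medians are robust", {
  beat <- simulate_beat(surrogate_lv_config(), tanh_params())
  # zero heterogeneity: all nodes identical to the beat
  ens0 <- nodal_ensemble(beat, n_nodes = 5,
                         heterogeneity = list(act_spread = 0, amp_cv = 0,
                                              stretch_sd = 0), seed = 1)
  expect_equal(ens0$sa[[3]]$values, beat$sa$values)
  expect_equal(ens0$activation_times, rep(0, 5))
  med <- align_and_median(ens0$sa, ens0$activation_times)
  expect_equal(med$values, beat$sa$values)
  # activation jitter only: aligned median recovers the beat exactly
  ens1 <- nodal_ensemble(beat, n_nodes = 7,
                         heterogeneity = list(act_spread = 40, amp_cv = 0,
                                              stretch_sd = 0), seed = 2)
  med1 <- align_and_median(ens1$sa, ens1$activation_times)
  expect_equal(trace_at(med1, c(100, 200, 300)),
               trace_at(beat$sa, c(100, 200, 300)), tolerance = 1e-9)
  # 10% lognormal amplitude noise: median within 2% of the beat (n = 101)
  ens2 <- nodal_ensemble(beat, n_nodes = 101,
                         heterogeneity = list(act_spread = 0, amp_cv = 0.1,
                                              stretch_sd = 0), seed = 3)
  med2 <- align_and_median(ens2$sa, ens2$activation_times)
  i <- which(beat$sa$values > 0.2 * max(beat$sa$values))
  rel <- abs(med2$values[i] - beat$sa$values[i]) / beat$sa$values[i]
  expect_lt(max(rel), 0.02)
})

test_that("synthetic clinical data is deterministic and bounded by its noise", {
  s1 <- synthetic_clinical_data(noise_frac = 0.1, seed = 7)
  s2 <- synthetic_clinical_data(noise_frac = 0.1, seed = 7)
  expect_identical(unlist(s1$biomarkers), unlist(s2$biomarkers))
  clean <- unlist(s1$clean_biomarkers)
  noisy <- unlist(s1$biomarkers)
  expect_true(all(abs(noisy - clean) <= 0.1 * abs(clean) + 1e-12))
  s0 <- synthetic_clinical_data(noise_frac = 0, seed = 7)
  expect_equal(unlist(s0$biomarkers), unlist(s0$clean_biomarkers))
})

test_that("resistance unit conversion multiplies by 1000", {
  expect_equal(convert_resistance_s_to_ms(0.0125), 12.5)
})
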