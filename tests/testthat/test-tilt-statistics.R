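test_that("step segmentation tiles the recording exactly with a settle exclusion", {
  prot <- default_protocol(step_duration_s = 60)
  ch <- pressure_channel("ICP", rnorm(13 * 60 * 50), 50)
  seg <- segment_steps(ch, settle_time_s = 0, protocol = prot)
  expect_equal(nrow(seg), 13L)
  expect_equal(seg$start_idx[1L], 1L)
  expect_equal(seg$end_idx[13L], 13L * 60L * 50L)
  expect_equal(seg$start_idx[-1L], seg$end_idx[-13L] + 1L)
  expect_equal(seg$end_idx - seg$start_idx + 1L, rep(3000L, 13L))
  seg60 <- segment_steps(ch, settle_time_s = 6, protocol = prot)
  expect_equal(seg60$end_idx - seg60$analysis_start_idx + 1L, rep(2700L, 13L))
  expect_error(
    segment_steps(ch, settle_time_s = 60, protocol = prot),
    "shorter than the shortest step"
  )
  short <- pressure_channel("ICP", rnorm(100), 50)
  expect_error(segment_steps(short, protocol = prot, settle_time_s = 0), "longer than the recording")
})

test_that("step means reduce constants and ramps exactly", {
  r <- list(analysis_start_idx = 1L, end_idx = 1000L)
  expect_equal(step_mean(rep(16.8, 1000), r), 16.8)
  ramp <- seq(10, 20, length.out = 1000)
  expect_within(step_mean(ramp, r), 15, 0.01)
  expect_error(step_mean(rep(1, 10), list(analysis_start_idx = 5L, end_idx = 20L)), "beyond")
})

test_that("the noise-free pipeline recovers generator step means to 0.01 mmHg", {
  # full-length 600 s steps: the step mean is insensitive to the zero-phase
  # filter's boundary smear only when the window is long relative to it
  specs <- list(
    cABP = clean_spec("cABP", 80.4, 18.8, -0.66),
    ICP = clean_spec("ICP", 16.8, 2.6, -0.45,
      resonances = list(c(4.2, 0.05)), lowpass_order = 1L
    )
  )
  cfg <- sim_cohort_config(
    n_subjects = 1, fs = 50, protocol = default_protocol(600),
    channel_specs = specs, seed = 21, between_subject_sd = 0,
    n_harmonics = 15, source_noise_frac = 0, settle_tau_s = 0
  )
  co <- generate_cohort(cfg)
  summ <- summarize_steps(co$recordings[[1L]], target_fs = 50, settle_time_s = 60)
  truth <- co$truth$step_means
  joined <- merge(summ, truth,
    by.x = c("subject_id", "channel", "label"),
    by.y = c("subject_id", "channel", "label")
  )
  expect_equal(nrow(joined), 26L)
  expect_lt(max(abs(joined$mean_pressure - joined$mean_true)), 0.01)
})

test_that("deltas are relative to the first baseline and sum to the algebraic identity", {
  s <- tibble::tibble(
    subject_id = "S01", channel = "ICP",
    label = c("0_1", "+13", "0_2", "-13", "0_3"),
    angle = c(0, 13, 0, -13, 0),
    mean_pressure = c(16.8, 10.9, 17.7, 27.6, 20.8)
  )
  d <- deltas_from_baseline(s)
  expect_equal(d$delta_from_baseline[1L], 0)
  expect_equal(d$delta_from_baseline[2L], 10.9 - 16.8)
  expect_equal(
    sum(d$delta_from_baseline),
    nrow(s) * (mean(s$mean_pressure) - s$mean_pressure[1L])
  )
  # a cohort baseline of 80.4 with a +13 step mean of 71.8 gives -8.6
  s2 <- s
  s2$mean_pressure[1:2] <- c(80.4, 71.8)
  expect_equal(deltas_from_baseline(s2)$delta_from_baseline[2L], -8.6)
  expect_error(deltas_from_baseline(s[-1L, ]), "no step labeled")
})

test_that("perfectly linear statistics give |r| = 1 with the right sign", {
  prot <- default_protocol(60)
  s <- tidyr::expand_grid(
    subject_id = c("S01", "S02"),
    tibble::tibble(label = prot$label, angle = prot$angle)
  )
  s$channel <- "ICP"
  s$mean_pressure <- 16.8 - 0.45 * s$angle
  s$pulse_amplitude <- 2.6
  s <- deltas_from_baseline(s)
  r <- correlate_with_angle(s, "mean")
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_equal(r$strength, "strong")
  # zero-variance pulse statistic is undefined, with a warning
  expect_warning(rp <- correlate_with_angle(s, "pulse"), "zero variance")
  expect_true(is.na(rp$r))
})

test_that("correlation is invariant to affine rescaling of pressures and angles", {
  set.seed(5)
  prot <- default_protocol(60)
  s <- tibble::tibble(
    subject_id = "S01", channel = "ICP", label = prot$label, angle = prot$angle,
    mean_pressure = 16.8 - 0.45 * prot$angle + rnorm(13, 0, 0.8),
    pulse_amplitude = 2.6
  )
  r1 <- correlate_with_angle(s, "mean")$r
  s2 <- s
  s2$mean_pressure <- 3.7 * s$mean_pressure - 120
  expect_equal(correlate_with_angle(s2, "mean")$r, r1, tolerance = 1e-12)
  s3 <- s
  s3$angle <- 2 * s$angle + 1
  expect_equal(correlate_with_angle(s3, "mean")$r, r1, tolerance = 1e-12)
})

test_that("strength classification switches exactly at |r| = 0.3 and 0.7", {
  expect_equal(
    classify_correlation(c(0.7, 0.699999, 0.3, 0.300001, -0.7, -0.3, 0, NA)),
    c("strong", "mild", "weak", "mild", "strong", "weak", "weak", NA)
  )
})

test_that("correlation p-values are uniform under the null (KS oracle)", {
  set.seed(33)
  prot <- default_protocol(60)
  pvals <- replicate(400, {
    s <- tibble::tibble(
      subject_id = "S01", channel = "ICP", label = prot$label, angle = prot$angle,
      mean_pressure = rnorm(13), pulse_amplitude = 1
    )
    correlate_with_angle(s, "mean")$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("cohort correlations recover the sign of the hydrostatic slope", {
  # seeded grid over slopes large enough to dominate the noise in step means
  specs <- default_channel_specs(noise_sd = 1, artifact_rate = 2)[c("cABP", "ICP", "ITP", "IVP")]
  cfg <- scaled_cohort_config(
    n_subjects = 3, seed = 17, channel_specs = specs,
    protocol = default_protocol(30)
  )
  co <- generate_cohort(cfg)
  summ <- cohort_step_summaries(co, settle_time_s = 10)
  r <- correlate_with_angle(summ, "mean")
  slopes <- vapply(specs, function(s) s$hydro_slope, numeric(1))
  for (ch in names(specs)) {
    expect_equal(sign(r$r[r$channel == ch]), sign(slopes[[ch]]))
  }
  expect_equal(r$strength[r$channel == "ICP"], "strong")
})

test_that("paired tests handle degenerate inputs and match t.test otherwise", {
  s <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:6),
    tibble::tibble(label = c("0_1", "+13"), angle = c(0, 13))
  )
  s$channel <- "ICP"
  s$mean_pressure <- rep(c(16, 11), 6)
  s$pulse_amplitude <- 1
  # constant offset, zero within-pair variance: the limit t = Inf, p = 0
  res <- paired_test(s, "0_1", "+13", "ICP")
  expect_equal(res$t, Inf)
  expect_equal(res$p, 0)
  # identical pairs: t = 0, p = 1
  s$mean_pressure <- rep(16, 12)
  res0 <- paired_test(s, "0_1", "+13", "ICP")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # generic data agrees with stats::t.test
  set.seed(8)
  a <- rnorm(6, 16)
  b <- rnorm(6, 11)
  s$mean_pressure <- as.vector(rbind(a, b))
  res1 <- paired_test(s, "0_1", "+13", "ICP")
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res1$t, unname(ref$statistic))
  expect_equal(res1$p, ref$p.value)
})

test_that("paired t-test power matches the noncentral-t oracle", {
  # d_i ~ N(1, 1), n = 6: power = P(|T_5(ncp = sqrt(6))| > t_crit)
  n <- 6
  tcrit <- qt(0.975, n - 1)
  ncp <- sqrt(n) * 1
  power_true <- 1 - pt(tcrit, n - 1, ncp) + pt(-tcrit, n - 1, ncp)
  set.seed(55)
  reps <- 10000
  rej <- 0L
  for (i in seq_len(reps)) {
    d <- rnorm(n, 1, 1)
    res <- tiltpress:::.paired_t(d, rep(0, n))
    if (res$p < 0.05) rej <- rej + 1L
  }
  expect_within(rej / reps, power_true, 0.03)
})

test_that("the paired-test matrix covers consecutive steps and baseline contrasts", {
  set.seed(2)
  prot <- default_protocol(60)
  s <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:4),
    tibble::tibble(label = prot$label, angle = prot$angle)
  )
  s$channel <- "ICP"
  s$mean_pressure <- 16.8 - 0.45 * s$angle + rnorm(nrow(s), 0, 0.5)
  s$pulse_amplitude <- 1
  m <- paired_test_matrix(s, "ICP")
  expect_equal(sum(m$comparison == "consecutive"), 12L)
  expect_equal(sum(m$comparison == "vs_baseline"), 12L)
  expect_true(all(m$p >= 0 & m$p <= 1))
})

test_that("OLS regression of deltas on angle recovers the generator slope", {
  prot <- default_protocol(60)
  s <- tidyr::expand_grid(
    subject_id = c("S01", "S02"),
    tibble::tibble(label = prot$label, angle = prot$angle)
  )
  set.seed(61)
  s$channel <- "ICP"
  s$mean_pressure <- 16.8 - 0.45 * s$angle + rnorm(nrow(s), 0, 0.01)
  s$pulse_amplitude <- 1
  s <- deltas_from_baseline(s)
  fit <- regress_vs_angle(s)
  expect_within(fit$slope_mmhg_per_deg, -0.45, 0.005)
  expect_within(fit$intercept_mmhg, 0, 0.05)
})

test_that("hydrostatic trigonometry matches the printed column and pressure", {
  pred <- hydrostatic_predict(sensor_geometry(70.0), angle = 13)
  expect_equal(round(pred$column_height_cm, 1), 15.7)
  expect_equal(round(pred$pressure_offset_mmhg, 1), 11.6)
  # zero angle gives a zero column; the sign flips with the angle
  p0 <- hydrostatic_predict(sensor_geometry(70.0), angle = 0)
  expect_equal(p0$column_height_cm, 0)
  expect_equal(p0$pressure_offset_mmhg, 0)
  pneg <- hydrostatic_predict(sensor_geometry(70.0), angle = -13)
  expect_equal(pneg$column_height_cm, -pred$column_height_cm)
  expect_error(hydrostatic_predict(sensor_geometry(70.0), angle = 100), "90")
})
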