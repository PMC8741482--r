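test_that("ROI extraction averages pixels and validates bounds", {
  frames <- array(7, dim = c(16, 16, 5))
  tr <- extract_roi_trace(frames, roi = c(2, 5, 2, 5),
                          frame_interval = 1.1)
  expect_true(all(tr$f == 7))
  expect_equal(tr$time_s, (0:4) * 1.1)
  expect_error(extract_roi_trace(frames, roi = c(2, 20, 2, 5),
                                 frame_interval = 1.1), "bounds")
  expect_error(extract_roi_trace(array(1, dim = c(4, 4, 1)),
                                 roi = c(1, 2, 1, 2),
                                 frame_interval = 1.1), "2 frames")
  expect_warning(extract_roi_trace(frames, roi = c(1, 2, 1, 2)),
                 "1.1 s")
})

test_that("delta_f subtracts the pre-wound baseline frame", {
  tr <- simulate_trace(repair_sim_config(tau = Inf, k_a0 = 50,
                                         noise_sd = 0))
  cv <- delta_f(tr)
  expect_equal(attr(cv, "f0"), 100)
  expect_equal(cv$delta_f[1], 0) # the wound frame itself
  # noise-free deficient curve is linear with per-second slope k_a0
  expect_equal(cv$delta_f, 50 * cv$t_post, tolerance = 1e-12)
  # constant trace -> all-zero deltas
  flat <- delta_f(simulate_trace(repair_sim_config(k_a0 = 0,
                                                   noise_sd = 0)))
  expect_true(all(flat$delta_f == 0))
})

test_that("subsampling picks every 10th frame at 11 s spacing", {
  cv <- delta_f(simulate_trace(repair_sim_config(noise_sd = 0)))
  sub <- cv[cv$subsampled, ]
  expect_equal(unique(round(diff(sub$t_post), 9)), 11.0)
  wf <- attr(cv, "wound_frame")
  expect_equal(sub$frame, seq(wf, max(cv$frame), by = 10))
  # subsampled points equal the full series at those indices
  expect_equal(sub$delta_f, cv$delta_f[match(sub$frame, cv$frame)])
})

test_that("wound-frame detection finds the largest intensity jump", {
  tr <- simulate_trace(repair_sim_config(tau = 10, k_a0 = 50,
                                         noise_sd = 0))
  expect_equal(detect_wound_frame(tr), attr(tr, "wound_frame"))
  # with noise, the influx onset jump (~83 units here) dominates the
  # noise-level jumps elsewhere
  noisy <- simulate_trace(repair_sim_config(tau = 10, k_a0 = 80,
                                            noise_sd = 5), seed = 3)
  expect_equal(detect_wound_frame(noisy), attr(noisy, "wound_frame"))
})

test_that("a wound frame without a pre-wound frame is an error", {
  tr <- simulate_trace(repair_sim_config(noise_sd = 0))
  expect_error(delta_f(tr, wound_frame = 1), "pre-wound")
  expect_error(delta_f(tr, wound_frame = 1000), "beyond")
})

test_that("noise-free linear data select the deficient model exactly", {
  cv <- delta_f(simulate_trace(repair_sim_config(tau = Inf, k_a0 = 37.5,
                                                 noise_sd = 0)))
  fit <- fit_kinetics(cv)
  expect_equal(fit$model, "deficient")
  expect_equal(fit$k_a0, 37.5, tolerance = 1e-6) # 6 significant digits
  expect_equal(fit$tau, Inf)
})

test_that("noise-free saturating data recover tau and k_a0", {
  cv <- delta_f(simulate_trace(repair_sim_config(tau = 10, k_a0 = 50,
                                                 noise_sd = 0)))
  fit <- fit_kinetics(cv)
  expect_equal(fit$model, "proficient")
  expect_equal(fit$tau, 10, tolerance = 1e-4)
  expect_equal(fit$k_a0, 50, tolerance = 1e-4)
  expect_equal(fit$plateau_delta_f, 500, tolerance = 1e-3)
})

test_that("tau far beyond the horizon is indistinguishable from linear", {
  cv <- delta_f(simulate_trace(repair_sim_config(tau = 1e6, k_a0 = 50,
                                                 noise_sd = 0)))
  fit <- fit_kinetics(cv)
  expect_equal(fit$model, "deficient")
})

test_that("tau is recovered from noisy traces in most seeded runs", {
  hits <- vapply(1:20, function(s) {
    cfg <- repair_sim_config(tau = 10, k_a0 = 50, noise_sd = 25)
    fit <- fit_kinetics(delta_f(simulate_trace(cfg, seed = 700 + s)))
    fit$model == "proficient" && abs(fit$tau - 10) / 10 <= 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("end-to-end stack pipeline recovers the generating kinetics", {
  cfg <- repair_sim_config(tau = 10, k_a0 = 50, noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(simulate_stack(cfg, seed = 19), path)
  fit <- fit_kinetics(delta_f(extract_roi_trace(path)))
  expect_equal(fit$model, "proficient")
  expect_lt(abs(fit$tau - 10) / 10, 0.05)
  expect_lt(abs(fit$k_a0 - 50) / 50, 0.05)
})

test_that("repair classification applies the horizon/3 rule strictly", {
  cv <- delta_f(simulate_trace(repair_sim_config(tau = 10, noise_sd = 0)))
  fit <- fit_kinetics(cv)
  expect_equal(classify_repair(fit, horizon = 180), "proficient")
  expect_equal(classify_repair(fit, horizon = fit$tau * 3), "deficient")
  lin <- fit_kinetics(delta_f(simulate_trace(
    repair_sim_config(tau = Inf, noise_sd = 0))))
  expect_equal(classify_repair(lin), "deficient")
})

test_that("tidy and glance summarize kinetic fits", {
  fit <- fit_kinetics(delta_f(simulate_trace(
    repair_sim_config(tau = 10, k_a0 = 50, noise_sd = 0))))
  td <- tidy(fit)
  expect_equal(td$term, c("k_a0", "tau", "offset", "plateau_delta_f"))
  gl <- glance(fit)
  expect_equal(gl$model, "proficient")
  expect_true(gl$aicc_proficient < gl$aicc_deficient)
})

test_that("group comparison separates phenotypes and guards its inputs", {
  make_group <- function(tau, seeds) {
    lapply(seeds, function(s) {
      delta_f(simulate_trace(repair_sim_config(tau = tau, k_a0 = 50,
                                               noise_sd = 25), seed = s))
    })
  }
  prof <- make_group(10, 800 + 1:15)
  defi <- make_group(Inf, 900 + 1:15)
  cmp <- compare_groups(prof, defi, "proficient", "deficient")
  expect_lt(cmp$test$p, 0.001)
  expect_equal(cmp$test$stars, "***")
  expect_gt(cmp$test$endpoint_mean_b, cmp$test$endpoint_mean_a)
  expect_equal(cmp$test$n_a, 15)
  expect_error(compare_groups(prof[1], defi), "at least 2")
  short <- make_group(10, 1:2)
  short[[1]] <- delta_f(simulate_trace(
    repair_sim_config(tau = 10, n_frames = 80, noise_sd = 0)))
  expect_error(compare_groups(short, defi), "time grid")
})

test_that("matched groups under identical configs rarely differ", {
  reps <- vapply(1:10, function(r) {
    g1 <- lapply(1:4, function(s) {
      delta_f(simulate_trace(repair_sim_config(tau = 10, noise_sd = 25),
                             seed = 2000 + 10 * r + s))
    })
    g2 <- lapply(1:4, function(s) {
      delta_f(simulate_trace(repair_sim_config(tau = 10, noise_sd = 25),
                             seed = 3000 + 10 * r + s))
    })
    compare_groups(g1, g2)$test$p
  }, numeric(1))
  expect_gte(mean(reps > 0.05), 0.9)
})
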