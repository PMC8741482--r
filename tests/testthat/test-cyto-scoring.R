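test_that("gmfi matches closed-form examples and is scale-equivariant", {
  expect_equal(as.numeric(gmfi(c(4, 9))), 6)
  expect_equal(as.numeric(gmfi(c(10, 1000))), 100)
  withr::with_seed(5, x <- rlnorm(50, 3, 1))
  for (c_ in c(0.1, 2, 1000)) {
    expect_equal(as.numeric(gmfi(c_ * x)), c_ * as.numeric(gmfi(x)),
                 tolerance = 1e-12)
  }
})

test_that("gmfi excludes non-positive values with a reported count", {
  expect_warning(g <- gmfi(c(4, 9, 0, -2)), "2 non-positive")
  expect_equal(as.numeric(g), 6)
  expect_equal(attr(g, "n_excluded"), 2)
  expect_error(suppressWarnings(gmfi(c(0, -1))), "no positive")
})

test_that("gating keeps live transfected cells when populations separate", {
  cfg <- cyto_sim_config(n_events = 10000, p_pm = 1)
  ev <- simulate_events(cfg, seed = 81)
  ctrl <- simulate_events(
    cyto_sim_config(n_events = 10000, frac_transfected = 0), seed = 82)
  # fixed cutoff in the gap between autofluorescence and reporter signal:
  # the well-separated case
  gated <- gate_events(ev, gating_config(dsred_cutoff = 800))
  # brute-force check against the simulation truth columns
  expect_true(all(gated$truth_dead == 0))
  expect_gt(mean(gated$truth_transfected), 0.99)
  # quantile-of-control rule admits (1 - quantile) of the background by
  # construction, still a nearly pure transfected population
  gated_q <- gate_events(ev, gating_config(), control = ctrl)
  expect_gt(mean(gated_q$truth_transfected), 0.95)
  info <- attr(gated_q, "gating")
  expect_equal(info$n_input, 10000)
  expect_equal(info$n_survivors, nrow(gated_q))
  expect_equal(info$n_input - info$n_removed_dead -
                 info$n_removed_dsred_negative, info$n_survivors)
})

test_that("degenerate populations raise gating errors", {
  ev <- simulate_events(cyto_sim_config(n_events = 1000, frac_dead = 1),
                        seed = 91)
  expect_error(gate_events(ev, gating_config(dsred_cutoff = 1)),
               class = "dysfscreen_gating_error")
  ev2 <- simulate_events(cyto_sim_config(n_events = 1000), seed = 92)
  expect_error(
    gate_events(ev2, gating_config(dapi_cutoff = 1e-300,
                                   dsred_cutoff = 1e12)),
    class = "dysfscreen_gating_error")
})

test_that("a population scored against itself gives exactly 1", {
  ev <- simulate_events(cyto_sim_config(n_events = 5000), seed = 101)
  ctrl <- simulate_events(
    cyto_sim_config(n_events = 5000, frac_transfected = 0), seed = 102)
  r <- two_a_value(ev, ev, gating_config(), control = ctrl)
  expect_identical(r$value, 1)
  expect_equal(r$raw_ratio, r$gmfi_far_red / r$gmfi_dsred)
})

test_that("a common far-red gain cancels to machine precision", {
  wt <- simulate_events(cyto_sim_config(n_events = 5000, p_pm = 1),
                        seed = 111)
  mut <- simulate_events(cyto_sim_config(n_events = 5000, p_pm = 0.3),
                         seed = 112)
  ctrl <- simulate_events(
    cyto_sim_config(n_events = 5000, frac_transfected = 0), seed = 113)
  base <- two_a_value(mut, wt, gating_config(), control = ctrl)
  for (g in c(0.01, 7, 1e4)) {
    mut_g <- dplyr::mutate(mut, far_red = far_red * g)
    wt_g <- dplyr::mutate(wt, far_red = far_red * g)
    scaled <- two_a_value(mut_g, wt_g, gating_config(), control = ctrl)
    expect_equal(scaled$value, base$value, tolerance = 1e-12)
  }
})

test_that("the score estimates the true membrane fraction", {
  # oracle: analytic expectation of the generative model is p_pm; a
  # 1e6-event brute-force run under these defaults gave 0.516 for
  # p_pm = 0.5 (small upward bias from additive autofluorescence)
  b <- sim_batch(p_pm = 0.5, n_reps = 1, n_events = 10000, seed = 121)
  r <- two_a_value(b$mut[[1]], b$wt[[1]], gating_config(),
                   control = b$ctrl)
  expect_lt(abs(r$value - 0.5), 0.05)
})

test_that("replicate scoring returns spread, p value and stars", {
  b <- sim_batch(p_pm = 0.1, n_reps = 3, n_events = 5000, seed = 131)
  res <- two_a_replicates(b$mut, b$wt, gating_config(), control = b$ctrl)
  expect_equal(res$n_replicates, 3)
  expect_gt(res$sd_value, 0) # independent seeded simulations vary
  expect_lt(res$mean_value, 0.25)
  expect_lt(res$p_vs_wt, 0.001)
  expect_equal(res$stars, "***")
})

test_that("replicate_summary handles edge counts per contract", {
  expect_equal(replicate_summary(c(1, 1, 1)),
               tibble::tibble(mean = 1, sd = 0, n = 3L))
  expect_equal(replicate_summary(c(0, 2)),
               tibble::tibble(mean = 1, sd = sqrt(2), n = 2L))
  one <- replicate_summary(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_error(replicate_summary(numeric(0)), "at least one")
})

test_that("classification is strict at the threshold and clamps negatives", {
  out <- classify(tibble::tibble(
    label = c("a", "b", "c", "d"),
    mean_value = c(0.14, 1.0, 0.25, 0.2499)))
  expect_equal(out$defective, c(TRUE, FALSE, FALSE, TRUE))
  expect_warning(neg <- classify(c(-0.1, 0.5)), "clamped")
  expect_equal(neg$mean_value, c(0, 0.5))
  expect_true(neg$defective[1])
  expect_error(classify(0.5, threshold = 0), "threshold")
})

test_that("t-test matches closed cases and the permutation oracle", {
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")
  sep <- ttest_unpaired(c(0, 0, 0) + c(1e-6, -1e-6, 0),
                        c(1, 1, 1) + c(1e-6, 0, -1e-6))
  expect_lt(sep$p, 0.001)
  expect_equal(sep$stars, "***")
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")
  # permutation oracle on random small fixtures
  withr::with_seed(17, {
    for (i in 1:5) {
      a <- rnorm(6, 0, 1)
      b <- rnorm(6, runif(1, 0, 1.5), 1)
      p_t <- ttest_unpaired(a, b)$p
      p_perm <- perm_t_p(a, b, seed = i)
      expect_lt(abs(p_t - p_perm), 0.02)
    }
  })
})

test_that("ICC concordance flags exactly the flipped labels", {
  scores <- tibble::tibble(label = paste0("V", 1:10),
                           mean_value = c(seq(0.02, 0.2, length.out = 5),
                                          seq(0.4, 0.9, length.out = 5)))
  icc <- tibble::tibble(label = scores$label,
                        pm_localized = as.integer(scores$mean_value >= 0.25))
  clean <- icc_concordance(scores, icc)
  expect_equal(attr(clean, "n_discordant"), 0)
  icc_flip <- icc
  icc_flip$pm_localized[3] <- 1L
  flipped <- icc_concordance(scores, icc_flip)
  expect_equal(flipped$label[flipped$discordant], "V3")
  expect_equal(attr(flipped, "n_discordant"), 1)
})

test_that("discordant labels cluster near the threshold on a registry-like fixture", {
  # fixture mirroring the observed pattern: disagreements only in the
  # transition zone around 0.25
  scores <- tibble::tibble(
    label = c("T252M", "T881P", "R2042C", "V67D", "A170E", "L1341P"),
    mean_value = c(0.22, 0.27, 0.30, 0.05, 0.98, 0.10))
  icc <- tibble::tibble(
    label = scores$label,
    pm_localized = c(1L, 0L, 0L, 0L, 1L, 0L))
  out <- icc_concordance(scores, icc)
  expect_equal(sort(out$label[out$discordant]),
               c("R2042C", "T252M", "T881P"))
  rng <- attr(out, "discordant_range")
  expect_gte(rng[1], 0.2)
  expect_lte(rng[2], 0.35)
  # labels in one table only are listed, not an error
  extra <- icc_concordance(scores,
                           dplyr::bind_rows(icc, tibble::tibble(
                             label = "R555W", pm_localized = 0L)))
  expect_equal(attr(extra, "only_in_icc"), "R555W")
})
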