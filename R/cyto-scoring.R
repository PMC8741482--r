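#' Gating configuration
#'
#' Live, transfected cells are selected by two gates: DAPI below a cutoff
#' (membrane-impermeant DAPI stains dead cells) and DsRed above a cutoff
#' (DsRed marks transfected cells). By default the DsRed cutoff is the
#' 99.5th percentile of an untransfected control's DsRed distribution,
#' supplied to [gate_events()] as `control`; a fixed numeric cutoff may be
#' given instead. The DAPI cutoff defaults to 700 intensity units, matched
#' to the simulator's live/dead DAPI scales, and should be set from an
#' instrument's dead-cell distribution for real data.
#'
#' @param dapi_cutoff Positive number; events with `dapi` at or above it
#'   are removed as dead.
#' @param dsred_cutoff Positive number, or `NULL` to derive it from an
#'   untransfected control via `dsred_quantile`.
#' @param dsred_quantile Quantile of the control DsRed distribution used
#'   when `dsred_cutoff` is `NULL`.
#' @param min_events_after_gating Minimum surviving events; fewer is a
#'   gating error.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(dapi_cutoff = 700,
                          dsred_cutoff = NULL,
                          dsred_quantile = 0.995,
                          min_events_after_gating = 200) {
  check_number(dapi_cutoff, "dapi_cutoff", lower = .Machine$double.xmin)
  if (!is.null(dsred_cutoff)) {
    check_number(dsred_cutoff, "dsred_cutoff", lower = .Machine$double.xmin)
  }
  check_number(dsred_quantile, "dsred_quantile",
               lower = .Machine$double.eps, upper = 1 - .Machine$double.eps)
  min_events_after_gating <- check_count(min_events_after_gating,
                                         "min_events_after_gating")
  structure(
    list(dapi_cutoff = dapi_cutoff, dsred_cutoff = dsred_cutoff,
         dsred_quantile = dsred_quantile,
         min_events_after_gating = min_events_after_gating),
    class = "gating_config"
  )
}

#' Gate an event table to live, DsRed-positive cells
#'
#' Removes dead cells (`dapi >= dapi_cutoff`) then DsRed-negative cells
#' (`dsred <= dsred_cutoff`). The counts removed at each gate and the
#' cutoffs used are attached as the `"gating"` attribute of the result.
#'
#' @param events Event tibble with channels `dsred`, `far_red`, `dapi`.
#' @param config A [gating_config()].
#' @param control Untransfected-control event tibble, required when
#'   `config$dsred_cutoff` is `NULL`.
#' @return The surviving events, with a `"gating"` attribute
#'   (`n_input`, `n_removed_dead`, `n_removed_dsred_negative`,
#'   `n_survivors`, `dapi_cutoff`, `dsred_cutoff`).
#' @export
gate_events <- function(events, config = gating_config(), control = NULL) {
  stopifnot(inherits(config, "gating_config"))
  missing <- setdiff(event_channels, names(events))
  if (length(missing) > 0) {
    abort(sprintf("event table lacks required channel(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dsred_cutoff <- config$dsred_cutoff
  if (is.null(dsred_cutoff)) {
    if (is.null(control)) {
      abort(paste("dsred_cutoff is NULL and no untransfected `control`",
                  "table was supplied to derive it from"))
    }
    dsred_cutoff <- as.numeric(
      quantile(control$dsred, config$dsred_quantile, names = FALSE))
  }
  live <- events[events$dapi < config$dapi_cutoff, ]
  gated <- live[live$dsred > dsred_cutoff, ]
  info <- list(
    n_input = nrow(events),
    n_removed_dead = nrow(events) - nrow(live),
    n_removed_dsred_negative = nrow(live) - nrow(gated),
    n_survivors = nrow(gated),
    dapi_cutoff = config$dapi_cutoff,
    dsred_cutoff = dsred_cutoff
  )
  if (nrow(gated) < config$min_events_after_gating) {
    abort(sprintf(
      "gating error: only %d events survive (minimum %d); removed %d dead, %d DsRed-negative of %d",
      nrow(gated), config$min_events_after_gating, info$n_removed_dead,
      info$n_removed_dsred_negative, info$n_input),
      class = "dysfscreen_gating_error")
  }
  attr(gated, "gating") <- info
  gated
}

#' Geometric mean fluorescence intensity
#'
#' `exp(mean(log(x)))` over the positive values of `x`. Non-positive
#' intensities (for which the geometric mean is undefined) are excluded
#' with a warning; the excluded count is attached as the `"n_excluded"`
#' attribute.
#'
#' @param values Numeric vector of intensities.
#' @return The geometric mean (positive scalar) with attribute
#'   `n_excluded`.
#' @examples
#' gmfi(c(4, 9))    # 6
#' gmfi(c(10, 1000)) # 100
#' @export
gmfi <- function(values) {
  stopifnot(is.numeric(values))
  keep <- is.finite(values) & values > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warn(sprintf("gmfi: excluded %d non-positive value(s)", n_excluded))
  }
  if (sum(keep) == 0) {
    abort("gmfi: no positive values")
  }
  structure(exp(mean(log(values[keep]))), n_excluded = n_excluded)
}

#' Wild-type-normalized surface-expression score (the 2A value)
#'
#' The score of a mutant population is the ratio of its far-red
#' (surface-label) gMFI to its DsRed gMFI, computed on gated live
#' DsRed-positive events, divided by the same ratio for the wild-type
#' population measured alongside it:
#' `value = (gMFI_far_red(mut)/gMFI_dsred(mut)) /
#'          (gMFI_far_red(wt)/gMFI_dsred(wt))`.
#' A population scored against itself gives exactly 1, and rescaling one
#' channel by a common gain in both populations leaves the value unchanged.
#'
#' @param mut_events,wt_events Event tibbles for the mutant and wild-type
#'   populations.
#' @param config A [gating_config()].
#' @param control Optional untransfected control passed to [gate_events()].
#' @return A one-row tibble: `gmfi_far_red`, `gmfi_dsred`, `raw_ratio`
#'   (mutant), `wt_raw_ratio`, `value`, `n_events`, `n_events_wt`.
#' @export
two_a_value <- function(mut_events, wt_events, config = gating_config(),
                        control = NULL) {
  gate_pop <- function(ev, pop) {
    tryCatch(gate_events(ev, config, control), error = function(e) {
      abort(sprintf("[%s population] %s", pop, conditionMessage(e)),
            class = "dysfscreen_gating_error")
    })
  }
  mut <- gate_pop(mut_events, "mutant")
  wt <- gate_pop(wt_events, "wild-type")
  ratio <- function(ev, pop) {
    tryCatch(as.numeric(gmfi(ev$far_red)) / as.numeric(gmfi(ev$dsred)),
             error = function(e) {
               abort(sprintf("[%s population] %s", pop,
                             conditionMessage(e)))
             })
  }
  fr <- as.numeric(gmfi(mut$far_red))
  ds <- as.numeric(gmfi(mut$dsred))
  raw_mut <- fr / ds
  raw_wt <- ratio(wt, "wild-type")
  tibble::tibble(
    gmfi_far_red = fr,
    gmfi_dsred = ds,
    raw_ratio = raw_mut,
    wt_raw_ratio = raw_wt,
    value = raw_mut / raw_wt,
    n_events = nrow(mut),
    n_events_wt = nrow(wt)
  )
}

#' Replicate-level scoring of a mutant against wild type
#'
#' Scores each replicate pair (mutant vs the wild-type population measured
#' in the same batch/run, per-batch normalization) and summarizes across
#' replicates as mean and sample standard deviation. `p_vs_wt` is the
#' two-sided Student's unpaired equal-variance t-test comparing the
#' per-replicate raw far-red/DsRed ratios of the mutant and wild-type
#' populations (equivalent to the test on WT-normalized values, since a
#' common scale factor does not change the t statistic).
#'
#' @param mut_list,wt_list Lists of event tibbles, one per replicate;
#'   replicate `i` of the mutant is normalized to replicate `i` of the
#'   wild type.
#' @param config A [gating_config()].
#' @param control Optional untransfected control (a single table or a list
#'   parallel to the replicates).
#' @return A one-row tibble: `mean_value`, `sd_value` (`NA` for a single
#'   replicate), `n_replicates`, `p_vs_wt` (`NA` when n < 2), `stars`, and
#'   a `values` list-column of the per-replicate scores.
#' @export
two_a_replicates <- function(mut_list, wt_list, config = gating_config(),
                             control = NULL) {
  stopifnot(is.list(mut_list), is.list(wt_list),
            length(mut_list) == length(wt_list), length(mut_list) >= 1)
  n <- length(mut_list)
  ctrl_i <- function(i) if (is.data.frame(control) || is.null(control)) {
    control
  } else {
    control[[i]]
  }
  per_rep <- purrr::map(seq_len(n), function(i) {
    two_a_value(mut_list[[i]], wt_list[[i]], config, ctrl_i(i))
  })
  values <- purrr::map_dbl(per_rep, "value")
  raw_mut <- purrr::map_dbl(per_rep, "raw_ratio")
  raw_wt <- purrr::map_dbl(per_rep, "wt_raw_ratio")
  p <- if (n >= 2) ttest_unpaired(raw_mut, raw_wt)$p else NA_real_
  tibble::tibble(
    mean_value = mean(values),
    sd_value = if (n >= 2) sd(values) else NA_real_,
    n_replicates = n,
    p_vs_wt = p,
    stars = p_stars(p),
    values = list(values)
  )
}

#' Mean, standard deviation and n of replicate values
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator).
#' A single replicate returns its value with `sd = NA` (flagged
#' unavailable); an empty input is an error.
#'
#' @param values Numeric vector of replicate values.
#' @return A one-row tibble with `mean`, `sd`, `n`.
#' @examples
#' replicate_summary(c(0, 2)) # mean 1, sd sqrt(2)
#' @export
replicate_summary <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) == 0) {
    abort("replicate_summary: need at least one value")
  }
  tibble::tibble(
    mean = mean(values),
    sd = if (length(values) >= 2) sd(values) else NA_real_,
    n = length(values)
  )
}

#' Classify variants against the defective threshold
#'
#' A variant is classified membrane-localization defective when its mean
#' score is strictly below the threshold (default 0.25, i.e. 25% of wild
#' type -- the transition zone at which microscopy stops detecting
#' membrane-localized protein). Scores exactly at the threshold are
#' non-defective. Negative mean values are clamped to 0 with a warning.
#'
#' @param scores A tibble with columns `label` and `mean_value`, or a
#'   numeric vector of mean values (labels are then generated).
#' @param threshold Classification threshold in (0, 1\].
#' @return A tibble with `label`, `mean_value`, `defective`, `threshold`.
#' @examples
#' classify(tibble::tibble(label = c("L1341P", "A170E"),
#'                         mean_value = c(0.14, 0.98)))
#' @export
classify <- function(scores, threshold = 0.25) {
  check_number(threshold, "threshold", lower = .Machine$double.eps,
               upper = 1)
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      label = paste0("variant_", seq_along(scores)),
      mean_value = as.numeric(scores))
  }
  stopifnot(all(c("label", "mean_value") %in% names(scores)))
  mv <- scores$mean_value
  if (any(mv < 0)) {
    warn(sprintf("classify: clamped %d negative mean value(s) to 0",
                 sum(mv < 0)))
    mv <- pmax(mv, 0)
  }
  tibble::tibble(
    label = scores$label,
    mean_value = mv,
    defective = mv < threshold,
    threshold = threshold
  )
}

#' Student's unpaired t-test with star annotation
#'
#' Two-sided unpaired t-test, equal variances by default (classic
#' Student's test; set `var_equal = FALSE` for Welch).
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param var_equal Assume equal variances (default `TRUE`).
#' @return A one-row tibble with `t`, `df`, `p`, `stars`.
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("ttest_unpaired: each sample needs at least 2 values")
  }
  # guard the degenerate identical-constant case t.test() refuses
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p = 1,
                          stars = ""))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    stars = p_stars(tt$p.value)
  )
}

#' Concordance between scores and microscopy localization calls
#'
#' Compares the threshold call implied by the quantitative score
#' (`mean_value >= threshold` means membrane-localized) with a binary
#' immunocytochemistry (ICC) call, flagging discordant variants.
#'
#' @param scores Tibble with columns `label`, `mean_value`.
#' @param icc_labels Tibble with columns `label`, `pm_localized` (0/1).
#' @param threshold Score threshold (default 0.25).
#' @return A tibble over the shared labels with `mean_value`,
#'   `pm_localized`, `score_positive`, `discordant`; attributes
#'   `only_in_scores`, `only_in_icc` (labels present in one table only),
#'   `n_discordant`, and `discordant_range` (the score interval containing
#'   all discordant labels, `c(NA, NA)` when none).
#' @export
icc_concordance <- function(scores, icc_labels, threshold = 0.25) {
  stopifnot(all(c("label", "mean_value") %in% names(scores)),
            all(c("label", "pm_localized") %in% names(icc_labels)))
  shared <- dplyr::inner_join(scores, icc_labels, by = "label")
  if (nrow(shared) == 0) {
    abort("icc_concordance: no shared labels between the two tables")
  }
  out <- shared |>
    dplyr::mutate(
      score_positive = .data$mean_value >= threshold,
      discordant = .data$score_positive != (.data$pm_localized == 1)
    )
  disc <- out$mean_value[out$discordant]
  attr(out, "only_in_scores") <- setdiff(scores$label, icc_labels$label)
  attr(out, "only_in_icc") <- setdiff(icc_labels$label, scores$label)
  attr(out, "n_discordant") <- sum(out$discordant)
  attr(out, "discordant_range") <-
    if (length(disc) > 0) range(disc) else c(NA_real_, NA_real_)
  out
}
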