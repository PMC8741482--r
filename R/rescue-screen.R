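#' Summarize replicate scores per variant and condition
#'
#' Collapses a long table of per-replicate scores into one row per
#' (variant, condition) with the replicate values kept as a list-column,
#' the form consumed by [call_hit()] and [additivity_check()].
#'
#' @param data Tibble with columns `label`, `condition`, `value` (and
#'   optionally `replicate`).
#' @return A tibble with `label`, `condition`, `mean`, `sd`, `n`, `values`.
#' @export
summarize_conditions <- function(data) {
  stopifnot(all(c("label", "condition", "value") %in% names(data)))
  data |>
    dplyr::group_by(.data$label, .data$condition) |>
    dplyr::summarize(
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() >= 2, sd(.data$value), NA_real_),
      n = dplyr::n(),
      values = list(.data$value),
      .groups = "drop"
    )
}

#' Call a rescue hit for one variant and treatment
#'
#' A treatment is a hit for a defective variant when it lifts the mean
#' score to at least the classification threshold (`>=`, since defective
#' membership is strict `<`), the increase over vehicle is statistically
#' significant (Student's unpaired t-test, `p < alpha`), and the treated
#' mean exceeds the vehicle mean.
#'
#' @param vehicle,treated One-row condition summaries for the same variant
#'   (see [summarize_conditions()]), each with at least 2 replicates.
#' @param threshold Score threshold (default 0.25).
#' @param alpha Significance level for the vehicle comparison.
#' @return A one-row tibble: `label`, `condition`, `mean_treated`,
#'   `mean_vehicle`, `p_vs_vehicle`, `stars`, `threshold`, `hit`.
#' @export
call_hit <- function(vehicle, treated, threshold = 0.25, alpha = 0.05) {
  stopifnot(nrow(vehicle) == 1, nrow(treated) == 1)
  if (vehicle$label != treated$label) {
    abort(sprintf("variant labels differ: vehicle '%s' vs treated '%s'",
                  vehicle$label, treated$label))
  }
  v <- vehicle$values[[1]]
  t_ <- treated$values[[1]]
  if (length(v) < 2 || length(t_) < 2) {
    abort("call_hit: each condition needs at least 2 replicates")
  }
  p <- ttest_unpaired(t_, v)$p
  tibble::tibble(
    label = treated$label,
    condition = treated$condition,
    mean_treated = mean(t_),
    mean_vehicle = mean(v),
    p_vs_vehicle = p,
    stars = p_stars(p),
    threshold = threshold,
    hit = mean(t_) >= threshold && p < alpha && mean(t_) > mean(v)
  )
}

#' Call rescue hits across a whole screen
#'
#' Applies [call_hit()] to every (variant, treatment) pair in a long
#' replicate table, comparing each treatment against the variant's vehicle
#' condition.
#'
#' @param data Long tibble with columns `label`, `condition`, `value`.
#' @param vehicle Name of the vehicle condition (default `"vehicle"`).
#' @param threshold,alpha Passed to [call_hit()].
#' @return A tibble of hit calls, one row per variant x treatment.
#' @export
screen_hits <- function(data, vehicle = "vehicle", threshold = 0.25,
                        alpha = 0.05) {
  summ <- summarize_conditions(data)
  if (!vehicle %in% summ$condition) {
    abort(sprintf("no '%s' condition found in the data", vehicle))
  }
  veh <- summ[summ$condition == vehicle, ]
  trt <- summ[summ$condition != vehicle, ]
  purrr::map_dfr(seq_len(nrow(trt)), function(i) {
    v <- veh[veh$label == trt$label[i], ]
    if (nrow(v) != 1) {
      abort(sprintf("variant '%s' has no (or multiple) vehicle condition",
                    trt$label[i]))
    }
    call_hit(v, trt[i, ], threshold = threshold, alpha = alpha)
  })
}

#' Per-condition responder counts for a screen
#'
#' Tallies hits per treatment condition, variants responding to any
#' treatment, and variants responding to exactly one.
#'
#' @param hits Hit-call tibble from [screen_hits()]/[call_hit()].
#' @return A tibble with `condition` (including `"any"`) and
#'   `n_responders`.
#' @export
screen_summary <- function(hits) {
  per_cond <- hits |>
    dplyr::filter(.data$hit) |>
    dplyr::count(.data$condition, name = "n_responders")
  any_row <- tibble::tibble(
    condition = "any",
    n_responders = dplyr::n_distinct(hits$label[hits$hit]))
  dplyr::bind_rows(per_cond, any_row)
}

#' Compare a drug combination against the best single agent
#'
#' Operationalizes (non-)additivity as: the combination is "additive"
#' only if its mean score is significantly greater than the better of the
#' two single agents (mode `"max"`, the default). Mode `"sum"` instead
#' tests the combination against the sum of the single-agent effects over
#' vehicle and then requires a `vehicle` summary.
#'
#' @param drugA,drugB,combo One-row condition summaries for the same
#'   variant (see [summarize_conditions()]).
#' @param alpha Significance level.
#' @param mode `"max"` (default) or `"sum"`.
#' @param vehicle Vehicle condition summary, required for `mode = "sum"`.
#' @return A one-row tibble: `label`, `mean_combo`, `reference`,
#'   `mean_reference`, `p`, `verdict` (`"additive"` / `"non-additive"`).
#' @export
additivity_check <- function(drugA, drugB, combo, alpha = 0.05,
                             mode = c("max", "sum"), vehicle = NULL) {
  mode <- match.arg(mode)
  for (nm in c("drugA", "drugB", "combo")) {
    x <- get(nm)
    if (is.null(x) || !is.data.frame(x) || nrow(x) != 1) {
      abort(sprintf("additivity_check: condition '%s' is missing", nm))
    }
  }
  labels <- c(drugA$label, drugB$label, combo$label)
  if (length(unique(labels)) != 1) {
    abort(sprintf("conditions belong to different variants: %s",
                  paste(unique(labels), collapse = ", ")))
  }
  cv <- combo$values[[1]]
  if (mode == "max") {
    best <- if (drugA$mean >= drugB$mean) drugA else drugB
    p <- ttest_unpaired(cv, best$values[[1]])$p
    additive <- p < alpha && mean(cv) > best$mean
    ref_name <- best$condition
    ref_mean <- best$mean
  } else {
    if (is.null(vehicle)) {
      abort("additivity_check: mode 'sum' needs a `vehicle` summary")
    }
    expected <- vehicle$mean + (drugA$mean - vehicle$mean) +
      (drugB$mean - vehicle$mean)
    tt <- t.test(cv, mu = expected)
    p <- tt$p.value
    additive <- p >= alpha || mean(cv) > expected
    ref_name <- "sum_of_effects"
    ref_mean <- expected
  }
  tibble::tibble(
    label = combo$label,
    mean_combo = mean(cv),
    reference = ref_name,
    mean_reference = ref_mean,
    p = p,
    verdict = if (additive) "additive" else "non-additive"
  )
}

#' Treated-to-vehicle viability ratio
#'
#' Ratio of mean absorbances `mean(treated)/mean(vehicle)` with its
#' standard deviation propagated by the delta method:
#' `sd = ratio * sqrt(se_t^2/mean_t^2 + se_v^2/mean_v^2)` with
#' `se = sd/sqrt(n)` of each arm.
#'
#' @param treated_abs,vehicle_abs Numeric vectors of raw viability
#'   readings (e.g. tetrazolium absorbances).
#' @return A one-row tibble with `ratio` and `sd`.
#' @export
viability_relative <- function(treated_abs, vehicle_abs) {
  stopifnot(is.numeric(treated_abs), is.numeric(vehicle_abs),
            length(treated_abs) >= 1, length(vehicle_abs) >= 1)
  mv <- mean(vehicle_abs)
  if (mv <= 0) {
    abort("viability_relative: vehicle mean must be positive")
  }
  mt <- mean(treated_abs)
  ratio <- mt / mv
  se2 <- function(x) if (length(x) >= 2) sd(x)^2 / length(x) else 0
  sd_ratio <- sqrt(se2(treated_abs) / mv^2 + mt^2 * se2(vehicle_abs) / mv^4)
  tibble::tibble(ratio = ratio, sd = sd_ratio)
}

#' Rescue frequency per protein-domain family
#'
#' Tallies, for each domain family, how many classified-defective variants
#' were rescued by at least one treatment, with integer-rounded
#' percentages (ties away from zero). Also reports the two-sided Fisher
#' exact p for the C2 vs non-C2 2x2 table (attribute `fisher_p_c2`) when
#' both groups are present.
#'
#' @param hits Hit-call tibble ([screen_hits()]); a variant counts as
#'   rescued when any of its rows has `hit == TRUE`.
#' @param records Variant records with `label` and `family` columns (see
#'   [assign_domain()]); one row per variant under consideration.
#' @return A tibble with `level` (`"family"` for per-family rows,
#'   `"c2_split"` for the aggregate C2 vs non-C2 rows), `family`,
#'   `n_variants`, `n_rescued`, `percent`; attribute `fisher_p_c2`
#'   carries the Fisher p (or `NA`).
#' @export
domain_rescue_frequency <- function(hits, records) {
  stopifnot(all(c("label", "hit") %in% names(hits)),
            all(c("label", "family") %in% names(records)))
  unresolved <- setdiff(hits$label, records$label)
  if (length(unresolved) > 0) {
    abort(sprintf("hit label(s) not resolvable to a variant record: %s",
                  paste(unresolved, collapse = ", ")))
  }
  rescued_labels <- unique(hits$label[hits$hit])
  rec <- records |>
    dplyr::distinct(.data$label, .keep_all = TRUE) |>
    dplyr::mutate(rescued = .data$label %in% rescued_labels)
  per_family <- rec |>
    dplyr::group_by(family = .data$family) |>
    dplyr::summarize(n_variants = dplyr::n(),
                     n_rescued = sum(.data$rescued), .groups = "drop") |>
    dplyr::mutate(level = "family", .before = 1)
  c2_split <- rec |>
    dplyr::group_by(family = ifelse(.data$family == "C2", "C2", "non-C2")) |>
    dplyr::summarize(n_variants = dplyr::n(),
                     n_rescued = sum(.data$rescued), .groups = "drop") |>
    dplyr::mutate(level = "c2_split", .before = 1)
  out <- dplyr::bind_rows(per_family, c2_split) |>
    dplyr::mutate(percent = round_half_away(
      100 * .data$n_rescued / .data$n_variants))
  fisher_p <- NA_real_
  if (nrow(c2_split) == 2) {
    m <- with(c2_split, rbind(n_rescued, n_variants - n_rescued))
    fisher_p <- fisher.test(m)$p.value
  }
  attr(out, "fisher_p_c2") <- fisher_p
  out
}
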