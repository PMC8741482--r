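#' Extract an ROI mean-intensity trace from an image stack
#'
#' Computes the per-frame arithmetic mean of the pixel intensities inside
#' a rectangular region of interest placed adjacent to the wound site.
#' Frame times come from the stack's frame-interval metadata; when absent
#' the protocol default of 1.1 s is used with a warning.
#'
#' @param stack A `repair_stack` ([simulate_stack()]), a list from
#'   [read_stack()], a TIFF file path, or a height x width x frames array.
#' @param roi ROI rectangle `c(row_min, row_max, col_min, col_max)`
#'   (1-based inclusive); defaults to the stack's recorded ROI when
#'   available.
#' @param frame_interval Seconds per frame; overrides stack metadata.
#' @param wound_frame 1-based first wounded frame; overrides stack
#'   metadata.
#' @return A `repair_trace` tibble (`frame`, `time_s`, `f`).
#' @export
extract_roi_trace <- function(stack, roi = NULL, frame_interval = NULL,
                              wound_frame = NULL) {
  meta <- list(frame_interval = NULL, wound_frame = NULL, roi = NULL)
  if (is.character(stack)) {
    stack <- read_stack(stack)
  }
  if (inherits(stack, "repair_stack")) {
    frames <- stack$frames
    meta <- list(frame_interval = stack$config$frame_interval,
                 wound_frame = stack$config$wound_frame,
                 roi = stack$config$roi)
  } else if (is.list(stack) && !is.null(stack$frames)) {
    frames <- stack$frames
    meta <- stack
  } else {
    frames <- stack
  }
  stopifnot(is.numeric(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) {
    abort("extract_roi_trace: need at least 2 frames")
  }
  roi <- roi %||% meta$roi
  if (is.null(roi)) {
    abort("extract_roi_trace: no `roi` supplied and none in metadata")
  }
  roi <- as.integer(roi)
  h <- dim(frames)[1]
  w <- dim(frames)[2]
  if (length(roi) != 4 || roi[1] > roi[2] || roi[3] > roi[4]) {
    abort("extract_roi_trace: roi must be c(row_min, row_max, col_min, col_max)")
  }
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > h || roi[4] > w) {
    abort(sprintf("roi [%s] exceeds image bounds %dx%d",
                  paste(roi, collapse = ", "), h, w))
  }
  f <- apply(frames[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE], 3, mean)
  fi <- frame_interval %||% meta$frame_interval
  if (is.null(fi)) {
    warn("no frame-interval metadata; assuming 1.1 s per frame")
    fi <- 1.1
  }
  new_repair_trace(
    tibble::tibble(frame = seq_along(f), time_s = (seq_along(f) - 1) * fi,
                   f = as.numeric(f)),
    wound_frame = wound_frame %||% meta$wound_frame,
    frame_interval = fi
  )
}

#' Net dye influx relative to the pre-wound baseline
#'
#' The baseline `F0` is the ROI intensity at the moment before wounding
#' (the single frame preceding `wound_frame`; an averaging window over
#' the last `baseline_frames` pre-wound frames is available but defaults
#' to 1). The net change `delta_f = f - F0` is reported for every frame
#' from `wound_frame` onward, and the curve is additionally subsampled at
#' every 10th frame after wounding (11 s spacing at the default 1.1 s
#' frame interval), the resolution at which repair curves are plotted.
#'
#' @param trace A `repair_trace` ([simulate_trace()],
#'   [extract_roi_trace()], [read_trace()]).
#' @param wound_frame 1-based first wounded frame; defaults to the
#'   trace's metadata. Must be at least 2 (a pre-wound frame must exist).
#' @param baseline_frames Number of pre-wound frames averaged for `F0`.
#' @return A tibble of class `repair_curve` with columns `frame`,
#'   `time_s`, `t_post` (seconds since wounding), `delta_f`,
#'   `subsampled`; attributes `f0`, `wound_frame`, `frame_interval`,
#'   `endpoint` (final `delta_f`).
#' @export
delta_f <- function(trace, wound_frame = NULL, baseline_frames = 1) {
  wound_frame <- wound_frame %||% attr(trace, "wound_frame")
  if (is.null(wound_frame)) {
    abort("delta_f: no `wound_frame` supplied and none in trace metadata")
  }
  n <- nrow(trace)
  if (wound_frame < 2) {
    abort("delta_f: wound_frame must be >= 2 (no pre-wound frame exists)")
  }
  if (wound_frame > n) {
    abort("delta_f: wound_frame beyond the end of the trace")
  }
  baseline_frames <- check_count(baseline_frames, "baseline_frames")
  lo <- max(1, wound_frame - baseline_frames)
  f0 <- mean(trace$f[lo:(wound_frame - 1)])
  post <- trace[trace$frame >= wound_frame, ]
  fi <- attr(trace, "frame_interval") %||%
    (trace$time_s[2] - trace$time_s[1])
  out <- tibble::tibble(
    frame = post$frame,
    time_s = post$time_s,
    t_post = post$time_s - trace$time_s[wound_frame],
    delta_f = post$f - f0,
    subsampled = (post$frame - wound_frame) %% 10 == 0
  )
  structure(out,
            f0 = f0, wound_frame = wound_frame, frame_interval = fi,
            endpoint = out$delta_f[nrow(out)],
            class = c("repair_curve", class(tibble::tibble())))
}

#' Detect the wound frame from a trace
#'
#' For stacks lacking wound metadata: the wound frame is taken as the
#' frame at the start of the largest single-frame intensity jump (the
#' wounded frame still sits at baseline; dye influx appears from the
#' next frame on, matching [delta_f()]'s convention that the wound
#' frame's net influx is 0). Always prefer recorded metadata when
#' available; detected frames should be flagged as such in downstream
#' reports.
#'
#' @param trace A `repair_trace`.
#' @return The detected 1-based wound frame (integer).
#' @export
detect_wound_frame <- function(trace) {
  stopifnot(nrow(trace) >= 2)
  as.integer(which.max(diff(trace$f)))
}

aicc_from_rss <- function(rss, n, k) {
  # k counts mean-model parameters plus the residual variance
  rss <- max(rss, n * .Machine$double.xmin)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Fit membrane-repair kinetics to a dye-influx curve
#'
#' Fits both kinetic models to the post-wound `delta_f` series by least
#' squares: the repair-proficient saturating model
#' `delta_f(t) = c0 + k_a0 * tau * (1 - exp(-t/tau))` and its nested
#' repair-deficient limit (`tau -> Inf`), the linear model
#' `delta_f(t) = c0 + k_a0 * t`. The free offset `c0` absorbs the
#' measurement error of the pre-wound baseline F0 (itself a single noisy
#' frame), which otherwise propagates as a shared shift of every
#' `delta_f` point and inflates the variance of the fitted time
#' constant; it is 0 for noise-free data. The model is selected by the
#' small-sample corrected information criterion (AICc); ties and
#' indistinguishable fits go to the simpler linear model. The saturating
#' fit bounds `tau` at 100x the observation horizon (a documented ridge
#' preventing divergence along the nested limit) and restarts from a
#' grid of `tau` starting values on non-convergence; if the saturating
#' fit never converges the deficient model is returned with a warning.
#'
#' @param curve A `repair_curve` from [delta_f()] (at least 10 post-wound
#'   points).
#' @param frame_interval Seconds per frame; defaults to curve metadata.
#' @return An object of class `kinetic_fit`: list with `model`
#'   (`"proficient"` or `"deficient"`), `k_a0`, `tau` (`Inf` for the
#'   deficient model), `offset` (fitted `c0`), `f0`, `rss`,
#'   `plateau_delta_f` (`k_a0 * tau`, `Inf` for deficient), `aicc`
#'   (named vector for both models), `rss_models` (both models), `n`,
#'   `horizon` (seconds of post-wound observation).
#' @export
fit_kinetics <- function(curve, frame_interval = NULL) {
  stopifnot(inherits(curve, "repair_curve"))
  t <- curve$t_post
  y <- curve$delta_f
  if (length(t) < 10) {
    abort("fit_kinetics: need at least 10 post-wound points")
  }
  horizon <- max(t)
  # deficient (linear) model: closed form
  fit_lin <- lm(y ~ t)
  slope <- unname(coef(fit_lin)["t"])
  offset_lin <- unname(coef(fit_lin)["(Intercept)"])
  rss_lin <- sum(fit_lin$residuals^2)
  # proficient (saturating) model with tau bounded away from the nested
  # linear limit
  tau_max <- 100 * horizon
  a_start <- max(max(y), .Machine$double.eps)
  starts <- unique(pmin(horizon * c(0.05, 0.2, 1), tau_max * 0.9))
  fit_sat <- NULL
  for (tau0 in starts) {
    fit_try <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c0 + A * (1 - exp(-t / tau)),
        start = list(c0 = 0, A = a_start, tau = tau0),
        lower = c(c0 = -Inf, A = .Machine$double.xmin, tau = 1e-6),
        upper = c(c0 = Inf, A = Inf, tau = tau_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit_try)) {
      if (is.null(fit_sat) ||
          sum(stats::resid(fit_try)^2) < sum(stats::resid(fit_sat)^2)) {
        fit_sat <- fit_try
      }
    }
  }
  n <- length(t)
  if (is.null(fit_sat)) {
    warn(sprintf(
      "saturating fit did not converge after %d restarts (linear rss %.4g); returning deficient model",
      length(starts), rss_lin))
    rss_sat <- NA_real_
    aicc_sat <- Inf
  } else {
    rss_sat <- sum(stats::resid(fit_sat)^2)
    aicc_sat <- aicc_from_rss(rss_sat, n, 4)
  }
  aicc_lin <- aicc_from_rss(rss_lin, n, 3)
  # the linear model is the nested limit: prefer it unless the saturating
  # model both lowers the rss and wins on AICc
  proficient <- !is.null(fit_sat) && rss_sat < rss_lin &&
    aicc_sat < aicc_lin
  f0 <- attr(curve, "f0") %||% NA_real_
  if (proficient) {
    cf <- coef(fit_sat)
    tau_hat <- unname(cf["tau"])
    a_hat <- unname(cf["A"])
    out <- list(model = "proficient", k_a0 = a_hat / tau_hat,
                tau = tau_hat, offset = unname(cf["c0"]), f0 = f0,
                rss = rss_sat, plateau_delta_f = a_hat)
  } else {
    out <- list(model = "deficient", k_a0 = slope, tau = Inf,
                offset = offset_lin, f0 = f0, rss = rss_lin,
                plateau_delta_f = Inf)
  }
  out$aicc <- c(deficient = aicc_lin, proficient = aicc_sat)
  out$rss_models <- c(deficient = rss_lin, proficient = rss_sat)
  out$n <- n
  out$horizon <- horizon
  structure(out, class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Membrane-repair kinetic fit (%s model)\n", x$model))
  if (x$model == "proficient") {
    cat(sprintf("  tau = %.4g s, k_a0 = %.4g /s, plateau dF = %.4g\n",
                x$tau, x$k_a0, x$plateau_delta_f))
  } else {
    cat(sprintf("  sustained influx, k_a0 = %.4g /s\n", x$k_a0))
  }
  cat(sprintf("  rss = %.4g over %d points (%.1f s horizon)\n",
              x$rss, x$n, x$horizon))
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A tibble of parameter estimates (`term`, `estimate`).
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_a0", "tau", "offset", "plateau_delta_f"),
    estimate = c(x$k_a0, x$tau, x$offset, x$plateau_delta_f)
  )
}

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `k_a0`, `tau`, `plateau_delta_f`,
#'   `rss`, `aicc_deficient`, `aicc_proficient`, `n`, `horizon`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, k_a0 = x$k_a0, tau = x$tau,
    plateau_delta_f = x$plateau_delta_f, rss = x$rss,
    aicc_deficient = unname(x$aicc["deficient"]),
    aicc_proficient = unname(x$aicc["proficient"]),
    n = x$n, horizon = x$horizon
  )
}

#' Classify repair phenotype from fitted kinetics
#'
#' Proficient if and only if the saturating model was selected and the
#' fitted resealing time constant is strictly below a third of the
#' observation horizon (so the plateau is actually reached within the
#' recording); everything else -- including `tau` exactly at the boundary
#' -- is deficient.
#'
#' @param params A `kinetic_fit`.
#' @param horizon Observation horizon in seconds (defaults to the fit's).
#' @return `"proficient"` or `"deficient"`.
#' @export
classify_repair <- function(params, horizon = params$horizon) {
  stopifnot(inherits(params, "kinetic_fit"))
  check_number(horizon, "horizon", lower = .Machine$double.eps)
  if (params$model == "proficient" && params$tau < horizon / 3) {
    "proficient"
  } else {
    "deficient"
  }
}

#' Compare two groups of repair curves
#'
#' Summarizes each group's subsampled (every-10th-frame) curve as
#' per-timepoint mean and sample sd, and compares the endpoint net influx
#' between groups by Student's unpaired t-test with the star convention.
#'
#' @param curves_a,curves_b Lists of `repair_curve` objects (at least 2
#'   per group, all on the same subsampled time grid).
#' @param label_a,label_b Group names for the report.
#' @return A list of class `repair_comparison`: `summary` (tibble:
#'   `group`, `t_post`, `mean`, `sd`, `n`), `test` (tibble: `t`, `df`,
#'   `p`, `stars`, `n_a`, `n_b`, `endpoint_mean_a`, `endpoint_mean_b`).
#' @export
compare_groups <- function(curves_a, curves_b, label_a = "group_a",
                           label_b = "group_b") {
  check_group <- function(curves, nm) {
    if (!is.list(curves) || length(curves) < 2) {
      abort(sprintf("compare_groups: '%s' needs at least 2 curves", nm))
    }
    lapply(curves, function(cv) stopifnot(inherits(cv, "repair_curve")))
  }
  check_group(curves_a, label_a)
  check_group(curves_b, label_b)
  sub_times <- function(cv) cv$t_post[cv$subsampled]
  grid <- sub_times(curves_a[[1]])
  all_curves <- c(curves_a, curves_b)
  same <- vapply(all_curves, function(cv) {
    ts <- sub_times(cv)
    length(ts) == length(grid) && all(abs(ts - grid) < 1e-9)
  }, logical(1))
  if (!all(same)) {
    abort("compare_groups: curves are not on a common subsampled time grid")
  }
  summarize_group <- function(curves, label) {
    mat <- vapply(curves, function(cv) cv$delta_f[cv$subsampled],
                  numeric(length(grid)))
    tibble::tibble(
      group = label, t_post = grid,
      mean = rowMeans(mat),
      sd = apply(mat, 1, sd),
      n = length(curves)
    )
  }
  endpoints <- function(curves) {
    vapply(curves, function(cv) attr(cv, "endpoint"), numeric(1))
  }
  ea <- endpoints(curves_a)
  eb <- endpoints(curves_b)
  tt <- ttest_unpaired(ea, eb)
  structure(
    list(
      summary = dplyr::bind_rows(summarize_group(curves_a, label_a),
                                 summarize_group(curves_b, label_b)),
      test = dplyr::mutate(tt, n_a = length(ea), n_b = length(eb),
                           endpoint_mean_a = mean(ea),
                           endpoint_mean_b = mean(eb))
    ),
    class = "repair_comparison"
  )
}

#' @export
print.repair_comparison <- function(x, ...) {
  cat("Repair-curve group comparison (endpoint dF, Student's t)\n")
  print(x$test)
  invisible(x)
}
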