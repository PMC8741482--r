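#' Configuration for the membrane-repair simulator
#'
#' Generative model for dye influx after laser wounding. A membrane
#' breach admits the dye at initial rate `k_a0` (intensity units per
#' second) and reseals exponentially with time constant `tau`, so the
#' noise-free ROI intensity is
#' `F(t) = f0` before wounding and
#' `F(t) = f0 + k_a0 * tau * (1 - exp(-(t - t_w)/tau))` afterwards;
#' the repair-deficient limit `tau = Inf` gives sustained linear influx
#' `F(t) = f0 + k_a0 * (t - t_w)`. This closed form is the package's own
#' minimal kinetic model for the two observed phenotypes (saturating
#' influx under proficient resealing vs sustained influx without it).
#'
#' Defaults follow the imaging protocol: one frame every 1.1 s for about
#' 3 minutes (165 frames) with imaging starting before wounding
#' (`wound_frame = 11`, i.e. 10 pre-wound frames; frames are 1-based).
#'
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames.
#' @param wound_frame 1-based index of the first wounded frame,
#'   `2 <= wound_frame <= n_frames`.
#' @param f0 Pre-wound ROI baseline intensity.
#' @param k_a0 Initial influx rate (intensity/s).
#' @param tau Resealing time constant in seconds; `Inf` for a
#'   repair-deficient membrane.
#' @param noise_sd Gaussian noise sd added per frame (ROI-intensity
#'   scale).
#' @param image_shape `c(height, width)` in pixels for stack rendering.
#' @param roi ROI rectangle `c(row_min, row_max, col_min, col_max)`
#'   (1-based inclusive pixel coordinates) for stack rendering.
#' @param wound_xy Wound-site pixel `c(row, col)` (cosmetic rendering
#'   only); defaults to just outside the ROI.
#' @param seed Default integer seed for [simulate_trace()] /
#'   [simulate_stack()].
#' @return A validated list of class `repair_sim_config`.
#' @export
repair_sim_config <- function(frame_interval = 1.1,
                              n_frames = 165,
                              wound_frame = 11,
                              f0 = 100,
                              k_a0 = 50,
                              tau = 10,
                              noise_sd = 0,
                              image_shape = c(64, 64),
                              roi = c(25, 40, 25, 40),
                              wound_xy = NULL,
                              seed = NULL) {
  check_number(frame_interval, "frame_interval",
               lower = .Machine$double.eps)
  n_frames <- check_count(n_frames, "n_frames", lower = 2)
  wound_frame <- check_count(wound_frame, "wound_frame", lower = 2)
  if (wound_frame > n_frames) {
    abort("wound_frame must be <= n_frames")
  }
  check_number(f0, "f0", lower = 0)
  check_number(k_a0, "k_a0", lower = 0)
  check_number(tau, "tau", lower = .Machine$double.xmin, allow_inf = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(image_shape) == 2, all(image_shape >= 1),
            length(roi) == 4)
  if (roi[1] > roi[2] || roi[3] > roi[4] || roi[1] < 1 || roi[3] < 1 ||
      roi[2] > image_shape[1] || roi[4] > image_shape[2]) {
    abort("roi rectangle lies outside the image bounds")
  }
  if (is.null(wound_xy)) {
    wound_xy <- c(max(roi[1] - 5, 1), max(roi[3] - 5, 1))
  }
  structure(
    list(frame_interval = frame_interval, n_frames = n_frames,
         wound_frame = wound_frame, f0 = f0, k_a0 = k_a0, tau = tau,
         noise_sd = noise_sd, image_shape = as.integer(image_shape),
         roi = as.integer(roi), wound_xy = as.integer(wound_xy),
         seed = seed),
    class = "repair_sim_config"
  )
}

#' Noise-free dye-influx closed form
#'
#' @param t Times in seconds (same origin as `t_wound`).
#' @param t_wound Wounding time in seconds.
#' @param f0 Baseline intensity.
#' @param k_a0 Initial influx rate (intensity/s).
#' @param tau Resealing time constant (s), `Inf` for no resealing.
#' @return Numeric vector of ROI intensities.
#' @export
repair_mean_curve <- function(t, t_wound, f0, k_a0, tau) {
  dt <- pmax(t - t_wound, 0)
  if (is.infinite(tau)) {
    f0 + k_a0 * dt
  } else {
    f0 + k_a0 * tau * (1 - exp(-dt / tau))
  }
}

#' Simulate a dye-influx ROI trace
#'
#' Evaluates the closed-form influx curve of [repair_sim_config()] on the
#' frame grid and adds per-frame Gaussian noise. Deterministic given
#' `seed`.
#'
#' @param config A [repair_sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble of class `repair_trace` with columns `frame`,
#'   `time_s`, `f`; attributes `wound_frame`, `frame_interval`, and
#'   `truth` (list of the generating `tau`, `k_a0`, `f0`).
#' @export
simulate_trace <- function(config = repair_sim_config(),
                           seed = config$seed) {
  stopifnot(inherits(config, "repair_sim_config"))
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  t_wound <- times[config$wound_frame]
  f <- repair_mean_curve(times, t_wound, config$f0, config$k_a0,
                         config$tau)
  if (config$noise_sd > 0) {
    noise <- if (is.null(seed)) {
      rnorm(config$n_frames, 0, config$noise_sd)
    } else {
      withr::with_seed(seed, rnorm(config$n_frames, 0, config$noise_sd))
    }
    f <- f + noise
  }
  new_repair_trace(
    tibble::tibble(frame = seq_len(config$n_frames), time_s = times,
                   f = f),
    wound_frame = config$wound_frame,
    frame_interval = config$frame_interval,
    truth = list(tau = config$tau, k_a0 = config$k_a0, f0 = config$f0)
  )
}

new_repair_trace <- function(data, wound_frame, frame_interval,
                             truth = NULL) {
  structure(data,
            wound_frame = wound_frame,
            frame_interval = frame_interval,
            truth = truth,
            class = c("repair_trace", class(tibble::tibble())))
}

#' Simulate a wounded-cell time-lapse image stack
#'
#' Renders the simulated trace of [simulate_trace()] into a multi-frame
#' grayscale stack: a radially decaying dye front spreads from the wound
#' site after wounding (cosmetic), a bright spot marks the wound site,
#' and the ROI pixels are set so that the ROI mean of every frame equals
#' the simulated trace exactly (up to 16-bit quantization when written to
#' TIFF).
#'
#' @param config A [repair_sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `repair_stack`: `frames` (height x width x
#'   n_frames array, ROI-intensity scale), `trace` (the `repair_trace`),
#'   `config`, and `intensity_scale` (the value mapped to 16-bit full
#'   scale on write).
#' @export
simulate_stack <- function(config = repair_sim_config(),
                           seed = config$seed) {
  stopifnot(inherits(config, "repair_sim_config"))
  trace <- simulate_trace(config, seed)
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  roi <- config$roi
  times <- trace$time_s
  t_wound <- times[config$wound_frame]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist_wound <- sqrt((rows - config$wound_xy[1])^2 +
                       (cols - config$wound_xy[2])^2)
  frames <- array(0, dim = c(h, w, config$n_frames))
  front_scale <- max(config$f0, 1)
  for (k in seq_len(config$n_frames)) {
    base <- matrix(config$f0 * 0.5, h, w)
    if (times[k] >= t_wound) {
      # cosmetic dye front: radial decay from the wound, advancing in time
      reach <- 2 + 1.5 * (times[k] - t_wound)
      front <- front_scale * exp(-dist_wound / reach)
      base <- base + front
      base[config$wound_xy[1], config$wound_xy[2]] <-
        base[config$wound_xy[1], config$wound_xy[2]] + 4 * front_scale
    }
    # the ROI carries the quantitative signal: uniform at the trace value
    base[roi[1]:roi[2], roi[3]:roi[4]] <- trace$f[k]
    frames[, , k] <- base
  }
  intensity_scale <- max(frames, 1) * 1.05
  structure(
    list(frames = frames, trace = trace, config = config,
         intensity_scale = intensity_scale),
    class = "repair_stack"
  )
}

#' Write / read an image stack as multi-frame 16-bit TIFF
#'
#' `write_stack()` scales intensities by the stack's `intensity_scale`,
#' writes a 16-bit grayscale multi-frame TIFF, and writes a JSON sidecar
#' (`<path>.json`) recording `frame_interval`, `wound_frame`, `roi` and
#' `intensity_scale` so the quantitative scale survives the round trip.
#' `read_stack()` reads the frames back (rescaled to ROI-intensity units
#' when the sidecar is present) together with the metadata.
#'
#' @param stack A `repair_stack` from [simulate_stack()], or a numeric
#'   array (height x width x frames) plus explicit metadata arguments.
#' @param path TIFF file path.
#' @param frame_interval,wound_frame,roi,intensity_scale Metadata used
#'   when `stack` is a bare array.
#' @return `write_stack()` returns `path` invisibly. `read_stack()`
#'   returns a list with `frames` (array), `frame_interval`,
#'   `wound_frame`, `roi`, `intensity_scale` (the latter `NULL` when no
#'   sidecar exists).
#' @export
write_stack <- function(stack, path, frame_interval = NULL,
                        wound_frame = NULL, roi = NULL,
                        intensity_scale = NULL) {
  if (inherits(stack, "repair_stack")) {
    frames <- stack$frames
    frame_interval <- stack$config$frame_interval
    wound_frame <- stack$config$wound_frame
    roi <- stack$config$roi
    intensity_scale <- stack$intensity_scale
  } else {
    frames <- stack
    if (is.null(intensity_scale)) intensity_scale <- max(frames, 1)
  }
  stopifnot(length(dim(frames)) == 3)
  scaled <- pmin(pmax(frames / intensity_scale, 0), 1)
  frame_list <- lapply(seq_len(dim(frames)[3]),
                       function(k) scaled[, , k])
  tiff::writeTIFF(frame_list, path, bits.per.sample = 16,
                  compression = "none")
  meta <- list(frame_interval = frame_interval, wound_frame = wound_frame,
               roi = roi, intensity_scale = intensity_scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  frame_list <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frame_list)) frame_list <- list(frame_list)
  frames <- array(unlist(frame_list),
                  dim = c(dim(frame_list[[1]]), length(frame_list)))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar)
  } else {
    list(frame_interval = NULL, wound_frame = NULL, roi = NULL,
         intensity_scale = NULL)
  }
  if (!is.null(meta$intensity_scale)) {
    frames <- frames * meta$intensity_scale
  }
  list(frames = frames, frame_interval = meta$frame_interval,
       wound_frame = meta$wound_frame, roi = meta$roi,
       intensity_scale = meta$intensity_scale)
}

#' Write / read a repair trace as CSV
#'
#' @param trace A `repair_trace`.
#' @param path CSV path.
#' @param wound_frame,frame_interval Metadata used on read when not
#'   recoverable from the file (`wound_frame` column attribute is stored
#'   as a column-independent header comment is avoided; supply them
#'   explicitly).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   `repair_trace`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(
    tibble::tibble(frame = trace$frame, time_s = trace$time_s,
                   f = trace$f,
                   wound_frame = attr(trace, "wound_frame"),
                   frame_interval = attr(trace, "frame_interval")),
    path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, wound_frame = NULL, frame_interval = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("frame", "time_s", "f"), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("trace at '%s' lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  wf <- wound_frame %||% raw$wound_frame[1]
  fi <- frame_interval %||% raw$frame_interval[1]
  new_repair_trace(raw[c("frame", "time_s", "f")],
                   wound_frame = wf, frame_interval = fi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
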