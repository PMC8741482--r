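#' Round half away from zero
#'
#' Integer rounding with ties going away from zero, the convention used for
#' all reported registry/screen percentages (so 72.5 -> 73, -0.5 -> -1).
#' Base `round()` rounds half to even and would not reproduce printed
#' percentage tables.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, integer-valued.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.49, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Significance stars for p values
#'
#' Central star convention used by every report in the package:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of star annotations.
#' @examples
#' p_stars(c(0.2, 0.04, 0.009, 1e-4))
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Write a machine-readable run manifest
#'
#' Records the inputs, configuration and seed of an analysis run as JSON so
#' that any stochastic step can be reproduced byte-identically from the
#' recorded seed.
#'
#' @param path Output file path (`.json`).
#' @param inputs Named list of input file paths or descriptions.
#' @param config Named list of configuration values (thresholds, alpha, ...).
#' @param seed Integer seed used for stochastic steps, or `NULL`.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), config = list(),
                               seed = NULL) {
  manifest <- list(
    package = "dysfscreen",
    version = as.character(utils::packageVersion("dysfscreen")),
    seed = seed,
    inputs = inputs,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# Shared argument checks -------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s], got: %s",
                  name, format(lower), format(upper),
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number, got %s", name, format(x)))
  }
  invisible(as.integer(x))
}
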