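#' Bar plot of variant scores with the classification threshold
#'
#' @param scores Classification tibble from [classify()] (optionally with
#'   `sd_value` for error bars).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores) {
  stopifnot(all(c("label", "mean_value", "defective") %in% names(scores)))
  thr <- if ("threshold" %in% names(scores)) scores$threshold[1] else 0.25
  p <- ggplot2::ggplot(
    scores,
    ggplot2::aes(x = stats::reorder(.data$label, -.data$mean_value),
                 y = .data$mean_value, fill = .data$defective)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "#4575b4", `TRUE` = "#d73027"),
      labels = c(`FALSE` = "localized", `TRUE` = "defective"),
      name = NULL) +
    ggplot2::labs(x = NULL, y = "surface expression (fraction of WT)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if ("sd_value" %in% names(scores)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_value - .data$sd_value,
                   ymax = .data$mean_value + .data$sd_value),
      width = 0.3)
  }
  p
}

#' Heat-strip of rescue hit calls
#'
#' One tile per variant x condition, filled by hit status.
#'
#' @param hits Hit-call tibble from [screen_hits()].
#' @return A ggplot object.
#' @export
plot_rescue <- function(hits) {
  stopifnot(all(c("label", "condition", "hit") %in% names(hits)))
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$label, y = .data$condition,
                                     fill = .data$hit)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey85", `TRUE` = "#1a9850"),
      labels = c(`FALSE` = "no rescue", `TRUE` = "rescued"), name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Positional lolliplot of variants over the protein domain track
#'
#' Draws the domain annotation as a track along the protein axis and each
#' variant as a lollipop at its position, colored by its classification.
#' An empty record table draws the domain track alone.
#'
#' @param records Variant records with `position` and (if non-empty)
#'   `defective`; typically [classify()] output joined to [parse_pmm()].
#' @param annotation Domain annotation ([read_domain_annotation()]).
#' @param protein_length Protein length in residues (default 2080,
#'   dysferlin isoform 8). Positions or domain ends beyond it are an
#'   error.
#' @return A ggplot object.
#' @export
plot_lolliplot <- function(records, annotation, protein_length = 2080) {
  ann <- validate_domain_annotation(annotation)
  check_count(protein_length, "protein_length")
  if (any(ann$end > protein_length)) {
    abort(sprintf("domain(s) extend beyond protein length %d: %s",
                  protein_length,
                  paste(ann$name[ann$end > protein_length],
                        collapse = ", ")))
  }
  if (nrow(records) > 0 && any(records$position > protein_length)) {
    abort(sprintf("variant position(s) beyond protein length %d: %s",
                  protein_length,
                  paste(records$label[records$position > protein_length],
                        collapse = ", ")))
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tibble::tibble(x = 1, xend = protein_length),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      linewidth = 0.8, color = "grey40") +
    ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -0.12,
                   ymax = 0.12, alpha = .data$family),
      fill = "#74add1", color = "grey30", show.legend = FALSE) +
    ggplot2::scale_alpha_manual(
      values = c(C2 = 0.9, FerA = 0.6, DysF = 0.6, TM = 1, other = 0.4)) +
    ggplot2::labs(x = "protein position (aa)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (nrow(records) > 0) {
    stopifnot(all(c("position", "defective") %in% names(records)))
    rec <- dplyr::mutate(
      records,
      class = ifelse(.data$defective, "defective", "localized"))
    p <- p +
      ggplot2::geom_segment(
        data = rec,
        ggplot2::aes(x = .data$position, xend = .data$position, y = 0.12,
                     yend = 0.55),
        color = "grey60", linewidth = 0.3) +
      ggplot2::geom_point(
        data = rec,
        ggplot2::aes(x = .data$position, y = 0.55, color = .data$class),
        size = 2) +
      ggplot2::scale_color_manual(
        values = c(defective = "#d73027", localized = "#4575b4"),
        name = NULL)
  }
  p
}

#' @export
autoplot.repair_trace <- function(object, ...) {
  wf <- attr(object, "wound_frame")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "ROI mean intensity") +
    ggplot2::theme_minimal()
  if (!is.null(wf)) {
    p <- p + ggplot2::geom_vline(xintercept = object$time_s[wf],
                                 linetype = "dotted")
  }
  p
}

#' @export
autoplot.repair_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_post,
                                       y = .data$delta_f)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(data = object[object$subsampled, ]) +
    ggplot2::labs(x = "time after wounding (s)",
                  y = expression(Delta * F)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.repair_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$t_post, y = .data$mean,
                               color = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time after wounding (s)",
                  y = expression(Delta * F), color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
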