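#' Offspring quantity at a given predation-mortality level
#'
#' Inverts the predation-mortality relation: the clutch size at which
#' \eqn{1 - w/N} equals `p_level` is \eqn{N = w/(1 - p)}. Used to place
#' iso-mortality gridlines on quadrant plots.
#'
#' @param p_level Predation-mortality probabilities in `[0, 1)` (vectorised).
#' @param w Replacement fitness constant (default 2).
#' @return Offspring counts; [predation_mortality()] of the result returns
#'   `p_level`.
#' @examples
#' iso_mortality_n(c(0, 0.9, 0.99))  # 2, 20, 200
#' @export
iso_mortality_n <- function(p_level, w = 2) {
  check_num(p_level, "p_level")
  check_num(w, "w", scalar = TRUE)
  if (w <= 0) stop("`w` must be positive", call. = FALSE)
  if (any(p_level < 0 | p_level >= 1)) {
    stop("`p_level` must lie in [0, 1)", call. = FALSE)
  }
  w / (1 - p_level)
}

#' Iso-mortality surface for plot overlays
#'
#' Tabulates, for a set of predation-mortality levels, the offspring count
#' achieving each level at the given `w`. Scarcity-mortality levels need no
#' conversion: S is read directly off the quality axis.
#'
#' @param p_levels Predation-mortality probabilities in `[0, 1)`.
#' @param w Replacement fitness constant.
#' @return A tibble with columns `p_level` and `n_at_level`, sorted so that
#'   `n_at_level` increases with `p_level`.
#' @export
mortality_surface <- function(p_levels = c(0.5, 0.9, 0.99), w = 2) {
  p_levels <- sort(unique(p_levels))
  tibble::tibble(p_level = p_levels,
                 n_at_level = iso_mortality_n(p_levels, w))
}

#' Quadrant plot of breeder investment strategies
#'
#' The model's signature figure: each species is a point at (effective N,
#' S), coloured by taxon group; solid set-point lines at `n_setpoint`
#' (vertical) and `s_setpoint` (horizontal) carve the plane into the four
#' selection-category regions, which are labelled in place. Optional dashed
#' gridlines mark offspring counts at chosen predation-mortality levels
#' (computed by [iso_mortality_n()]). The quantity axis is log10-scaled by
#' default because realistic tables span singleton broods to marine clutches
#' of a million eggs.
#'
#' @param results A classified table from [classify_species()].
#' @param params Model parameters; defaults to the parameters stored on
#'   `results`, else [model_params()].
#' @param iso_p Predation-mortality levels for dashed iso-P gridlines
#'   (`NULL` for none).
#' @param log_n Use a log10 quantity axis (default `TRUE`).
#' @param colour_by Column name to colour points by (default
#'   `"taxon_group"`; `NULL` for uncoloured points).
#' @return A ggplot object.
#' @examples
#' spp <- generate_species(generator_config(c(3, 3, 3, 3), seed = 7))
#' quadrant_plot(classify_species(spp))
#' @export
quadrant_plot <- function(results, params = NULL, iso_p = NULL,
                          log_n = TRUE, colour_by = "taxon_group") {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty classified table", call. = FALSE)
  }
  needed <- c("effective_n", "S")
  if (!all(needed %in% names(results))) {
    stop("`results` must come from classify_species() ",
         "(missing effective_n/S columns)", call. = FALSE)
  }
  if (is.null(params)) params <- attr(results, "params")
  params <- as_params(params)

  n_rng <- range(results$effective_n)
  s_rng <- range(results$S)
  xlim <- c(min(n_rng[1], params$n_setpoint) / 2,
            max(n_rng[2], params$n_setpoint) * 2)
  ylim <- c(0, max(s_rng[2], params$s_setpoint) * 1.3)

  lab_x <- if (log_n) {
    c(sqrt(xlim[1] * params$n_setpoint), sqrt(params$n_setpoint * xlim[2]))
  } else {
    c((xlim[1] + params$n_setpoint) / 2, (params$n_setpoint + xlim[2]) / 2)
  }
  lab_y <- c(params$s_setpoint / 2,
             (params$s_setpoint + ylim[2]) / 2)
  region_labels <- tibble::tibble(
    effective_n = c(lab_x[1], lab_x[2], lab_x[1], lab_x[2]),
    S = c(lab_y[1], lab_y[1], lab_y[2], lab_y[2]),
    label = c("weak\nselection", "predation\nselection",
              "scarcity\nselection", "convergent\nselection")
  )

  aes_pts <- if (!is.null(colour_by) && colour_by %in% names(results)) {
    ggplot2::aes(x = .data$effective_n, y = .data$S,
                 colour = .data[[colour_by]])
  } else {
    ggplot2::aes(x = .data$effective_n, y = .data$S)
  }

  p <- ggplot2::ggplot(results) +
    ggplot2::geom_text(data = region_labels,
                       ggplot2::aes(x = .data$effective_n, y = .data$S,
                                    label = .data$label),
                       colour = "grey55", size = 3.4, lineheight = 0.9) +
    ggplot2::geom_vline(xintercept = params$n_setpoint, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = params$s_setpoint, linewidth = 0.6) +
    ggplot2::geom_point(aes_pts, size = 2.2, alpha = 0.85) +
    ggplot2::labs(
      x = "offspring quantity per breeding event (N, effective)",
      y = "relative offspring quality (S = m/M)",
      colour = colour_by,
      title = "Breeder investment quadrants",
      subtitle = sprintf("set points: S = %g, N = %g; w = %g",
                         params$s_setpoint, params$n_setpoint, params$w)
    ) +
    ggplot2::theme_minimal()

  if (!is.null(iso_p)) {
    surf <- mortality_surface(iso_p, params$w)
    p <- p +
      ggplot2::geom_vline(xintercept = surf$n_at_level, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::annotate("text", x = surf$n_at_level, y = ylim[2],
                        label = sprintf("P = %g", surf$p_level),
                        hjust = -0.1, vjust = 1, size = 3, colour = "grey40")
  }
  p <- p + if (log_n) {
    ggplot2::scale_x_log10(limits = xlim)
  } else {
    ggplot2::xlim(xlim)
  }
  p + ggplot2::ylim(ylim)
}

#' @rdname quadrant_plot
#' @param object A `matrisk_classification` object.
#' @param ... Passed on to [quadrant_plot()].
#' @export
autoplot.matrisk_classification <- function(object, ...) {
  quadrant_plot(object, ...)
}

#' Save a quadrant plot to a PNG or SVG file
#'
#' Thin writer around [quadrant_plot()] for script use.
#'
#' @inheritParams quadrant_plot
#' @param path Output file path; format from extension unless `format` given.
#' @param format `"png"` or `"svg"` (default: from the file extension).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
save_quadrant_plot <- function(results, path, params = NULL, iso_p = NULL,
                               log_n = TRUE, colour_by = "taxon_group",
                               format = NULL, width = 7, height = 5) {
  p <- quadrant_plot(results, params = params, iso_p = iso_p, log_n = log_n,
                     colour_by = colour_by)
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("png", "svg")) {
    stop("`format` must be \"png\" or \"svg\"", call. = FALSE)
  }
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
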