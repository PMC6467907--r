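#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a species classification
#'
#' Returns the per-species classification as a plain tibble (the class and
#' parameter attributes dropped).
#'
#' @param x A `matrisk_classification` from [classify_species()].
#' @param ... Unused.
#' @return A tibble, one row per species.
#' @export
tidy.matrisk_classification <- function(x, ...) {
  out <- x
  attr(out, "params") <- NULL
  class(out) <- setdiff(class(out), "matrisk_classification")
  tibble::as_tibble(out)
}

#' One-row summary of a species classification
#'
#' @param x A `matrisk_classification` from [classify_species()].
#' @param ... Unused.
#' @return A one-row tibble: total species, per-category counts, number of
#'   singleton-rule substitutions, and the parameters used.
#' @export
glance.matrisk_classification <- function(x, ...) {
  params <- attr(x, "params")
  counts <- table(factor(x$category, levels = selection_categories()))
  tibble::tibble(
    n_species = nrow(x),
    n_predation = as.integer(counts[["predation"]]),
    n_scarcity = as.integer(counts[["scarcity"]]),
    n_weak = as.integer(counts[["weak"]]),
    n_convergent = as.integer(counts[["convergent"]]),
    n_singleton_rule = sum(x$singleton_rule_applied),
    w = params$w,
    s_setpoint = params$s_setpoint,
    n_setpoint = params$n_setpoint
  )
}

#' Tidy a conjecture-harness simulation
#'
#' @param x A `matrisk_simulation` from [run_conjecture_harness()].
#' @param ... Unused.
#' @return The per-cell tibble: regime (`p`, `threshold`), `alpha`,
#'   `replacement_freq`, `mean_gini`, `scarcity_mortality`, `c_value`.
#' @export
tidy.matrisk_simulation <- function(x, ...) {
  x$cells
}

#' One-row summary of a conjecture-harness simulation
#'
#' @param x A `matrisk_simulation` from [run_conjecture_harness()].
#' @param ... Unused.
#' @return A one-row tibble: cell count, replicates, seed, and the
#'   across-cell correlation between mean brood Gini and `C = P*S`.
#' @export
glance.matrisk_simulation <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    replicates = x$replicates,
    w = x$w,
    seed = x$seed,
    cor_g_c = x$cor_g_c
  )
}

#' Plot a conjecture-harness simulation
#'
#' Mean brood inequality against the joint-mortality index `C = P*S` per
#' simulation cell, sized by replacement frequency — the visual form of the
#' conjecture that harsher joint mortality co-occurs with more unequal
#' broods.
#'
#' @param object A `matrisk_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.matrisk_simulation <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$c_value, y = .data$mean_gini,
                               size = .data$replacement_freq,
                               colour = factor(.data$p))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "joint mortality index C = P·S",
                  y = "mean brood Gini (G)",
                  colour = "P (predation)", size = "replacement freq.") +
    ggplot2::theme_minimal()
}
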