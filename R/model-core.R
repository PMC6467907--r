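#' Probability of offspring mortality by predation
#'
#' The risk-management model approximates per-brood predation mortality as
#' \eqn{P \approx 1 - w/N}: a breeder producing `N` offspring against a
#' replacement requirement of `w` survivors can "afford" to lose a fraction
#' `1 - w/N` of the brood. The caller is responsible for applying the
#' singleton-brood substitution ([apply_singleton_rule()]) first; inputs with
#' `N < w` would yield a negative probability and are rejected with an error
#' rather than clamped, so data problems surface.
#'
#' @param n_offspring Offspring quantity per breeding event (vectorised;
#'   may be fractional after averaging across sources).
#' @param w Replacement fitness constant (default 2).
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @examples
#' predation_mortality(20)        # 0.9
#' predation_mortality(2.1)       # 1 - 2/2.1
#' predation_mortality(1e6)       # ~1
#' @seealso [iso_mortality_n()] for the inverse, [apply_singleton_rule()].
#' @export
predation_mortality <- function(n_offspring, w = 2) {
  check_num(n_offspring, "n_offspring")
  check_num(w, "w", scalar = TRUE)
  if (w <= 0) stop("`w` must be positive", call. = FALSE)
  if (any(n_offspring <= 0)) {
    stop("`n_offspring` must be positive", call. = FALSE)
  }
  if (any(n_offspring < w)) {
    stop("`n_offspring` < `w` would give a negative mortality probability; ",
         "apply the singleton rule first (see apply_singleton_rule())",
         call. = FALSE)
  }
  1 - w / n_offspring
}

#' Relative offspring quality
#'
#' \eqn{S = m/M}: offspring mass at dispersal relative to the mass of the
#' breeding female. `S` doubles as the modelled probability of offspring
#' mortality by spatiotemporal scarcity. Values above 1 are unusual but
#' permitted (they can arise from averaging heterogeneous sources) and are
#' reported with a warning rather than rejected.
#'
#' @param offspring_mass Mass of one offspring at dispersal (vectorised).
#' @param breeder_mass Mass of the breeding female, same units.
#' @return Numeric vector of mass ratios.
#' @examples
#' relative_quality(5, 100)   # 0.05
#' @export
relative_quality <- function(offspring_mass, breeder_mass) {
  check_num(offspring_mass, "offspring_mass")
  check_num(breeder_mass, "breeder_mass")
  if (any(breeder_mass <= 0)) stop("`breeder_mass` must be positive",
                                   call. = FALSE)
  if (any(offspring_mass < 0)) stop("`offspring_mass` must be non-negative",
                                    call. = FALSE)
  s <- offspring_mass / breeder_mass
  if (any(s > 1)) {
    warning(sum(s > 1), " record(s) with S > 1 (offspring heavier than ",
            "breeder at dispersal); kept as-is", call. = FALSE)
  }
  s
}

#' Gini coefficient of brood inequality
#'
#' Inequality of per-offspring resource shares within one brood: 0 for a
#' perfectly equal brood, 1 when a single offspring holds the entire mass.
#' Two algebraically equivalent forms are provided:
#'
#' * `"pairwise"` (default): the bias-corrected mean-absolute-difference form
#'   \eqn{G = \sum_{i,j} |m_i - m_j| / (2 N (N-1) \mu)}. It involves no
#'   ranking, so ties need no tie-break rule.
#' * `"rank"`: the rank form
#'   \eqn{G = (N+1)/(N-1) - [2/(N(N-1)\mu)] \sum_i R_i m_i} with descending
#'   ranks (the largest offspring receives rank 1, the smallest rank `N`).
#'   Equivalent to `"pairwise"` whenever masses are distinct; with ties the
#'   ranking is done on sorted masses, which keeps the two forms equal.
#'
#' Both are invariant under permutation of the masses and under scaling all
#' masses by a positive constant.
#'
#' @param masses Numeric vector of per-offspring masses (>= 2 entries, all
#'   non-negative, at least one positive).
#' @param method `"pairwise"` or `"rank"`.
#' @return A single number in `[0, 1]`.
#' @examples
#' gini(rep(1, 10))           # 0: equal brood
#' gini(c(1, rep(0, 9)))      # 1: one offspring holds all mass
#' gini(c(3, 2, 1))           # 1/3
#' @export
gini <- function(masses, method = c("pairwise", "rank")) {
  method <- match.arg(method)
  check_num(masses, "masses")
  if (length(masses) < 2) {
    stop("a brood needs at least 2 offspring to measure inequality",
         call. = FALSE)
  }
  if (any(masses < 0)) stop("`masses` must be non-negative", call. = FALSE)
  mu <- mean(masses)
  if (mu == 0) stop("degenerate brood: all masses are zero", call. = FALSE)
  n <- length(masses)
  if (method == "pairwise") {
    # sum_{i,j} |m_i - m_j| via the sorted-cumulative identity (O(n log n))
    s <- sort(masses)
    total_abs_diff <- 2 * sum((2 * seq_len(n) - n - 1) * s)
    total_abs_diff / (2 * n * (n - 1) * mu)
  } else {
    m_desc <- sort(masses, decreasing = TRUE)
    r <- seq_len(n)                       # rank 1 = largest offspring
    (n + 1) / (n - 1) - 2 * sum(r * m_desc) / (n * (n - 1) * mu)
  }
}

#' Per-offspring brood profile
#'
#' Packages one brood's masses with their descending ranks (largest offspring
#' rank 1, smallest rank N), the mean mass, and the Gini inequality index.
#'
#' @param masses Per-offspring masses, as for [gini()].
#' @return A tibble of class `matrisk_brood` with columns `offspring` (input
#'   order), `mass` and `rank`, and attributes `mu` and `gini`.
#' @examples
#' brood_profile(c(4, 1, 1))
#' @export
brood_profile <- function(masses) {
  g <- gini(masses)  # validates
  ranks <- rank(-masses, ties.method = "first")
  out <- tibble::tibble(
    offspring = seq_along(masses),
    mass = as.numeric(masses),
    rank = as.integer(ranks)
  )
  attr(out, "mu") <- mean(masses)
  attr(out, "gini") <- g
  class(out) <- c("matrisk_brood", class(out))
  out
}

#' @export
print.matrisk_brood <- function(x, ...) {
  cat(sprintf("<brood of %d offspring: mean mass %.6g, Gini %.6g>\n",
              nrow(x), attr(x, "mu"), attr(x, "gini")))
  NextMethod()
}

#' Convergent-selection index
#'
#' \eqn{C = P \cdot S}: the joint probability of offspring mortality by
#' predation and by scarcity, treating the two mortality sources as
#' independent. The model conjectures \eqn{C \approx G}, the brood Gini
#' coefficient — i.e. that joint mortality pressure favors unequal broods;
#' see [run_conjecture_harness()] for the simulation harness that probes
#' this association.
#'
#' @param p_value Predation-mortality probability in `[0, 1]` (vectorised).
#' @param s_value Scarcity-mortality probability in `[0, 1]`.
#' @return `p_value * s_value`.
#' @examples
#' convergent_index(0.9, 0.5)  # 0.45
#' @export
convergent_index <- function(p_value, s_value) {
  check_num(p_value, "p_value")
  check_num(s_value, "s_value")
  if (any(p_value < 0 | p_value > 1)) {
    stop("`p_value` must lie in [0, 1]", call. = FALSE)
  }
  if (any(s_value < 0 | s_value > 1)) {
    stop("`s_value` must lie in [0, 1]", call. = FALSE)
  }
  p_value * s_value
}

#' Substitute offspring quantity for broods below replacement
#'
#' Broods with `N < w` would give a negative predation mortality
#' \eqn{1 - w/N}. For such species (typically singleton-brood mammals), the
#' offspring quantity is replaced by `params$n_substitute` (default 2.1),
#' which keeps P slightly above zero. The substitution is reported in the
#' returned flag, never applied silently. The trigger is `N < w` rather than
#' `N == 1` so that fractional averaged quantities below `w` are also caught.
#'
#' @param n_offspring Offspring quantities (vectorised).
#' @inheritParams classify_species
#' @return A tibble with columns `effective_n` and `singleton_rule_applied`.
#' @examples
#' apply_singleton_rule(c(1, 2, 50))
#' @export
apply_singleton_rule <- function(n_offspring, params = model_params()) {
  params <- as_params(params)
  check_num(n_offspring, "n_offspring")
  if (any(n_offspring <= 0)) {
    stop("`n_offspring` must be positive", call. = FALSE)
  }
  applied <- n_offspring < params$w
  tibble::tibble(
    effective_n = ifelse(applied, params$n_substitute, n_offspring),
    singleton_rule_applied = applied
  )
}

# Category assignment from (S, effective N). Boundary semantics follow the
# printed set points: "<=" on the low side of both thresholds, ">" above.
assign_category <- function(s_value, effective_n, params) {
  low_s <- s_value <= params$s_setpoint
  low_n <- effective_n <= params$n_setpoint
  dplyr::case_when(
    low_s & !low_n ~ "predation",
    !low_s & low_n ~ "scarcity",
    low_s & low_n ~ "weak",
    .default = "convergent"
  )
}

#' Category levels of the risk-management model
#'
#' The four natural-selection categories in display order.
#' @return Character vector `c("predation", "scarcity", "weak", "convergent")`.
#' @export
selection_categories <- function() {
  c("predation", "scarcity", "weak", "convergent")
}

#' Classify species by breeder investment strategy
#'
#' The model's central operation. For each species row it computes relative
#' offspring quality `S = m/M`, applies the singleton-brood substitution,
#' computes predation mortality `P = 1 - w/N_eff` and the convergent index
#' `C = P*S`, computes the brood Gini `G` where per-offspring masses are
#' available, and assigns one of the four selection categories by comparing
#' `(S, N_eff)` with the set points:
#'
#' * **predation**: `S <= s_setpoint` and `N > n_setpoint` — many cheap
#'   offspring; fish, reptiles, marine invertebrates.
#' * **scarcity**: `S > s_setpoint` and `N <= n_setpoint` — few
#'   well-provisioned offspring; birds, mammals.
#' * **weak**: both low — minimal investment; apex predators.
#' * **convergent**: both high — diversified investment; social insects and
#'   social mammals.
#'
#' The four regions partition the plane, so every valid row receives exactly
#' one category.
#'
#' @param data A data frame with columns `n_offspring`, `offspring_mass`,
#'   `breeder_mass`, and optionally `species`, `taxon_group` and
#'   `brood_masses` (a list-column of numeric vectors, or a
#'   semicolon-separated character column as read by [read_species_table()]).
#' @param params A [model_params()] object; `NULL` uses the defaults.
#' @return A tibble of class `matrisk_classification`: the input columns plus
#'   `S`, `P`, `C`, `G` (`NA` where no brood masses), `category` (factor),
#'   `effective_n` and `singleton_rule_applied`. The parameters used are kept
#'   in the `params` attribute.
#' @examples
#' spp <- tibble::tibble(
#'   species = c("cod", "elephant", "viper", "fire ant"),
#'   n_offspring = c(1e6, 1, 4, 1e5),
#'   offspring_mass = c(0.001, 1200, 20, 0.9),
#'   breeder_mass = c(8000, 4000, 200, 1)
#' )
#' classify_species(spp)
#' @export
classify_species <- function(data, params = NULL) {
  params <- as_params(params)
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  required <- c("n_offspring", "offspring_mass", "breeder_mass")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("`data` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("`data` has no rows", call. = FALSE)

  out <- tibble::as_tibble(data)
  out$S <- relative_quality(out$offspring_mass, out$breeder_mass)
  sub <- apply_singleton_rule(out$n_offspring, params)
  out$effective_n <- sub$effective_n
  out$singleton_rule_applied <- sub$singleton_rule_applied
  out$P <- predation_mortality(out$effective_n, params$w)
  out$C <- out$P * out$S  # S > 1 already warned about in relative_quality()
  out$G <- brood_gini_column(out)
  out$category <- factor(assign_category(out$S, out$effective_n, params),
                         levels = selection_categories())
  out <- out[, c(setdiff(names(out), c("S", "P", "C", "G", "category",
                                       "effective_n",
                                       "singleton_rule_applied")),
                 c("S", "P", "C", "G", "category", "effective_n",
                   "singleton_rule_applied"))]
  attr(out, "params") <- params
  class(out) <- c("matrisk_classification", class(out))
  out
}

# G per row from a `brood_masses` column that is either a list of numeric
# vectors or semicolon-separated text; NA when absent or too short.
brood_gini_column <- function(data) {
  if (!"brood_masses" %in% names(data)) return(rep(NA_real_, nrow(data)))
  bm <- data$brood_masses
  if (is.character(bm)) bm <- lapply(bm, parse_brood_masses)
  purrr::map_dbl(bm, function(m) {
    if (is.null(m) || length(m) < 2 || all(is.na(m))) return(NA_real_)
    gini(m)
  })
}

#' Map model categories onto r/K and CSR selection
#'
#' The legacy correspondence: the scarcity category lines up with
#' *r*-selection and Grime's S-selection, the weak category with
#' *K*-selection and C-selection, and the predation category with
#' R-selection (no r/K counterpart); convergent selection has no counterpart
#' in either legacy scheme.
#'
#' @param category Character vector (or factor) of category names.
#' @return A tibble with columns `category`, `rk_counterpart`,
#'   `csr_counterpart` (`NA` where the legacy theory has no counterpart).
#' @examples
#' map_to_legacy(c("weak", "convergent"))
#' @export
map_to_legacy <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), selection_categories())
  if (length(bad) > 0) {
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lut <- tibble::tibble(
    category = selection_categories(),
    rk_counterpart = c(NA, "r-selection", "K-selection", NA),
    csr_counterpart = c("R-selection", "S-selection", "C-selection", NA)
  )
  dplyr::left_join(tibble::tibble(category = category), lut, by = "category")
}

#' Taxon-by-category contingency table
#'
#' Counts classified species per (taxon group, category) cell. Cells with no
#' species are kept at zero so the table is always complete over the four
#' categories.
#'
#' @param results A classified table from [classify_species()] (or any data
#'   frame with `taxon_group` and `category` columns).
#' @return A tibble with columns `taxon_group`, `category`, `n`.
#' @export
summarize_by_taxon <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("taxon_group", "category") %in% names(results))) {
    stop("`results` needs `taxon_group` and `category` columns",
         call. = FALSE)
  }
  results |>
    tibble::as_tibble() |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = selection_categories())) |>
    dplyr::count(.data$taxon_group, .data$category, .drop = FALSE) |>
    dplyr::arrange(.data$taxon_group, .data$category)
}

check_num <- function(x, name, scalar = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop("`", name, "` must be finite and numeric", call. = FALSE)
  }
  if (scalar && length(x) != 1) {
    stop("`", name, "` must be a single number", call. = FALSE)
  }
  invisible(x)
}
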