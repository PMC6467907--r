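#' Configuration for the synthetic species generator
#'
#' Describes a synthetic community whose species fall, by construction,
#' strictly inside the set-point region of their intended category, so that
#' [classify_species()] must recover every label. The defaults emulate the
#' structure of the 87-species compilation the model was demonstrated on:
#' fish, reptiles and marine invertebrates clustering in the predation
#' region, birds and mammals in the scarcity region, a handful of apex
#' predators in the weak region, and social insects/mammals in the
#' convergent region (counts 30/35/10/12).
#'
#' Offspring quantity is drawn log-uniformly and relative quality uniformly
#' within per-category bounds; breeder mass is log-normal spanning insects
#' to large vertebrates; offspring mass is derived as `S * M`. Broods with
#' `n <= max_brood_n` also receive per-offspring masses drawn by
#' [generate_brood()] with concentration `alpha`.
#'
#' @param n_per_category Species counts, in category order
#'   (predation, scarcity, weak, convergent). Default `c(30, 35, 10, 12)`.
#' @param n_bounds Named list of length-2 offspring-quantity bounds per
#'   category, each strictly inside that category's region.
#' @param s_bounds Named list of length-2 relative-quality bounds per
#'   category, likewise strictly in-region.
#' @param breeder_meanlog,breeder_sdlog Log-normal parameters for breeder
#'   mass in grams.
#' @param alpha Dirichlet concentration for per-offspring brood masses
#'   (smaller = more unequal).
#' @param max_brood_n Largest brood for which per-offspring masses are
#'   generated.
#' @param params Set points the bounds are checked against.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `matrisk_generator_config` list.
#' @export
generator_config <- function(n_per_category = c(30, 35, 10, 12),
                             n_bounds = NULL, s_bounds = NULL,
                             breeder_meanlog = log(1000),
                             breeder_sdlog = 3,
                             alpha = 1, max_brood_n = 30,
                             params = model_params(), seed = 1L) {
  params <- as_params(params)
  stopifnot(length(n_per_category) == 4, all(n_per_category >= 0))
  n_bounds <- n_bounds %||% list(
    predation = c(20, 1e6),
    scarcity = c(1, 8),
    weak = c(1, 8),
    convergent = c(20, 1e5)
  )
  s_bounds <- s_bounds %||% list(
    predation = c(1e-5, 0.08),
    scarcity = c(0.15, 0.6),
    weak = c(0.005, 0.08),
    convergent = c(0.15, 0.9)
  )
  cats <- selection_categories()
  names(n_per_category) <- cats
  for (cat in cats) {
    check_region_bounds(cat, n_bounds[[cat]], s_bounds[[cat]], params)
  }
  stopifnot(alpha > 0, breeder_sdlog > 0, max_brood_n >= 2)
  structure(
    list(n_per_category = n_per_category, n_bounds = n_bounds,
         s_bounds = s_bounds, breeder_meanlog = breeder_meanlog,
         breeder_sdlog = breeder_sdlog, alpha = alpha,
         max_brood_n = max_brood_n, params = params,
         seed = as.integer(seed)),
    class = "matrisk_generator_config"
  )
}

# A category's sampling bounds must sit strictly inside its set-point
# region; the singleton substitution is taken into account on the low-N side.
check_region_bounds <- function(category, nb, sb, params) {
  if (is.null(nb) || is.null(sb) || length(nb) != 2 || length(sb) != 2) {
    stop("bounds for category '", category, "' must be length-2 vectors",
         call. = FALSE)
  }
  if (nb[1] > nb[2] || sb[1] > sb[2] || any(nb <= 0) || any(sb <= 0)) {
    stop("invalid bounds for category '", category, "'", call. = FALSE)
  }
  # effective N after the singleton rule never drops below n_substitute
  n_eff <- pmax(nb, ifelse(nb < params$w, params$n_substitute, nb))
  low_n <- c(predation = FALSE, scarcity = TRUE, weak = TRUE,
             convergent = FALSE)[[category]]
  low_s <- c(predation = TRUE, scarcity = FALSE, weak = TRUE,
             convergent = FALSE)[[category]]
  n_ok <- if (low_n) all(n_eff <= params$n_setpoint) else
    all(n_eff > params$n_setpoint)
  s_ok <- if (low_s) all(sb <= params$s_setpoint) else
    all(sb > params$s_setpoint)
  if (!n_ok || !s_ok) {
    stop("bounds for category '", category, "' straddle or fall outside ",
         "its set-point region", call. = FALSE)
  }
  invisible(TRUE)
}

taxon_pool <- list(
  predation = c("fish", "reptile", "marine invertebrate"),
  scarcity = c("bird", "mammal"),
  weak = c("shark", "reptile"),
  convergent = c("social insect", "social mammal")
)

#' Generate a synthetic species table with known category labels
#'
#' Draws species whose (S, N) values fall strictly inside the set-point
#' region of their intended category (see [generator_config()]); the true
#' label is returned in the `true_category` column, separate from the
#' species-table schema columns, so classifier label recovery can be
#' asserted. Identical seeds give identical tables.
#'
#' @param config A [generator_config()] object.
#' @param path Optional path; when given, the species-table columns (without
#'   `true_category`) are written there in the [read_species_table()] schema.
#' @return A tibble with the species-table columns (`species`, `taxon_group`,
#'   `n_offspring`, `offspring_mass`, `breeder_mass`, `brood_masses`
#'   list-column) plus `true_category`.
#' @examples
#' spp <- generate_species(generator_config(c(10, 10, 10, 10), seed = 42))
#' all(classify_species(spp)$category == spp$true_category)
#' @export
generate_species <- function(config = generator_config(), path = NULL) {
  if (!inherits(config, "matrisk_generator_config")) {
    stop("`config` must come from generator_config()", call. = FALSE)
  }
  local_seed(config$seed)
  cats <- selection_categories()
  rows <- purrr::map(cats, function(cat) {
    k <- config$n_per_category[[cat]]
    if (k == 0) return(NULL)
    nb <- config$n_bounds[[cat]]
    sb <- config$s_bounds[[cat]]
    n <- 10^stats::runif(k, log10(nb[1]), log10(nb[2]))
    s <- stats::runif(k, sb[1], sb[2])
    big_m <- stats::rlnorm(k, config$breeder_meanlog, config$breeder_sdlog)
    tibble::tibble(
      species = sprintf("%s_sp%02d", gsub(" ", "_", cat), seq_len(k)),
      taxon_group = sample(taxon_pool[[cat]], k, replace = TRUE),
      n_offspring = n,
      offspring_mass = s * big_m,
      breeder_mass = big_m,
      true_category = cat
    )
  })
  out <- dplyr::bind_rows(rows)
  out$brood_masses <- purrr::pmap(
    list(out$n_offspring, out$offspring_mass),
    function(n, m) {
      n_int <- round(n)
      if (n_int < 2 || n_int > config$max_brood_n) return(NULL)
      generate_brood(n_int, total_mass = m * n_int,
                     alpha = config$alpha)$mass
    }
  )
  out <- out[, c("species", "taxon_group", "n_offspring", "offspring_mass",
                 "breeder_mass", "brood_masses", "true_category")]
  if (!is.null(path)) {
    write_results(out[, setdiff(names(out), "true_category")], path)
  }
  out
}

#' Generate one brood by Dirichlet mass allocation
#'
#' Splits `total_mass` among `n` offspring using a symmetric Dirichlet
#' proportional split with concentration `alpha` (gamma draws renormalised
#' to sum exactly to `total_mass`). Small `alpha` concentrates mass in few
#' offspring (high Gini); large `alpha` approaches an equal split;
#' `equal = TRUE` (the `alpha -> Inf` limit) gives exactly equal masses.
#'
#' @param n Number of offspring (>= 2).
#' @param total_mass Total brood mass (> 0).
#' @param alpha Dirichlet concentration (> 0).
#' @param equal Produce an exactly equal split (ignores `alpha`).
#' @param seed Optional integer seed for a self-contained reproducible draw;
#'   `NULL` uses (and advances) the current RNG state.
#' @return A [brood_profile()]: masses, descending ranks, mean and Gini.
#' @examples
#' b <- generate_brood(10, 100, alpha = 0.5, seed = 3)
#' sum(b$mass)         # exactly 100
#' attr(b, "gini")
#' @export
generate_brood <- function(n, total_mass, alpha = 1, equal = FALSE,
                           seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(total_mass) || length(total_mass) != 1 || total_mass <= 0) {
    stop("`total_mass` must be a single positive number", call. = FALSE)
  }
  if (!equal && (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  if (!is.null(seed)) local_seed(seed)
  shares <- if (equal) {
    rep(1 / n, n)
  } else {
    g <- stats::rgamma(n, shape = alpha, rate = 1)
    if (sum(g) == 0) g <- rep(1, n)  # guards underflow at tiny alpha
    g / sum(g)
  }
  brood_profile(shares * total_mass)
}

#' Monte-Carlo harness for the convergent-selection conjecture
#'
#' The model conjectures that joint predation-and-scarcity mortality
#' (`C = P*S`) is associated with unequal broods (high Gini `G`). The model
#' leaves the mechanism open; this harness operationalises it minimally:
#' in each replicate a brood is drawn ([generate_brood()]), every offspring
#' independently survives predation with probability `1 - P`, and survivors
#' additionally survive scarcity only if their mass reaches the regime's
#' scarcity threshold (scarcity acts at dispersal, after predation). A brood
#' "replaces" its breeder if at least `w` offspring survive both.
#'
#' For every (regime x alpha) cell the harness reports the replacement
#' frequency, the mean brood Gini, the empirical scarcity mortality among
#' predation survivors, and `C = P * S_hat` from those; the across-cell
#' Pearson correlation between mean `G` and `C` summarises the association.
#' This measures the conjecture under the harness's own mechanism only — it
#' is not a confirmation of it.
#'
#' @param regimes A data frame with columns `p` (predation probability in
#'   `[0, 1]`) and `threshold` (scarcity mass threshold, >= 0), one row per
#'   regime.
#' @param alphas Dirichlet concentrations to cross with the regimes; `Inf`
#'   means an exactly equal split.
#' @param n Offspring per brood.
#' @param total_mass Total brood mass (so the equal share is
#'   `total_mass / n`).
#' @param masses Optional fixed per-offspring mass vector used for every
#'   replicate instead of Dirichlet draws (`alphas` is then ignored).
#' @param replicates Monte-Carlo replicates per cell (>= 1).
#' @param w Replacement survivor count (default 2).
#' @param seed Integer seed; results are bit-identical for identical seeds.
#' @return A `matrisk_simulation` object: list with `cells` (a tibble with
#'   `p`, `threshold`, `alpha`, `replacement_freq`, `mean_gini`,
#'   `scarcity_mortality`, `c_value`), `cor_g_c`, `replicates`, `w`, `seed`.
#' @examples
#' sim <- run_conjecture_harness(
#'   regimes = data.frame(p = c(0.1, 0.6), threshold = c(0, 8)),
#'   alphas = c(0.5, Inf), n = 10, total_mass = 100,
#'   replicates = 500, seed = 11
#' )
#' tidy(sim)
#' @export
run_conjecture_harness <- function(regimes, alphas = c(0.2, 1, 5, Inf),
                                   n = 10, total_mass = 100, masses = NULL,
                                   replicates = 2000, w = 2, seed = 1L) {
  if (!is.data.frame(regimes) || !all(c("p", "threshold") %in% names(regimes))) {
    stop("`regimes` must be a data frame with `p` and `threshold` columns",
         call. = FALSE)
  }
  if (any(regimes$p < 0 | regimes$p > 1)) {
    stop("regime `p` must lie in [0, 1]", call. = FALSE)
  }
  if (any(regimes$threshold < 0)) {
    stop("regime `threshold` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  if (!is.null(masses)) {
    if (length(masses) < 2 || any(masses < 0)) {
      stop("fixed `masses` must be >= 2 non-negative values", call. = FALSE)
    }
    n <- length(masses)
    alphas <- NA_real_
  } else if (any(alphas <= 0)) {
    stop("`alphas` must be positive (Inf allowed for equal split)",
         call. = FALSE)
  }
  replicates <- as.integer(replicates)
  local_seed(seed)

  grid <- tidyr::expand_grid(
    regime = seq_len(nrow(regimes)),
    alpha = alphas
  )
  cells <- purrr::pmap(grid, function(regime, alpha) {
    p <- regimes$p[regime]
    thr <- regimes$threshold[regime]
    replaced <- logical(replicates)
    ginis <- numeric(replicates)
    pred_survivors <- 0
    scarcity_deaths <- 0
    for (r in seq_len(replicates)) {
      m <- if (!is.null(masses)) {
        masses
      } else if (is.infinite(alpha)) {
        rep(total_mass / n, n)
      } else {
        generate_brood(n, total_mass, alpha)$mass
      }
      survives_pred <- stats::runif(n) < (1 - p)
      fed <- m >= thr
      alive <- survives_pred & fed
      replaced[r] <- sum(alive) >= w
      ginis[r] <- gini(m)
      pred_survivors <- pred_survivors + sum(survives_pred)
      scarcity_deaths <- scarcity_deaths + sum(survives_pred & !fed)
    }
    s_hat <- if (pred_survivors > 0) scarcity_deaths / pred_survivors else NA_real_
    tibble::tibble(
      p = p, threshold = thr, alpha = alpha,
      replacement_freq = mean(replaced),
      mean_gini = mean(ginis),
      scarcity_mortality = s_hat,
      c_value = p * s_hat
    )
  }) |> dplyr::bind_rows()

  cor_g_c <- if (nrow(cells) >= 3 &&
                 stats::sd(cells$mean_gini) > 0 &&
                 stats::sd(cells$c_value, na.rm = TRUE) > 0) {
    stats::cor(cells$mean_gini, cells$c_value, use = "complete.obs")
  } else {
    NA_real_
  }

  structure(
    list(cells = cells, cor_g_c = cor_g_c, replicates = replicates,
         w = w, seed = as.integer(seed)),
    class = "matrisk_simulation"
  )
}

#' @export
print.matrisk_simulation <- function(x, ...) {
  cat(sprintf(
    "<conjecture-harness simulation: %d cell(s) x %d replicates, seed %d>\n",
    nrow(x$cells), x$replicates, x$seed))
  cat(sprintf("  across-cell cor(mean G, C = P*S): %s\n",
              ifelse(is.na(x$cor_g_c), "NA", sprintf("%.3f", x$cor_g_c))))
  print(x$cells)
  invisible(x)
}

# set.seed scoped to the calling frame: prior RNG state is restored when the
# caller exits, so package functions never perturb a user's random stream.
local_seed <- function(seed, env = parent.frame()) {
  seed <- as.integer(as.numeric(seed) %% .Machine$integer.max)
  withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}
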