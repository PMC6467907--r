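test_that("predation mortality follows 1 - w/N and rejects out-of-domain input", {
  expect_equal(predation_mortality(20, 2), 0.9)
  expect_equal(predation_mortality(2, 2), 0)
  # singleton-substituted brood: 1 - 2/2.1 = 1/21 exactly
  expect_equal(predation_mortality(2.1, 2), 1 / 21, tolerance = 1e-12)
  expect_equal(predation_mortality(c(4, 8), 2), c(0.5, 0.75))

  expect_error(predation_mortality(0, 2), "positive")
  expect_error(predation_mortality(5, -1), "positive")
  expect_error(predation_mortality(1, 2), "singleton rule")
})

test_that("relative quality is m/M, allows S > 1 with a warning only", {
  expect_equal(relative_quality(5, 100), 0.05)
  expect_equal(relative_quality(0, 10), 0)
  expect_equal(relative_quality(10, 10), 1)
  expect_warning(s <- relative_quality(12, 10), "S > 1")
  expect_equal(s, 1.2)
  expect_error(relative_quality(5, 0), "breeder_mass")
  expect_error(relative_quality(-1, 10), "non-negative")
})

test_that("convergent index is the product P*S on the unit square", {
  expect_equal(convergent_index(0.9, 0.5), 0.45)
  expect_equal(convergent_index(0, 0.7), 0)
  expect_equal(convergent_index(1, 1), 1)
  expect_error(convergent_index(1.2, 0.5), "\\[0, 1\\]")
  expect_error(convergent_index(0.5, -0.1), "\\[0, 1\\]")
})

test_that("singleton rule substitutes only below w and flags it", {
  out <- apply_singleton_rule(c(1, 50, 2, 1.5))
  expect_equal(out$effective_n, c(2.1, 50, 2, 2.1))
  expect_equal(out$singleton_rule_applied, c(TRUE, FALSE, FALSE, TRUE))
  # substituted broods always end up with strictly positive P
  expect_true(all(predation_mortality(out$effective_n, 2) >= 0))
  expect_gt(predation_mortality(out$effective_n[1], 2), 0)
  expect_error(apply_singleton_rule(0), "positive")
})

test_that("classification assigns the printed quadrants, boundaries inclusive on the low side", {
  cases <- tibble::tibble(
    S = c(0.05, 0.5, 0.1, 0.3),
    N = c(100, 2.1, 10, 500),
    expected = c("predation", "scarcity", "weak", "convergent")
  )
  dat <- tibble::tibble(
    n_offspring = cases$N,
    offspring_mass = cases$S * 100,
    breeder_mass = 100
  )
  res <- classify_species(dat)
  expect_equal(as.character(res$category), cases$expected)
  expect_equal(res$S, cases$S)
  expect_equal(res$P, 1 - 2 / cases$N)
  expect_equal(res$C, res$P * res$S)
  expect_true(all(is.na(res$G)))
})

test_that("classification uses effective N after the singleton rule", {
  # a singleton-brood species with high S must land in scarcity, not error
  dat <- tibble::tibble(n_offspring = 1, offspring_mass = 30,
                        breeder_mass = 100)
  res <- classify_species(dat)
  expect_equal(as.character(res$category), "scarcity")
  expect_true(res$singleton_rule_applied)
  expect_equal(res$effective_n, 2.1)
  expect_equal(res$P, 1 - 2 / 2.1)
})

test_that("custom set points move the partition", {
  dat <- tibble::tibble(n_offspring = 8, offspring_mass = 5,
                        breeder_mass = 100)  # S = 0.05
  expect_equal(as.character(classify_species(dat)$category), "weak")
  p <- model_params(n_setpoint = 5)
  expect_equal(as.character(classify_species(dat, p)$category), "predation")
})

test_that("the quadrant partition is exhaustive and mutually exclusive", {
  params <- model_params()
  s_grid <- c(seq(0.001, 0.3, length.out = 40), params$s_setpoint)
  n_grid <- c(10^seq(log10(2), 6, length.out = 40), params$n_setpoint)
  grid <- tidyr::expand_grid(S = s_grid, N = n_grid)
  dat <- tibble::tibble(n_offspring = grid$N,
                        offspring_mass = grid$S * 50,
                        breeder_mass = 50)
  res <- classify_species(dat, params)
  expect_false(any(is.na(res$category)))
  expect_true(all(res$category %in% selection_categories()))
  # each assignment agrees with a direct region check (exclusive by definition)
  manual <- ifelse(
    res$S <= 0.1 & res$effective_n > 10, "predation",
    ifelse(res$S > 0.1 & res$effective_n <= 10, "scarcity",
           ifelse(res$S <= 0.1 & res$effective_n <= 10, "weak", "convergent")))
  expect_equal(as.character(res$category), manual)
})

test_that("P increases in N and S increases in m (monotonicity)", {
  n <- sort(10^runif(50, log10(2), 6))
  expect_true(all(diff(predation_mortality(n)) > 0))
  m <- sort(runif(50, 0, 100))
  expect_true(all(diff(relative_quality(m, 123)) > 0))
  # C non-decreasing in each factor on [0,1]
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(convergent_index(p, 0.6)) >= 0))
  expect_true(all(diff(convergent_index(0.3, p)) >= 0))
})

test_that("legacy-theory mapping matches the published correspondence", {
  m <- map_to_legacy(selection_categories())
  expect_equal(m$rk_counterpart, c(NA, "r-selection", "K-selection", NA))
  expect_equal(m$csr_counterpart,
               c("R-selection", "S-selection", "C-selection", NA))
  expect_error(map_to_legacy("balanced"), "unknown category")
})

test_that("taxon summary conserves counts and keeps empty cells", {
  res <- classify_species(make_species_tbl())
  tab <- summarize_by_taxon(res)
  expect_equal(sum(tab$n), nrow(res))
  # every taxon has a row for all four categories
  expect_equal(nrow(tab), 4 * length(unique(res$taxon_group)))
  row_sums <- dplyr::count(tidy(res), taxon_group, wt = 1, name = "total")
  joined <- dplyr::summarise(dplyr::group_by(tab, taxon_group),
                             total = sum(n))
  expect_equal(dplyr::arrange(joined, taxon_group)$total,
               dplyr::arrange(row_sums, taxon_group)$total)
  expect_error(summarize_by_taxon(res[0, ]), "non-empty")
})

test_that("glance reports per-category counts and parameter echo", {
  res <- classify_species(make_species_tbl())
  g <- glance(res)
  expect_equal(g$n_species, 4)
  expect_equal(g$n_predation + g$n_scarcity + g$n_weak + g$n_convergent, 4)
  expect_equal(g$w, 2)
  expect_equal(g$n_setpoint, 10)
})
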