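test_that("classifier recovers every generator-assigned label", {
  cfg <- generator_config(c(10, 10, 10, 10), seed = 42)
  spp <- generate_species(cfg)
  expect_equal(nrow(spp), 40)
  res <- classify_species(spp)
  expect_equal(as.character(res$category), spp$true_category)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_species(generator_config(c(5, 5, 5, 5), seed = 7))
  b <- generate_species(generator_config(c(5, 5, 5, 5), seed = 7))
  expect_identical(a, b)
  c <- generate_species(generator_config(c(5, 5, 5, 5), seed = 8))
  expect_false(identical(a$n_offspring, c$n_offspring))
})

test_that("bounds straddling a set point are a config error", {
  expect_error(
    generator_config(n_bounds = list(predation = c(20, 1e6),
                                     scarcity = c(10, 20),
                                     weak = c(1, 8),
                                     convergent = c(20, 1e5))),
    "straddle"
  )
  expect_error(
    generator_config(s_bounds = list(predation = c(0.05, 0.2),
                                     scarcity = c(0.15, 0.6),
                                     weak = c(0.005, 0.08),
                                     convergent = c(0.15, 0.9))),
    "straddle"
  )
})

test_that("generated tables survive the CSV round trip with labels intact", {
  cfg <- generator_config(c(4, 4, 4, 4), seed = 5)
  path <- tempfile(fileext = ".csv")
  spp <- generate_species(cfg, path = path)
  suppressMessages(back <- read_species_table(path))
  expect_equal(nrow(back), 16)
  res <- classify_species(back)
  expect_equal(as.character(res$category), spp$true_category)
})

test_that("brood masses conserve total mass and respond to alpha", {
  b <- generate_brood(10, 100, alpha = 0.5, seed = 3)
  expect_equal(sum(b$mass), 100, tolerance = 1e-12)
  expect_true(all(b$mass >= 0))
  expect_setequal(b$rank, 1:10)

  eq <- generate_brood(10, 100, equal = TRUE)
  expect_equal(attr(eq, "gini"), 0)
  expect_equal(eq$mass, rep(10, 10))

  expect_error(generate_brood(1, 10), ">= 2")
  expect_error(generate_brood(5, 0), "positive")
  expect_error(generate_brood(5, 10, alpha = 0), "positive")
})

test_that("same-seed brood draws are identical and gini matches the oracle", {
  b1 <- generate_brood(8, 50, alpha = 1, seed = 123)
  b2 <- generate_brood(8, 50, alpha = 1, seed = 123)
  expect_identical(b1$mass, b2$mass)
  expect_equal(attr(b1, "gini"), gini_pairwise_oracle(b1$mass),
               tolerance = 1e-12)
})

test_that("mean brood Gini decreases as the Dirichlet concentration grows", {
  withr::local_seed(2026)
  mean_g <- vapply(c(0.1, 1, 10), function(a) {
    mean(vapply(1:5000, function(i)
      attr(generate_brood(6, 30, alpha = a), "gini"), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_g) < 0))
})

test_that("harness hits the closed-form extremes", {
  reg <- data.frame(p = c(0, 1), threshold = 0)
  sim <- run_conjecture_harness(reg, alphas = c(1), n = 6, total_mass = 60,
                                replicates = 300, seed = 4)
  cells <- tidy(sim)
  expect_equal(cells$replacement_freq[cells$p == 0], 1)
  expect_equal(cells$replacement_freq[cells$p == 1], 0)
  expect_true(all(cells$replacement_freq >= 0 & cells$replacement_freq <= 1))
})

test_that("harness is bit-identical for identical seeds", {
  reg <- data.frame(p = 0.4, threshold = 5)
  s1 <- run_conjecture_harness(reg, alphas = c(0.5, Inf), n = 8,
                               total_mass = 80, replicates = 200, seed = 99)
  s2 <- run_conjecture_harness(reg, alphas = c(0.5, Inf), n = 8,
                               total_mass = 80, replicates = 200, seed = 99)
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(glance(s1), glance(s2))
})

test_that("Monte-Carlo replacement matches exact enumeration on a two-tier brood", {
  # three well-fed and three subsistence offspring; the threshold splits them
  masses <- c(16, 16, 16, 3, 3, 3)
  p <- 0.5; thr <- 10
  exact <- replacement_prob_oracle(masses, p, thr, w = 2)
  reps <- 20000
  sim <- run_conjecture_harness(data.frame(p = p, threshold = thr),
                                masses = masses, replicates = reps,
                                seed = 2718)
  mc <- tidy(sim)$replacement_freq
  se <- sqrt(exact * (1 - exact) / reps)
  expect_lt(abs(mc - exact), 3 * se)
  # the equal brood spreads the same total below the threshold (share 9.5),
  # so under this regime it can never replace — the unequal brood can
  eq_masses <- rep(mean(masses), 6)
  exact_eq <- replacement_prob_oracle(eq_masses, p, thr, w = 2)
  expect_identical(exact_eq, 0)
  expect_gt(exact, 0)
  sim_eq <- run_conjecture_harness(data.frame(p = p, threshold = thr),
                                   masses = eq_masses, replicates = reps,
                                   seed = 2719)
  expect_identical(tidy(sim_eq)$replacement_freq, 0)
})

test_that("simulation accessors and plot work", {
  reg <- data.frame(p = c(0.2, 0.7), threshold = c(2, 8))
  sim <- run_conjecture_harness(reg, alphas = c(0.3, 2, Inf), n = 6,
                                total_mass = 60, replicates = 150, seed = 1)
  expect_equal(nrow(tidy(sim)), 6)
  g <- glance(sim)
  expect_equal(g$replicates, 150)
  expect_true(is.na(g$cor_g_c) || (g$cor_g_c >= -1 && g$cor_g_c <= 1))
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_error(run_conjecture_harness(data.frame(p = 1.5, threshold = 0)),
               "\\[0, 1\\]")
})
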