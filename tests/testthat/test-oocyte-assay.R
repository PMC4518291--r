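geom <- oocyte_geometry(V0 = 9.05e-4, apparent_area = 4.52e-2)

make_tc <- function(rel, times = seq(0, 20, 2), osm_in = 200, osm_out = 20)
  swelling_timecourse(times, rel, osm_in, osm_out, geom)

test_that("the initial slope is the OLS slope of relative volume on time", {
  t <- seq(0, 20, 2)
  exact <- make_tc(1 + 0.002 * t)
  est <- estimate_initial_slope(exact)
  expect_equal(est$slope, 0.002, tolerance = 1e-12)
  expect_equal(est$fit_r2, 1)

  flat <- estimate_initial_slope(make_tc(rep(1, 11)))
  expect_equal(flat$slope, 0)

  expect_error(estimate_initial_slope(make_tc(1 + 0.002 * t),
                                      window = c(0, 2)),
               "at least 3 samples")

  # sub-window fitting uses only the requested points
  sub <- estimate_initial_slope(make_tc(1 + 0.002 * t), window = c(0, 4))
  expect_equal(sub$n_points, 3L)
})

test_that("oocyte geometry derives S from the folding correction", {
  expect_equal(geom$S, 9 * 4.52e-2)
  expect_equal(oocyte_geometry(1, 2, folding_factor = 1)$S, 2)
  expect_error(oocyte_geometry(-1, 1), "positive")
})

test_that("the permeability formula reproduces hand-computed values", {
  # unit inputs
  expect_equal(pf_formula(V0 = 1, S = 1, slope = 0.5, delta_c = 1, Vw = 1), 0.5)
  expect_equal(pf_formula(1, 1, 0, 1, 1), 0)
  expect_error(pf_formula(1, 1, 1, 0), "undefined")

  # spherical oocyte, 200 -> 20 mOsm, slope 1e-3/s; hand-evaluated:
  # 9.05e-4 * 1e-3 / (0.4068 * 18 * 1.8e-4) = 6.8663e-4 cm/s
  tc <- make_tc(rep(1, 11))
  pf <- compute_pf(tc, slope = 1e-3)
  expect_equal(pf$Pf, 6.8663e-4, tolerance = 1e-4)
  expect_equal(pf$delta_c_mol_cm3, 1.8e-4)
  expect_equal(compute_pf(tc, slope = 0)$Pf, 0)
})

test_that("Pf is linear in slope and inversely proportional to gradient and surface", {
  set.seed(21)
  for (i in 1:20) {
    V0 <- runif(1, 5e-4, 2e-3); area <- runif(1, 0.02, 0.08)
    sl <- runif(1, 1e-4, 5e-3); dosm <- runif(1, 50, 300)
    g <- oocyte_geometry(V0, area)
    tc <- swelling_timecourse(seq(0, 20, 2), rep(1, 11), dosm + 20, 20, g)
    base <- compute_pf(tc, slope = sl)$Pf
    expect_equal(compute_pf(tc, slope = 2 * sl)$Pf, 2 * base)
    tc2 <- swelling_timecourse(seq(0, 20, 2), rep(1, 11), 2 * dosm + 20, 20, g)
    expect_equal(compute_pf(tc2, slope = sl)$Pf, base / 2)
    g2 <- oocyte_geometry(V0, 2 * area)
    tc3 <- swelling_timecourse(seq(0, 20, 2), rep(1, 11), dosm + 20, 20, g2)
    expect_equal(compute_pf(tc3, slope = sl)$Pf, base / 2)
  }
})

test_that("simulated swelling courses recover the generating Pf", {
  cfg <- swelling_sim_config(pf = 1e-3, sigma = 0.002, n_oocytes = 10,
                             seed = 77)
  sim <- simulate_swelling(cfg)
  ests <- vapply(sim$timecourses, function(tc) compute_pf(tc)$Pf, 0)
  expect_lt(abs(mean(ests) / 1e-3 - 1), 0.1)
  # estimated slope within 10% of the simulator's analytic initial slope
  sl <- vapply(sim$timecourses,
               function(tc) estimate_initial_slope(tc)$slope, 0)
  expect_lt(abs(mean(sl) / sim$truth$initial_slope - 1), 0.1)
})

test_that("uptake conversion subtracts background and is linear in excess counts", {
  m <- uptake_measurement(counts = rep(150, 5), zero_time_counts = rep(150, 4))
  u <- compute_uptake(m, conversion = 10)
  expect_equal(u$per_oocyte, rep(0, 5))

  m2 <- uptake_measurement(counts = rep(300, 5), zero_time_counts = rep(150, 4))
  u2 <- compute_uptake(m2, conversion = 10)
  expect_equal(u2$per_oocyte, rep(15, 5))  # excess 150 counts / 10 per pmol
  expect_equal(u2$mean, 15)

  # derived conversion: SA 50 Ci/mmol, eff 1, 5 uM hot in 1 mM cold
  u3 <- compute_uptake(uptake_measurement(counts = 200, zero_time_counts = 100))
  expect_equal(u3$conversion, 50 * 2.22e12 * 1e-9 * (5e-6 / (5e-6 + 1e-3)))

  # negative excess clamps to zero and is flagged
  m4 <- uptake_measurement(counts = c(100, 40), zero_time_counts = rep(80, 3))
  u4 <- compute_uptake(m4, conversion = 10)
  expect_equal(u4$n_clamped, 1L)
  expect_true(all(u4$per_oocyte >= 0))

  expect_error(compute_uptake(m4, conversion = 0), "degenerate")
})

test_that("simulated Poisson uptake is recovered within sampling error", {
  m <- simulate_uptake_counts(truth_pmol = 50, conversion = 10,
                              background = 100, n = 10, seed = 3)
  u <- compute_uptake(m, conversion = 10)
  expect_lt(abs(u$mean - 50), 2 * u$sem + 2)  # zero-time noise adds a little

  m0 <- simulate_uptake_counts(0, conversion = 10, background = 100,
                               n = 200, seed = 4)
  expect_lt(abs(mean(m0$counts) - 100), 3 * sqrt(100 / 200))

  expect_warning(simulate_uptake_counts(5, conversion = 0, background = 10,
                                        n = 3, seed = 5), "no information")
})

test_that("the dose-response plateau is the first dose not below the maximum", {
  doses <- rep(c(0.5, 1.5, 3, 6, 15, 30), each = 6)
  # flat: everything is at plateau, lowest dose wins
  set.seed(15)
  flat <- dose_response_plateau(doses, rnorm(length(doses), 5, 0.1))
  expect_equal(flat$plateau_dose, 0.5)

  # saturating curve whose ceiling is reached at 15 ng
  sat_means <- c(2, 4, 6, 8, 10, 10)
  pf <- rep(sat_means, each = 6) + rnorm(length(doses), 0, 0.3)
  sat <- dose_response_plateau(doses, pf)
  expect_equal(sat$plateau_dose, 15)

  # strictly increasing with large separation: only the top dose qualifies
  inc <- dose_response_plateau(doses, rep(c(1, 2, 3, 4, 5, 6) * 10, each = 6) +
                                 rnorm(length(doses), 0, 0.01))
  expect_equal(inc$plateau_dose, 30)

  expect_error(dose_response_plateau(c(1, 1, 2), c(1, 2, 3)), ">= 2 replicates")
})

test_that("one-way ANOVA matches hand computation and handles degeneracy", {
  # two groups of three: SSB = 13.5 (df 1), SSW = 4 (df 4) -> F = 13.5
  cmp <- compare_groups_anova(c(1, 2, 3, 4, 5, 6),
                              rep(c("ctrl", "trt"), each = 3), "ctrl")
  expect_equal(cmp$f_statistic, 13.5, tolerance = 1e-10)
  expect_equal(cmp$p_value, pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)

  # all observations identical: F undefined, p reported as 1
  deg <- compare_groups_anova(rep(2, 6), rep(c("a", "b"), each = 3), "a")
  expect_true(is.na(deg$f_statistic))
  expect_equal(deg$p_value, 1)

  expect_error(compare_groups_anova(1:4, rep("a", 4), "a"), "2 groups")
})

test_that("versus-control comparisons star clearly separated groups", {
  set.seed(33)
  vals <- c(rnorm(8, 0, 0.5), rnorm(8, 5, 0.5), rnorm(8, 0.1, 0.5))
  grp <- rep(c("water", "strong", "null"), each = 8)
  cmp <- compare_groups_anova(vals, grp, control = "water")
  vs <- cmp$vs_control
  expect_equal(vs$stars[vs$comparison == "strong - water"], "**")
  expect_equal(vs$stars[vs$comparison == "null - water"], "")
  expect_equal(cmp$group_summary$n, rep(8L, 3))
  # sem definition: sd / sqrt(n)
  w <- vals[grp == "water"]
  expect_equal(cmp$group_summary$sem[cmp$group_summary$group == "water"],
               sd(w) / sqrt(8))

  # Holm fallback gives the same qualitative answer
  cmp2 <- compare_groups_anova(vals, grp, control = "water", method = "holm")
  expect_equal(cmp2$vs_control$stars[vs$comparison == "strong - water"], "**")
})
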