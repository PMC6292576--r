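test_that("an area spike followed by decline is called at the spike", {
  area <- c(100, 101, 99, 100, 160, 140, 70, 60, 60, 58)
  r <- detect_endpoint_area_peak(area, delta = 0.3)
  expect_false(r$censored)
  expect_equal(r$index, 5)
  expect_equal(r$death_time_h, 4)      # default 0-based hourly grid
  expect_gt(r$diagnostics$peak_ratio, 1.3)
})

test_that("healthy monotone growth is censored, not called", {
  r <- detect_endpoint_area_peak(seq(100, 400, length.out = 20))
  expect_true(r$censored)
  expect_true(is.na(r$death_time_h))
  expect_error(detect_endpoint_area_peak(c(1, 2, 3)), "5 timepoints")
})

test_that("the energy-drop rule follows its hand-traced definition", {
  r <- detect_endpoint_energy_drop(c(10, 10, 10, 1, 1, 1),
                                   theta = 0.5, m = 2L, k = 3L)
  expect_false(r$censored)
  expect_equal(r$index, 4)             # death at the 4th timepoint
  expect_equal(r$death_time_h, 3)
  # constant energy: censored
  expect_true(detect_endpoint_energy_drop(rep(10, 8), theta = 0.5,
                                          m = 2L, k = 3L)$censored)
  # one-timepoint transient dip rejected by persistence
  expect_true(detect_endpoint_energy_drop(c(10, 10, 10, 1, 10, 10, 10),
                                          theta = 0.5, m = 2L,
                                          k = 3L)$censored)
  # undetermined when the baseline cannot be formed
  u <- detect_endpoint_energy_drop(c(NaN, NaN, NaN, 1, 1, 1),
                                   theta = 0.5, m = 2L, k = 3L)
  expect_true(u$undetermined)
})

test_that("raising theta can only make death calls earlier or equal", {
  set.seed(19)
  for (i in 1:10) {
    e <- pmax(10 * exp(-(0:24) / runif(1, 3, 12)) +
                rnorm(25, 0, 0.3), 0.01)
    lo <- detect_endpoint_energy_drop(e, theta = 0.2)
    hi <- detect_endpoint_energy_drop(e, theta = 0.5)
    if (!lo$censored) {
      expect_false(hi$censored)
      expect_lte(hi$death_time_h, lo$death_time_h)
    }
  }
})

test_that("stage routing picks area-peak for E3 and energy-drop later", {
  coh <- generate_trait_cohort(2, death_times_h = c(8, 8),
                               death_model = list(mode = "osmotic"),
                               seed = 3)
  e3 <- identify_lethal_endpoints(
    phenome_dataset("A", traits = coh$traits[[1]]), "E3")
  expect_equal(e3$method, "area_peak")
  expect_false(e3$censored)
  expect_lte(abs(e3$death_time_h - 8), 2)

  ces <- generate_trait_cohort(1, death_times_h = 8,
                               death_model = list(mode = "cardiac_cessation"),
                               seed = 4)
  e9 <- identify_lethal_endpoints(
    phenome_dataset("B", traits = ces$traits[[1]]), "E9")
  expect_equal(e9$method, "energy_drop")
  expect_false(e9$censored)
  expect_lte(abs(e9$death_time_h - 8), 2)

  # E3 cessation-style death (stable area): the energy fallback catches it
  e3b <- identify_lethal_endpoints(
    phenome_dataset("C", traits = ces$traits[[1]]), "E3")
  expect_equal(e3b$method, "combined")
  expect_false(e3b$censored)

  healthy <- generate_trait_cohort(1, death_times_h = NA_real_, seed = 5)
  h <- identify_lethal_endpoints(
    phenome_dataset("D", traits = healthy$traits[[1]]), "E7")
  expect_true(h$censored)
  expect_error(identify_lethal_endpoints(
    phenome_dataset("D", traits = healthy$traits[[1]]), "E5"),
    "unknown developmental stage")
})

test_that("cohort death times are recovered within two recording intervals", {
  coh <- generate_trait_cohort(60, seed = 101)
  calls <- lapply(names(coh$traits), function(id)
    identify_lethal_endpoints(phenome_dataset(id, traits = coh$traits[[id]]),
                              "E3"))
  calls <- do.call(rbind, calls)
  truth <- coh$truth
  died <- !is.na(truth$death_time_h)
  expect_gt(sum(died), 20)             # the cohort really contains deaths
  hit <- !calls$censored[died] &
    abs(calls$death_time_h[died] - truth$death_time_h[died]) <= 2
  expect_gte(mean(hit), 0.95)
  # false alarms on survivors are rare
  expect_lte(mean(!calls$censored[!died]), 0.1)
})

test_that("survival curves and LT percentiles follow the step convention", {
  # point mass: every embryo dies at 10 h
  pm <- survival_curve(rep(10, 4))
  expect_equal(unname(lt_percentiles(pm, 50)), 10)
  # staggered deaths at 2, 6, 10, 14 h
  sc <- survival_curve(c(2, 6, 10, 14))
  expect_equal(sc$proportion_surviving, c(1, 0.75, 0.5, 0.25, 0))
  lt <- lt_percentiles(sc)
  expect_equal(unname(lt), c(2, 6, 10))
  expect_true(lt["LT25"] <= lt["LT50"] && lt["LT50"] <= lt["LT75"])
  # censored cohort: no level is ever reached
  none <- survival_curve(rep(NA_real_, 5), time_grid_h = 0:24)
  expect_true(all(is.nan(lt_percentiles(none))))
  expect_true(all(none$proportion_surviving == 1))
  expect_error(lt_percentiles(sc, 0), "between 0 and 100")
})

test_that("survival curves are non-increasing with conserved risk sets", {
  set.seed(55)
  for (i in 1:5) {
    dt <- ifelse(runif(30) < 0.7, round(rexp(30, 0.1)), NA)
    sc <- survival_curve(dt, time_grid_h = seq(0, 50, by = 1))
    expect_true(all(diff(sc$proportion_surviving) <= 0))
    expect_true(all(sc$proportion_surviving >= 0 &
                    sc$proportion_surviving <= 1))
    expect_equal(sc$proportion_surviving[1], 1 - sum(dt %in% 0) / 30)
    lt <- lt_percentiles(sc)
    fin <- lt[is.finite(lt)]
    expect_true(!is.unsorted(fin))
  }
})

test_that("cohort LT50 matches the analytic median of realized deaths", {
  coh <- generate_trait_cohort(60, seed = 202,
                               death_model = list(rate_per_h = 0.12,
                                                  mode = "mixed"))
  calls <- do.call(rbind, lapply(names(coh$traits), function(id)
    identify_lethal_endpoints(phenome_dataset(id, traits = coh$traits[[id]]),
                              "E3")))
  sc <- survival_curve(calls$death_time_h, time_grid_h = 0:24)
  lt50 <- unname(lt_percentiles(sc, 50))
  realized <- coh$truth$death_time_h
  analytic_median <- median(realized, na.rm = TRUE)
  expect_lte(abs(lt50 - analytic_median), 1)   # one recording interval
})
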