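test_that("photosensitizer presets peak where their absorption bands sit", {
  hyp <- photosensitizer("hypericin")
  expect_equal(relative_absorbance(hyp, 590), 1, tolerance = 0.02)
  expect_gt(relative_absorbance(hyp, 542), 0.5)
  expect_lt(relative_absorbance(hyp, 450), 0.05)
  fos <- photosensitizer("foscan")
  expect_equal(relative_absorbance(fos, 406), 1, tolerance = 0.02)
  expect_gt(relative_absorbance(fos, 652), 0.2)
  expect_lt(relative_absorbance(fos, 652), 0.4)
  # tabulated spectra renormalize to max 1 and reject out-of-range lookups
  tab <- photosensitizer("x", spectrum = data.frame(
    wavelength = c(400, 500, 600), absorbance = c(2, 4, 1)))
  expect_equal(relative_absorbance(tab, 500), 1)
  expect_error(relative_absorbance(tab, 700), "outside")
})

test_that("time to target follows E/(P x duty)", {
  expect_equal(time_to_target(0.001, 1, 1), 1000)
  expect_equal(time_to_target(0.001, 1, 0.25), 4000)
  expect_equal(time_to_target(0.5, 0, 1), 0)
  expect_error(time_to_target(0, 1, 1), "power")
  expect_error(time_to_target(1, 1, 0), "duty")
})

test_that("regimen scoring is seed-deterministic and respects criterion bounds", {
  ph <- build_preset_phantom("default", 1)
  sch <- illumination_schedule("pulsed", 25, 10, duration_s = 30)
  reg <- regimen_spec(photosensitizer("foscan"),
                      list(light_source(c(10, 10, 0), wavelength = 406,
                                        power_mW = 10),
                           light_source(c(10, 10, 0), wavelength = 652,
                                        power_mW = 10)),
                      schedule = sch, target_energy_J = 0.5)
  a <- score_regimen(ph, reg, n_photons = 2000, seed = 3,
                     thermal_duration_s = 5)
  b <- score_regimen(ph, reg, n_photons = 2000, seed = 3,
                     thermal_duration_s = 5)
  expect_identical(a$absorbance_fraction, b$absorbance_fraction)
  expect_identical(a$time_to_target_s, b$time_to_target_s)
  expect_gte(a$absorbance_fraction, 0); expect_lte(a$absorbance_fraction, 1)
  expect_gte(a$uniformity, 0); expect_lte(a$uniformity, 1)
  expect_gte(a$penetration_mm, 0)
  expect_gte(a$delta_T_C, 0)
  expect_false(a$unreachable)
})

test_that("zero-power regimens flag the target as unreachable", {
  ph <- build_preset_phantom("default", 1)
  reg <- regimen_spec(photosensitizer("foscan"),
                      list(light_source(c(10, 10, 0), wavelength = 652,
                                        power_mW = 0)),
                      schedule = illumination_schedule("constant",
                                                      duration_s = 10),
                      target_energy_J = 1)
  s <- score_regimen(ph, reg, n_photons = 500, seed = 1,
                     thermal_duration_s = 2)
  expect_true(s$unreachable)
  expect_identical(s$absorbance_fraction, 0)
})

test_that("dual-band activation beats the single band it contains", {
  # with equal total power, adding a band the photosensitizer absorbs
  # cannot lower the activation-weighted tumor dose (additivity)
  ph <- build_preset_phantom("default", 1)
  ps <- photosensitizer("foscan")
  src <- function(wl, p) light_source(c(10, 10, 0), wavelength = wl,
                                      power_mW = p)
  t406 <- run_transport(ph, src(406, 10), 4000, seed = 1)
  t652 <- run_transport(ph, src(652, 10), 4000, seed = 2)
  tumor <- label_mask(ph, "tumor")
  both <- sum(combine_wavelengths(list(t406, t652), ps,
                                  weights = c(10, 10))[tumor])
  only652 <- sum(combine_wavelengths(list(t652), ps, weights = 20)[tumor])
  dose406 <- sum(combine_wavelengths(list(t406), ps, weights = 10)[tumor])
  dose652 <- sum(combine_wavelengths(list(t652), ps, weights = 10)[tumor])
  expect_equal(both, dose406 + dose652)
  # the Soret-like 406 nm band is absorbed far more strongly, so replacing
  # half the 652 nm power with 406 nm raises the activation-weighted dose
  expect_gt(dose406, dose652)
  expect_gt(both, only652)
})

test_that("single candidates rank trivially with all normalized values 1", {
  rk <- rank_regimens(list(fake_score(1, 0.2, 0.5, 100, 0.1)))
  expect_equal(rk$order, 1)
  expect_true(all(rk$normalized == 1))
  expect_false(rk$pareto_dominated)
  expect_error(rank_regimens(list()), "no scores")
})

test_that("a candidate strictly better on all criteria ranks first", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    scores <- replicate(n, fake_score(runif(1, 1, 5), runif(1), runif(1),
                                      runif(1, 100, 1e4), runif(1, 0, 2)),
                        simplify = FALSE)
    dom <- fake_score(6, 1, 1, 50, 0)  # dominates everything
    rk <- rank_regimens(c(scores, list(dom)))
    expect_equal(rk$order[1], n + 1)
    expect_false(rk$pareto_dominated[n + 1])
    expect_true(all(rk$pareto_dominated[seq_len(n)]))
  }
})

test_that("ranking never places a Pareto-dominated candidate above its dominator", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    scores <- replicate(n, fake_score(runif(1, 0, 5), runif(1), runif(1),
                                      runif(1, 10, 1e4), runif(1, 0, 3)),
                        simplify = FALSE)
    rk <- rank_regimens(scores)
    pos <- match(seq_len(n), rk$order)
    raw <- rk$raw
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      hb <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
      ge <- all(ifelse(hb, as.numeric(raw[a, ]) >= as.numeric(raw[b, ]),
                       as.numeric(raw[a, ]) <= as.numeric(raw[b, ])))
      gt <- any(ifelse(hb, as.numeric(raw[a, ]) > as.numeric(raw[b, ]),
                       as.numeric(raw[a, ]) < as.numeric(raw[b, ])))
      if (ge && gt) {
        expect_lt(pos[a], pos[b])
        expect_true(rk$pareto_dominated[b] || !all(ge))
      }
    }
  }
})

test_that("ranking is invariant under affine rescaling of one criterion", {
  set.seed(13)
  scores <- replicate(5, fake_score(runif(1, 0, 5), runif(1), runif(1),
                                    runif(1, 10, 1e4), runif(1, 0, 3)),
                      simplify = FALSE)
  rk1 <- rank_regimens(scores)
  rescaled <- lapply(scores, function(s) {
    s$penetration_mm <- 3.2 * s$penetration_mm + 11
    s
  })
  rk2 <- rank_regimens(rescaled)
  expect_equal(rk1$order, rk2$order)
  expect_equal(rk1$normalized, rk2$normalized)
})
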