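test_that("zero photons yield an all-zero tally", {
  ph <- absorbing_phantom()
  src <- light_source(c(5, 5, 0), beam = "pencil", wavelength = 652)
  tl <- run_transport(ph, src, 0, seed = 1)
  expect_true(all(tl$absorbed == 0))
  expect_equal(tl$reflected_fraction + tl$transmitted_fraction +
                 tl$escaped_fraction, 0)
})

test_that("depth-binned absorption matches Beer-Lambert within 3 MC standard errors", {
  ph <- absorbing_phantom(voxel = 0.1, cube = 10, mu_a = 1, mu_s = 0, n = 1)
  src <- light_source(c(5, 5, 0), beam = "pencil", wavelength = 652)
  n <- 1e5
  tl <- run_transport(ph, src, n, seed = 42)
  # aggregate the voxel planes into 0.5 mm depth bins so the per-bin 3-SE
  # band is appropriate for the ~10 simultaneous comparisons it implies
  per_plane <- apply(tl$absorbed, 3, sum)
  obs <- vapply(seq_len(10), function(b)
    sum(per_plane[(5 * b - 4):(5 * b)]), numeric(1))
  edges <- (0:10) * 0.5
  p <- exp(-edges[-11]) - exp(-edges[-1])
  se <- sqrt(p * (1 - p) / n)
  expect_lt(max(abs(obs - p) / se), 3)
})

test_that("identical seeds give bitwise-identical tallies", {
  ph <- absorbing_phantom(mu_a = 0.3, mu_s = 3, g = 0.8, n = 1.4)
  src <- light_source(c(5, 5, 0), beam = "cone", wavelength = 652)
  a <- run_transport(ph, src, 3000, seed = 9)
  b <- run_transport(ph, src, 3000, seed = 9)
  expect_identical(a$absorbed, b$absorbed)
  expect_identical(a$reflected_fraction, b$reflected_fraction)
  c <- run_transport(ph, src, 3000, seed = 10)
  expect_false(identical(a$absorbed, c$absorbed))
})

test_that("energy ledger closes to machine precision in scattering media", {
  ph <- absorbing_phantom(mu_a = 0.2, mu_s = 4, g = 0.9, n = 1.4)
  src <- light_source(c(5, 5, 0), beam = "cone", wavelength = 652)
  for (seed in c(1, 7, 23)) {
    tl <- run_transport(ph, src, 5000, seed = seed)
    expect_lt(abs(energy_balance_residual(tl)), 1e-6)
  }
})

test_that("fluence map implements absorbed/(mu_a * voxel volume)", {
  ph <- absorbing_phantom(voxel = 0.1, mu_a = 1, mu_s = 0, n = 1)
  src <- light_source(c(5, 5, 0), beam = "pencil", wavelength = 652)
  tl <- run_transport(ph, src, 1e4, seed = 3)
  fl <- fluence_map(tl, ph)
  expect_equal(fl, tl$absorbed / (1 * 0.1^3))
  # doubling mu_a with the same tally halves fluence
  ph2 <- set_optical_properties(ph, "dermis", 652, mu_a = 2, mu_s = 0,
                                g = 0, n = 1)
  expect_equal(fluence_map(tl, ph2), fl / 2)
  # zero tally -> zero fluence
  tl0 <- run_transport(ph, src, 0, seed = 1)
  expect_true(all(fluence_map(tl0, ph) == 0))
})

test_that("penetration depth reproduces 1/mu_a in a Beer-Lambert medium", {
  src <- light_source(c(5, 5, 0), beam = "pencil", wavelength = 652)
  for (mua in c(1, 2)) {
    ph <- absorbing_phantom(voxel = 0.1, mu_a = mua, mu_s = 0, n = 1)
    tl <- run_transport(ph, src, 1e5, seed = 11)
    expect_equal(as.numeric(penetration_depth(tl, ph)), 1 / mua,
                 tolerance = 0.05)
  }
})

test_that("penetration depth is monotone non-increasing in mu_a", {
  src <- light_source(c(5, 5, 0), beam = "pencil", wavelength = 652)
  depths <- vapply(c(0.5, 1, 2, 4), function(mua) {
    ph <- absorbing_phantom(voxel = 0.1, mu_a = mua, mu_s = 0, n = 1)
    as.numeric(penetration_depth(run_transport(ph, src, 2e4, seed = 5), ph))
  }, numeric(1))
  expect_true(all(diff(depths) <= 0))
})

test_that("penetration depth flags truncation in a near-transparent medium", {
  ph <- absorbing_phantom(voxel = 0.5, cube = 10, mu_a = 0.01, mu_s = 0, n = 1)
  src <- light_source(c(5, 5, 0), beam = "pencil", wavelength = 652)
  tl <- run_transport(ph, src, 2e4, seed = 2)
  pd <- penetration_depth(tl, ph)
  expect_true(attr(pd, "truncated"))
})

test_that("tumor absorption fraction equals the brute-force label sum", {
  ph <- build_preset_phantom("default", 0.5)
  src <- light_source(c(10, 10, 0), beam = "cone", wavelength = 652)
  tl <- run_transport(ph, src, 5000, seed = 4)
  f <- tumor_absorption_fraction(tl, ph)
  manual <- 0
  for (i in seq_len(40)) for (j in seq_len(40)) for (k in seq_len(40))
    if (ph$labels[i, j, k] == 3L) manual <- manual + tl$absorbed[i, j, k]
  expect_equal(f, manual)
  expect_lte(f, sum(tl$absorbed))
  # no tumor -> 0
  nt <- build_preset_phantom("no-tumor", 0.5)
  tl2 <- run_transport(nt, src, 2000, seed = 4)
  expect_identical(tumor_absorption_fraction(tl2, nt), 0)
})

test_that("tumor uniformity matches hand-computed CV and is scale-free", {
  ph <- build_preset_phantom("default", 0.5)
  # flat dose over tumor voxels -> 1
  flat <- array(0, dim = ph$dims)
  flat[label_mask(ph, "tumor")] <- 3.7
  expect_equal(tumor_uniformity(NULL, ph, map = flat), 1)
  # dose (1,0,0,0) over 4 voxels: CV = sqrt(3) (population sd)
  idx <- which(label_mask(ph, "tumor"))
  v4 <- array(0, dim = ph$dims)
  v4[label_mask(ph, "tumor")] <- 0
  ph4 <- ph
  ph4$labels[] <- 0L
  ph4$labels[idx[1:4]] <- 3L
  m <- array(0, dim = ph$dims)
  m[idx[1]] <- 1
  expect_equal(tumor_uniformity(NULL, ph4, map = m), 1 / (1 + sqrt(3)))
  expect_equal(tumor_uniformity(NULL, ph4, map = m * 17),
               tumor_uniformity(NULL, ph4, map = m))
  expect_error(tumor_uniformity(NULL, ph4, map = m * 0), "zero tumor dose")
})

test_that("wavelength combination is linear and spectrum-weighted", {
  ph <- build_preset_phantom("default", 0.5)
  ps <- photosensitizer("foscan")
  s406 <- light_source(c(10, 10, 0), beam = "cone", wavelength = 406)
  s652 <- light_source(c(10, 10, 0), beam = "cone", wavelength = 652)
  tA <- run_transport(ph, s406, 2000, seed = 1)
  tB <- run_transport(ph, s652, 2000, seed = 2)
  both <- combine_wavelengths(list(tA, tB), ps)
  expect_equal(both, combine_wavelengths(list(tA), ps) +
                 combine_wavelengths(list(tB), ps))
  # unit absorbance is the identity on the tally
  flat <- photosensitizer("flat", spectrum = data.frame(
    wavelength = c(400, 700), absorbance = c(1, 1)))
  expect_equal(combine_wavelengths(list(tA), flat), tA$absorbed)
  # zero absorbance wipes the map
  zero <- photosensitizer("z", spectrum = data.frame(
    wavelength = c(400, 500, 700), absorbance = c(1, 0, 0)))
  expect_true(all(combine_wavelengths(list(tB), zero) == 0))
})

test_that("radial fluence around an isotropic point source follows diffusion theory", {
  ph <- build_preset_phantom("homogeneous", 0.5, cube_mm = 16)
  ph <- set_optical_properties(ph, "dermis", 590, mu_a = 0.1, mu_s = 10,
                               g = 0, n = 1)
  src <- light_source(c(8, 8, 8), beam = "isotropic", wavelength = 590)
  tl <- run_transport(ph, src, 2e4, seed = 5, roulette_threshold = 1e-3)
  fl <- fluence_map(tl, ph)
  cc <- (seq_len(32) - 0.5) * 0.5
  r <- sqrt(outer(outer((cc - 8)^2, (cc - 8)^2, "+"), (cc - 8)^2, "+"))
  mu_eff <- sqrt(3 * 0.1 * (0.1 + 10))
  mids <- seq(1, 3.5, by = 0.5)
  obs <- vapply(mids, function(m) mean(fl[r >= m - 0.25 & r < m + 0.25]),
                numeric(1))
  theory <- exp(-mu_eff * mids) / mids
  ratio <- (obs / theory) / (obs[1] / theory[1])
  expect_lt(max(abs(ratio - 1)), 0.15)
})

test_that("off-grid sources are rejected", {
  ph <- absorbing_phantom()
  expect_error(run_transport(ph, light_source(c(50, 5, 0), beam = "pencil",
                                              wavelength = 652), 10, 1),
               "surface source")
  expect_error(run_transport(ph, light_source(c(5, 5, 5), beam = "pencil",
                                              wavelength = 652), 10, 1))
  expect_error(run_transport(ph, light_source(c(5, 5, 50),
                                              beam = "isotropic",
                                              wavelength = 652), 10, 1),
               "inside the grid")
})
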