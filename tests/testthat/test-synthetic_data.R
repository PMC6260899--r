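test_that("published schemes have the stated structure", {
  ivim <- paper_scheme("ivim")
  expect_equal(length(unique(ivim$bvalues)), 10L)
  expect_equal(max(ivim$bvalues), 700)
  expect_equal(sum(ivim$bvalues == 0), 1L)
  expect_equal(sum(ivim$bvalues == 100), 6L)

  dti <- paper_scheme("dti")
  expect_equal(length(dti), 31L)
  expect_equal(sort(unique(dti$bvalues)), c(0, 100, 300))

  # directions pairwise non-collinear (and unit norm, by construction)
  for (sch in list(ivim, dti)) {
    d <- unique(sch$directions[sch$bvalues > 0, ])
    gram <- abs(d %*% t(d))
    diag(gram) <- 0
    expect_lt(max(gram), 1 - 1e-3)
  }
  expect_error(paper_scheme("flair"))
})

test_that("make_phantom emits per-label decay consistent with its presets", {
  ivim <- paper_scheme("ivim")
  # single-label phantom: constant S0 at b = 0
  spec1 <- phantom_spec(shape = c(4, 4, 2), tissues = list(
    cortex = list(preset = "healthy_cortex",
                  region = list("box", c(1, 4), c(1, 4), c(1, 2)))), snr = Inf)
  ph1 <- make_phantom(spec1, scheme = ivim)
  b0_vol <- ph1$volume[, , , which(ivim$bvalues == 0)]
  expect_true(all(b0_vol == 100))

  # cyst decays below cortex at b = 700 (higher D_tri)
  ph <- tiny_phantom()
  i700 <- which(ph$scheme$bvalues == 700)[1]
  cortex_vox <- ph$labels$voxels == 1
  cyst_vox <- ph$labels$voxels == 2
  s700 <- ph$volume[, , , i700]
  expect_lt(max(s700[cyst_vox]), min(s700[cortex_vox]))

  # noise-free signals satisfy forward-model invariants per voxel
  ub <- sort(unique(ph$scheme$bvalues))
  avg <- average_directions(ph$volume[1, 1, 1, ], ph$scheme, "geometric")
  expect_true(all(avg$signal > 0))
  expect_true(all(diff(avg$signal) < 0))

  # truth maps match the presets
  expect_equal(unique(ph$truth$D_tri[cortex_vox]), 1.41)
  expect_equal(unique(ph$truth$D_tri[cyst_vox]), 2.74)

  # overlapping regions are rejected at spec time
  expect_error(phantom_spec(shape = c(4, 4, 2), tissues = list(
    a = list(preset = "cyst", region = list("box", c(1, 3), c(1, 4), c(1, 2))),
    b = list(preset = "cc_rcc", region = list("box", c(3, 4), c(1, 4), c(1, 2)))
  )), "overlap")
  # label without parameters errors at generation time
  spec_bad <- spec1
  spec_bad$tissues$cortex$preset <- NULL
  expect_error(make_phantom(spec_bad, scheme = ivim), "preset")
})

test_that("Rician noise has the stated law and is reproducible", {
  vol <- array(50, c(5, 5, 2, 3))
  expect_identical(add_rician_noise(vol, 0), vol)
  expect_error(add_rician_noise(vol, -1), "non-negative")

  # closed-form mean at zero signal: sigma * sqrt(pi/2)
  z <- add_rician_noise(array(0, c(60, 60, 30)), sigma = 1, seed = 5)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.01)

  a <- add_rician_noise(vol, 2, seed = 42)
  b <- add_rician_noise(vol, 2, seed = 42)
  c <- add_rician_noise(vol, 2, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))

  # SNR -> infinity converges to the noise-free signal
  sig <- array(100, c(10, 10, 5))
  mad_at <- vapply(c(10, 100, 1000), function(snr) {
    mean(abs(add_rician_noise(sig, 100 / snr, seed = 7) - sig))
  }, numeric(1))
  expect_true(all(diff(mad_at) < 0))
  expect_lt(mad_at[3], 0.1)
})

test_that("cohort sampling reproduces its stated world", {
  co <- sample_cohort(n_solid = 13, n_cyst = 5, seed = 3, roi_voxels = 2)
  expect_equal(nrow(co$lesions), 18L)
  expect_length(co$datasets, 18L)
  expect_equal(sum(co$lesions$type == "cyst"), 5L)
  expect_equal(nrow(co$healthy), 36L)  # cortex + medulla per lesion

  # same seed identical, different seed different
  co2 <- sample_cohort(n_solid = 13, n_cyst = 5, seed = 3)
  expect_identical(co$lesions, co2$lesions)
  co3 <- sample_cohort(n_solid = 13, n_cyst = 5, seed = 4)
  expect_false(identical(co$lesions, co3$lesions))

  # single-preset cohort with zero SD collapses onto the preset means
  co0 <- sample_cohort(n_solid = 3, n_cyst = 0,
                       solid_presets = "cc_rcc_necrosis", seed = 1)
  expect_true(all(co0$lesions$D_tri == 0.71))
  expect_true(all(co0$lesions$f_fast == 6.13))

  # preset means preserved within 3 standard errors at n = 500
  big <- sample_cohort(n_solid = 500, n_cyst = 0, solid_presets = "cc_rcc",
                       seed = 9)
  p <- tissue_presets("cc_rcc")
  for (nm in c("MD", "D_tri", "f_interm")) {
    se <- p$sd[[nm]] / sqrt(500)
    expect_lt(abs(mean(big$lesions[[nm]]) - p$mean[[nm]]), 3 * se)
  }
})
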