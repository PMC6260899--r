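IVIM_B <- c(0, 10, 25, 40, 75, 100, 200, 300, 500, 700)

test_that("average_directions reduces per b-value in both modes", {
  sch <- acq_scheme(c(0, 100, 100), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  # identical signals -> that value in both modes
  for (mode in c("geometric", "arithmetic")) {
    avg <- average_directions(c(5, 2, 2), sch, mode)
    expect_equal(avg$signal, c(5, 2))
    expect_equal(avg$bvalues, c(0, 100))
  }
  # geometric mean of (e^0, e^2) is e^1; arithmetic differs
  avg <- average_directions(c(5, exp(0), exp(2)), sch, "geometric")
  expect_equal(avg$signal[2], exp(1))
  avg_a <- average_directions(c(5, exp(0), exp(2)), sch, "arithmetic")
  expect_equal(avg_a$signal[2], mean(c(1, exp(2))))
  # non-positive signal falls back to arithmetic, with a warning
  expect_warning(avg_f <- average_directions(c(5, -1, 3), sch, "geometric"),
                 "arithmetic")
  expect_equal(avg_f$signal[2], 1)

  # 6-direction data from an isotropic tensor averages to the MD mono decay
  ivim <- paper_scheme("ivim")
  iso <- tensor_fit(100, c(1.7, 1.7, 1.7, 0, 0, 0))
  sig <- predict_tensor(iso, ivim$bvalues, ivim$directions)
  avg_i <- average_directions(sig, ivim, "geometric")
  expect_equal(avg_i$signal,
               predict_mono(mono_params(100, tensor_md(iso)), avg_i$bvalues),
               tolerance = 1e-10)
})

test_that("fit_mono is exact on noise-free data and handles degenerate input", {
  sig <- exp(-IVIM_B * 1.5e-3)
  fit <- fit_mono(sig, IVIM_B)
  expect_equal(fit$params$D_mono, 1.5, tolerance = 1e-9)
  expect_equal(fit$params$S0, 1, tolerance = 1e-9)

  cfit <- fit_mono(rep(3, 10), IVIM_B)
  expect_equal(cfit$params$D_mono, 0, tolerance = 1e-12)

  expect_error(fit_mono(c(1, 2), c(100, 100)), "distinct b-values")
  expect_error(fit_mono(c(1, -1), c(0, 700)), "positive")

  # D_mono on tri-exp cortex data has the same order of magnitude as MD
  tri_sig <- predict_triexp(preset_triexp("healthy_cortex"), IVIM_B)
  dm <- fit_mono(tri_sig, IVIM_B)$params$D_mono
  expect_gt(dm, 2.16 / 3)
  expect_lt(dm, 2.16 * 3)
})

test_that("tensor WLLS recovers noise-free tensors and rejects spikes", {
  dti <- paper_scheme("dti")
  # isotropic cortex-MD tensor
  iso <- tensor_fit(100, c(2.16, 2.16, 2.16, 0, 0, 0))
  fit <- fit_tensor_wlls(predict_tensor(iso, dti$bvalues, dti$directions), dti)
  expect_equal(tensor_md(fit$params), 2.16, tolerance = 1e-6)
  expect_equal(tensor_fa(fit$params), 0, tolerance = 1e-6)
  expect_length(fit$excluded, 0)

  # anisotropic tensor built to FA 0.38 at MD 2.16
  aniso <- tensor_from_md_fa(2.16, 0.38, axis = c(1, 1, 0), S0 = 100)
  sig <- predict_tensor(aniso, dti$bvalues, dti$directions)
  fit_a <- fit_tensor_wlls(sig, dti)
  expect_equal(tensor_fa(fit_a$params), 0.38, tolerance = 1e-3)
  expect_equal(tensor_md(fit_a$params), 2.16, tolerance = 1e-6)
  # noise-free: equals the plain log-linear LS fit (nothing rejected)
  expect_length(fit_a$excluded, 0)
  expect_lte(fit_a$iterations, 3L)

  # a single 10x spike is rejected; result matches spike-free fit to 1e-6
  spiked <- sig
  spiked[17] <- spiked[17] * 10
  fit_s <- fit_tensor_wlls(spiked, dti)
  expect_equal(fit_s$excluded, 17L)
  expect_equal(fit_s$params$tensor, fit_a$params$tensor, tolerance = 1e-6)

  # manual-removal oracle: fit with the spike dropped from the scheme
  keep <- setdiff(seq_along(dti$bvalues), 17L)
  sch_m <- acq_scheme(dti$bvalues[keep], dti$directions[keep, ])
  fit_m <- fit_tensor_wlls(sig[keep], sch_m)
  expect_equal(fit_s$params$tensor, fit_m$params$tensor, tolerance = 1e-6)

  expect_error(fit_tensor_wlls(rep(1, 5), acq_scheme(
    c(0, 100, 100, 100, 100),
    rbind(c(0, 0, 0), diag(3)[c(1, 2, 3, 1), ]))), "at least 7")
})

test_that("bi-exponential fit recovers presets and beats the grid oracle", {
  cfg <- fit_config("biexp")
  p <- preset_biexp("healthy_cortex", S0 = 100)
  sig <- predict_biexp(p, IVIM_B)
  fit <- fit_biexp(sig, IVIM_B, cfg)
  expect_equal(fit$params$f_star, 0.101, tolerance = 0.01)
  expect_equal(fit$params$D_bi, 1.93, tolerance = 0.01)

  # degenerate f_star = 0
  sig0 <- predict_mono(mono_params(100, 1.8), IVIM_B)
  fit0 <- fit_biexp(sig0, IVIM_B, cfg)
  expect_lte(fit0$params$f_star, 0.005)
  expect_equal(fit0$params$D_bi, 1.8, tolerance = 1e-3)

  # NLLS residual <= exhaustive grid-search residual (cyst preset)
  pc <- preset_biexp("cyst", S0 = 100)
  sigc <- predict_biexp(pc, IVIM_B)
  fitc <- fit_biexp(sigc, IVIM_B, cfg)
  grid_best <- oracle_biexp_grid(sigc, IVIM_B, D_star = 50, S0 = 100)
  expect_lte(fitc$rss, grid_best + 1e-12)

  expect_error(fit_biexp(c(1, 0.5, 0.4), c(0, 300, 700)), "distinct")
})

test_that("tri-exponential fixed-mode fit recovers published presets to 1%", {
  cfg <- fit_config("triexp")
  for (nm in c("healthy_cortex", "healthy_medulla", "cc_rcc_necrosis",
               "oncocytoma")) {
    m <- tissue_presets(nm)$mean
    sig <- predict_triexp(preset_triexp(nm, S0 = 100), IVIM_B)
    fit <- fit_triexp(sig, IVIM_B, cfg)
    expect_equal(fit$params$f_fast, m[["f_fast"]] / 100, tolerance = 0.01)
    expect_equal(fit$params$f_interm, m[["f_interm"]] / 100, tolerance = 0.01)
    expect_equal(fit$params$D_tri, m[["D_tri"]], tolerance = 0.01)
  }
  # necrotic-lesion slow coefficient, explicitly
  fitn <- fit_triexp(predict_triexp(preset_triexp("cc_rcc_necrosis"), IVIM_B),
                     IVIM_B, cfg)
  expect_equal(fitn$params$D_tri, 0.71, tolerance = 0.01 * 0.71)

  # zero-fraction data collapses to mono
  sig0 <- predict_mono(mono_params(100, 1.41), IVIM_B)
  fit0 <- fit_triexp(sig0, IVIM_B, cfg)
  expect_lte(fit0$params$f_fast, 0.005)
  expect_lte(fit0$params$f_interm, 0.005)
  expect_equal(fit0$params$D_tri, 1.41, tolerance = 1e-3)
})

test_that("exact recovery holds for random in-bounds parameters (fixed mode)", {
  set.seed(19)
  cfg <- fit_config("triexp")
  cfg_b <- fit_config("biexp")
  for (i in 1:10) {
    ff <- runif(1, 0, 0.2)
    fi <- runif(1, 0.05, 0.35)
    Dt <- runif(1, 0.5, 2.8)
    S0 <- runif(1, 50, 200)
    sig <- predict_triexp(triexp_params(S0, ff, 50, fi, 6, Dt), IVIM_B)
    fit <- fit_triexp(sig, IVIM_B, cfg)
    expect_equal(fit$params$f_fast, ff, tolerance = 0.01)
    expect_equal(fit$params$f_interm, fi, tolerance = 0.01)
    expect_equal(fit$params$D_tri, Dt, tolerance = 0.01)

    fs <- runif(1, 0.02, 0.4)
    Db <- runif(1, 0.5, 3.2)
    sig_b <- predict_biexp(biexp_params(S0, fs, 50, Db), IVIM_B)
    fit_b <- fit_biexp(sig_b, IVIM_B, cfg_b)
    expect_equal(fit_b$params$f_star, fs, tolerance = 0.01)
    expect_equal(fit_b$params$D_bi, Db, tolerance = 0.01)
  }
})

test_that("fit_volume recovers a 3-label phantom and flags bad voxels", {
  ivim <- paper_scheme("ivim")
  spec <- phantom_spec(shape = c(6, 4, 2), tissues = list(
    cortex = list(preset = "healthy_cortex", region = list("box", c(1, 2), c(1, 4), c(1, 2))),
    lesion = list(preset = "cc_rcc", region = list("box", c(3, 4), c(1, 4), c(1, 2))),
    cyst = list(preset = "cyst", region = list("box", c(5, 6), c(1, 4), c(1, 2)))),
    snr = Inf)
  ph <- make_phantom(spec, scheme = ivim)
  mask <- ph$labels$voxels > 0
  maps <- fit_volume(ph$volume, ivim, mask, fit_config("triexp"))
  for (nm in c("f_fast", "f_interm", "D_tri")) {
    err <- abs(maps[[nm]][mask] - ph$truth[[nm]][mask]) /
      pmax(ph$truth[[nm]][mask], 1e-6)
    expect_lt(max(err), 0.01)
  }
  expect_true(all(is.nan(maps$D_tri[!mask])))

  # single-voxel mask -> exactly one finite voxel
  mask1 <- array(FALSE, dim(mask)); mask1[1, 1, 1] <- TRUE
  maps1 <- fit_volume(ph$volume, ivim, mask1, fit_config("triexp"))
  expect_equal(sum(is.finite(maps1$D_tri)), 1L)

  # voxel with non-finite input is skipped and flagged
  vol_bad <- ph$volume
  vol_bad[1, 1, 1, 3] <- NA
  maps_b <- fit_volume(vol_bad, ivim, mask, fit_config("triexp"))
  expect_false(maps_b$converged[1, 1, 1])
  expect_true(is.nan(maps_b$D_tri[1, 1, 1]))

  expect_error(fit_volume(ph$volume, ivim, array(FALSE, dim(mask)),
                          fit_config("triexp")), "empty mask")
})

test_that("Rician noise never pushes estimates outside bounds", {
  set.seed(23)
  cfg <- fit_config("triexp")
  sig <- predict_triexp(preset_triexp("healthy_cortex", S0 = 100), IVIM_B)
  for (i in 1:20) {
    noisy <- as.vector(add_rician_noise(array(sig, c(1, 1, 1, length(sig))),
                                        sigma = 2, seed = i))
    fit <- suppressWarnings(fit_triexp(noisy, IVIM_B, cfg))
    p <- fit$params
    expect_gte(p$f_fast, 0); expect_gte(p$f_interm, 0)
    expect_lte(p$f_fast + p$f_interm, 1)
    expect_gte(p$D_tri, 0); expect_lte(p$D_tri, 4)
  }
})
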