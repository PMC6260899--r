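# Synthetic renal DWI phantoms.
#
# The phantom states a world the analysis assumes: labeled geometry (nested
# boxes/ellipsoids on a 32 x 32 x 8 grid at 3 mm isotropic), per-label
# multi-exponential decay with published tissue parameters, axially symmetric
# tensors built from published MD/FA, and Rician magnitude noise at a fixed
# seed. Default SNR is 50 (the source protocol reports none; this is a
# stand-in, not a published value).

#' Phantom specification
#'
#' @param shape voxel grid dimensions (length 3).
#' @param tissues named list: one entry per label, each a list with elements
#'   `preset` (a [tissue_presets()] name) and `region` (see Details), plus
#'   optional `S0`. Labels are assigned 1, 2, ... in order.
#' @param snr signal-to-noise ratio S0 / sigma; `Inf` for noise-free.
#' @param S0 default b = 0 signal for all tissues.
#' @param seed integer seed for the noise generator.
#' @param pixdim voxel size in mm.
#' @param D_fast,D_interm pseudo-diffusion coefficients used for signal
#'   generation (1e-3 mm^2/s).
#'
#' @details A `region` is a list: `list("box", xlim, ylim, zlim)` with
#'   inclusive voxel index ranges, or `list("ellipsoid", center, radii)` in
#'   voxel units. Regions must not overlap. With `tissues = NULL` a default
#'   three-tissue layout is used: a cortex box, a medulla box nested beside
#'   it and a spherical lesion (cyst preset).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 8), tissues = NULL, snr = 50,
                         S0 = 100, seed = 1L, pixdim = c(3, 3, 3),
                         D_fast = pseudo_diffusion_defaults()[["D_fast"]],
                         D_interm = pseudo_diffusion_defaults()[["D_interm"]]) {
  if (snr <= 0) stop("SNR must be positive")
  if (is.null(tissues)) {
    tissues <- list(
      cortex = list(preset = "healthy_cortex",
                    region = list("box", c(3, 14), c(3, 30), c(2, 7))),
      medulla = list(preset = "healthy_medulla",
                     region = list("box", c(17, 26), c(3, 30), c(2, 7))),
      lesion = list(preset = "cyst",
                    region = list("ellipsoid", c(29, 16, 4.5), c(2.5, 6, 2.5)))
    )
  }
  spec <- structure(list(shape = as.integer(shape), tissues = tissues,
                         snr = snr, S0 = S0, seed = as.integer(seed),
                         pixdim = pixdim, D_fast = D_fast,
                         D_interm = D_interm),
                    class = "phantom_spec")
  build_label_array(spec)   # validates geometry (overlap, bounds) eagerly
  spec
}

region_mask <- function(region, shape) {
  kind <- region[[1]]
  m <- array(FALSE, shape)
  if (kind == "box") {
    xl <- region[[2]]; yl <- region[[3]]; zl <- region[[4]]
    if (xl[1] < 1 || yl[1] < 1 || zl[1] < 1 ||
        xl[2] > shape[1] || yl[2] > shape[2] || zl[2] > shape[3]) {
      stop("box region exceeds grid bounds")
    }
    m[xl[1]:xl[2], yl[1]:yl[2], zl[1]:zl[2]] <- TRUE
  } else if (kind == "ellipsoid") {
    ctr <- region[[2]]; rad <- region[[3]]
    g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
    inside <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
              ((g$z - ctr[3]) / rad[3])^2 <= 1
    m[cbind(g$x, g$y, g$z)[inside, , drop = FALSE]] <- TRUE
  } else {
    stop("unknown region kind: ", kind)
  }
  m
}

build_label_array <- function(spec) {
  lab <- array(0L, spec$shape)
  for (i in seq_along(spec$tissues)) {
    m <- region_mask(spec$tissues[[i]]$region, spec$shape)
    if (any(lab[m] != 0L)) {
      stop("phantom tissue regions overlap (tissue ", names(spec$tissues)[i], ")")
    }
    lab[m] <- i
  }
  lab
}

#' Generate a noise-free phantom dataset pair
#'
#' Builds the label map and, per acquisition scheme, the 4D signal volume:
#' the IVIM scheme uses each label's tri-exponential preset parameters, the
#' DTI scheme an axially symmetric tensor with the preset MD/FA (principal
#' axis along x). Ground-truth parameter maps are returned for recovery
#' scoring. Noise is applied separately via [add_rician_noise()].
#'
#' @param spec a [phantom_spec()].
#' @param scheme an [acq_scheme()], or `NULL` to generate both published
#'   protocols.
#' @return list with `labels` (a [labeled_volume()]), `truth` (named list of
#'   ground-truth 3D maps: f_fast, f_interm, f_slow, D_tri, MD, FA, S0) and
#'   either `volume` + `scheme` (when `scheme` was given) or `ivim`/`dti`
#'   sublists each holding `volume` + `scheme`.
#' @export
make_phantom <- function(spec, scheme = NULL) {
  lab <- build_label_array(spec)
  tissue_names <- names(spec$tissues)
  labels <- labeled_volume(lab, stats::setNames(tissue_names,
                                                seq_along(tissue_names)),
                           pixdim = spec$pixdim)

  truth_names <- c("S0", "f_fast", "f_interm", "f_slow", "D_tri", "MD", "FA")
  truth <- stats::setNames(
    lapply(truth_names, function(nm) array(NaN, spec$shape)), truth_names)
  tri <- vector("list", length(spec$tissues))
  tens <- vector("list", length(spec$tissues))
  for (i in seq_along(spec$tissues)) {
    tis <- spec$tissues[[i]]
    if (is.null(tis$preset)) stop("tissue ", tissue_names[i], " has no preset")
    s0 <- if (is.null(tis$S0)) spec$S0 else tis$S0
    tri[[i]] <- preset_triexp(tis$preset, S0 = s0, D_fast = spec$D_fast,
                              D_interm = spec$D_interm)
    tens[[i]] <- preset_tensor(tis$preset, S0 = s0)
    vox <- lab == i
    truth$S0[vox] <- s0
    truth$f_fast[vox] <- tri[[i]]$f_fast
    truth$f_interm[vox] <- tri[[i]]$f_interm
    truth$f_slow[vox] <- tri[[i]]$f_slow
    truth$D_tri[vox] <- tri[[i]]$D_tri
    truth$MD[vox] <- tensor_md(tens[[i]])
    truth$FA[vox] <- tensor_fa(tens[[i]])
  }

  fill_volume <- function(sch, kind) {
    vol <- array(0, c(spec$shape, length(sch)))
    vmat <- matrix(vol, prod(spec$shape), length(sch))
    for (i in seq_along(spec$tissues)) {
      sig <- if (kind == "ivim") {
        predict_triexp(tri[[i]], sch$bvalues)
      } else {
        predict_tensor(tens[[i]], sch$bvalues, sch$directions)
      }
      vmat[lab == i, ] <- matrix(sig, sum(lab == i), length(sch), byrow = TRUE)
    }
    array(vmat, c(spec$shape, length(sch)))
  }

  if (!is.null(scheme)) {
    kind <- if (length(unique(scheme$bvalues)) > 5L) "ivim" else "dti"
    return(list(volume = fill_volume(scheme, kind), scheme = scheme,
                labels = labels, truth = truth))
  }
  ivim <- paper_scheme("ivim")
  dti <- paper_scheme("dti")
  list(ivim = list(volume = fill_volume(ivim, "ivim"), scheme = ivim),
       dti = list(volume = fill_volume(dti, "dti"), scheme = dti),
       labels = labels, truth = truth)
}

#' Add Rician magnitude noise
#'
#' `out = sqrt((S + n1)^2 + n2^2)` with `n1`, `n2` i.i.d. Gaussian(0, sigma):
#' the noise model of magnitude MRI. `sigma = 0` returns the input unchanged.
#'
#' @param volume numeric array of noise-free signals.
#' @param sigma Gaussian noise standard deviation (>= 0); for a phantom at
#'   SNR r use `sigma = S0 / r`.
#' @param seed integer seed; same seed, same output.
#' @return array of the same shape.
#' @export
add_rician_noise <- function(volume, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(volume)
  n <- length(volume)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n1 <- stats::rnorm(n, 0, sigma)
  n2 <- stats::rnorm(n, 0, sigma)
  out <- sqrt((volume + n1)^2 + n2^2)
  array(out, dim(volume))
}

#' Sample a synthetic lesion cohort
#'
#' Emulates the shape of the clinical cohort (13 solid lesions plus 5 cysts
#' by default): per lesion, a parameter set is drawn from a Gaussian around
#' its preset means with the preset SDs, truncated to the fit bounds, along
#' with matched healthy cortex and medulla draws for the same "patient".
#' Optionally a small single-label ROI dataset is generated per lesion.
#'
#' @param n_solid,n_cyst number of solid lesions and cysts.
#' @param solid_presets preset names the solid lesions cycle through.
#' @param snr SNR for the per-lesion datasets (`Inf` = noise-free).
#' @param seed integer seed.
#' @param roi_voxels if > 0, per-lesion datasets are generated as an ROI of
#'   this many voxels on the IVIM scheme.
#' @return list with `lesions` (data frame: lesion_id, type, and the seven
#'   parameters), `healthy` (data frame: lesion_id, tissue cortex/medulla,
#'   parameters) and, when `roi_voxels > 0`, `datasets` (per-lesion list
#'   with `volume`, `scheme`, `truth` row).
#' @export
sample_cohort <- function(n_solid = 13L, n_cyst = 5L,
                          solid_presets = c("cc_rcc", "p_rcc", "hemangioma",
                                            "oncocytoma"),
                          snr = Inf, seed = 1L, roi_voxels = 0L) {
  if (n_solid + n_cyst < 1L) stop("cohort needs at least one lesion")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  types <- c(rep_len(solid_presets, n_solid), rep("cyst", n_cyst))
  draw <- function(preset) {
    p <- tissue_presets(preset)
    lims <- param_truncation_limits()
    v <- numeric(length(PRESET_COLS))
    names(v) <- PRESET_COLS
    for (nm in PRESET_COLS) {
      v[nm] <- rtruncnorm1(p$mean[[nm]], p$sd[[nm]], lims[[nm]][1], lims[[nm]][2])
    }
    v
  }
  lesions <- data.frame(lesion_id = seq_along(types), type = types,
                        stringsAsFactors = FALSE)
  lp <- t(vapply(types, draw, numeric(length(PRESET_COLS))))
  lesions <- cbind(lesions, as.data.frame(lp))
  healthy <- do.call(rbind, lapply(seq_along(types), function(i) {
    rbind(
      data.frame(lesion_id = i, tissue = "healthy_cortex",
                 t(draw("healthy_cortex")), stringsAsFactors = FALSE),
      data.frame(lesion_id = i, tissue = "healthy_medulla",
                 t(draw("healthy_medulla")), stringsAsFactors = FALSE))
  }))
  rownames(healthy) <- NULL
  out <- list(lesions = lesions, healthy = healthy)

  if (roi_voxels > 0L) {
    defaults <- pseudo_diffusion_defaults()
    out$datasets <- lapply(seq_along(types), function(i) {
      row <- lesions[i, ]
      pars <- triexp_params(100,
                            f_fast = min(row$f_fast, 99) / 100,
                            D_fast = defaults[["D_fast"]],
                            f_interm = max(0, min(row$f_interm,
                                                  99 - min(row$f_fast, 99))) / 100,
                            D_interm = defaults[["D_interm"]],
                            D_tri = min(row$D_tri,
                                        defaults[["D_interm"]] * 0.99))
      sch <- paper_scheme("ivim")
      sig <- predict_triexp(pars, sch$bvalues)
      vol <- array(rep(sig, each = roi_voxels),
                   c(roi_voxels, 1L, 1L, length(sch)))
      if (is.finite(snr)) {
        vol <- add_rician_noise(vol, sigma = 100 / snr,
                                seed = seed + i)
      }
      list(lesion_id = i, type = types[i], volume = vol, scheme = sch,
           truth = row)
    })
  }
  out
}

# Truncation keeps synthetic lesions physically valid (fit bounds; fractions
# are in percent here).
param_truncation_limits <- function() {
  list(MD = c(0, 4), FA = c(0, 1), f_star = c(0, 100), D_bi = c(0, 4),
       f_fast = c(0, 100), f_interm = c(0, 100), D_tri = c(0, 4))
}

# one truncated-normal draw by rejection (bounds are many SDs out in practice)
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in seq_len(1000L)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}
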