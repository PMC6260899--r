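# Published renal tissue parameter presets.
#
# Each preset carries the per-tissue group mean (and, where reported, SD) of
# the seven diffusion parameters: MD and FA from the tensor model, f_star and
# D_bi from the bi-exponential model, f_fast, f_interm and D_tri from the
# tri-exponential model. Diffusivities in 1e-3 mm^2/s; fractions in percent,
# as reported. Single-lesion presets have SD = 0.
#
# The fast and intermediate pseudo-diffusion coefficients were never reported
# numerically; module-wide defaults place D_fast/D_star in the perfusion
# regime and D_interm at free-water scale.

#' Default pseudo-diffusion coefficients
#'
#' D_fast and D_star default to 50e-3 mm^2/s (perfusion regime); D_interm to
#' 6e-3 mm^2/s (order of magnitude of free water). All fitting and phantom
#' routines take these as overridable arguments.
#'
#' @return named numeric vector with `D_fast`, `D_star`, `D_interm`
#'   (1e-3 mm^2/s).
#' @export
pseudo_diffusion_defaults <- function() {
  c(D_fast = 50, D_star = 50, D_interm = 6)
}

PRESET_COLS <- c("MD", "FA", "f_star", "D_bi", "f_fast", "f_interm", "D_tri")

preset_row <- function(n, MD, FA, f_star, D_bi, f_fast, f_interm, D_tri,
                       sd = rep(0, 7)) {
  list(n = n,
       mean = c(MD = MD, FA = FA, f_star = f_star, D_bi = D_bi,
                f_fast = f_fast, f_interm = f_interm, D_tri = D_tri),
       sd = stats::setNames(sd, PRESET_COLS))
}

#' Renal tissue parameter presets
#'
#' Published group means (SDs in parentheses in the source tables) of the
#' diffusion parameters for healthy renal cortex and medulla, grouped
#' lesions, and the individual solid-lesion subtypes. Units: MD, D_bi, D_tri
#' in 1e-3 mm^2/s; FA dimensionless; f_star, f_fast, f_interm in percent.
#'
#' @param name optional preset name; omit to get the whole library.
#' @return For one preset: a list with `n`, `mean` (named vector over MD, FA,
#'   f_star, D_bi, f_fast, f_interm, D_tri) and `sd`. Otherwise the full
#'   named list.
#' @examples
#' tissue_presets("healthy_cortex")$mean[["D_tri"]]  # 1.41
#' @export
tissue_presets <- function(name = NULL) {
  lib <- list(
    healthy_cortex = preset_row(13, 2.16, 0.38, 10.1, 1.93, 4.14, 28.8, 1.41,
                                sd = c(0.12, 0.09, 2.58, 0.10, 1.92, 5.09, 0.09)),
    healthy_medulla = preset_row(13, 2.21, 0.39, 9.69, 2.02, 4.57, 26.4, 1.55,
                                 sd = c(0.14, 0.08, 2.90, 0.11, 1.74, 6.65, 0.12)),
    all_solid = preset_row(13, 1.94, 0.47, 11.6, 1.71, 7.30, 18.7, 1.39,
                           sd = c(0.32, 0.11, 3.88, 0.43, 3.29, 5.02, 0.35)),
    rcc = preset_row(11, 1.90, 0.46, 11.6, 1.65, 7.21, 18.3, 1.34,
                     sd = c(0.32, 0.10, 3.45, 0.40, 2.88, 5.35, 0.33)),
    cyst = preset_row(5, 3.04, 0.37, 1.88, 2.90, 1.18, 8.31, 2.74,
                      sd = c(0.17, 0.11, 1.60, 0.11, 1.70, 2.02, 0.08)),
    benign = preset_row(2, 2.18, 0.48, 11.6, 2.04, 7.76, 20.9, 1.68,
                        sd = c(0.28, 0.19, 7.83, 0.58, 6.75, 2.43, 0.45)),
    cc_rcc = preset_row(9, 1.94, 0.46, 11.6, 1.71, 7.36, 18.8, 1.38,
                        sd = c(0.33, 0.12, 3.62, 0.42, 3.14, 5.78, 0.34)),
    cc_rcc_sarcomatoid = preset_row(1, 1.77, 0.58, 12.5, 1.38, 7.83, 20.1, 1.04),
    cc_rcc_necrosis = preset_row(1, 1.19, 0.64, 10.78, 0.92, 6.13, 15.11, 0.71),
    cc_rcc_papillary_growth = preset_row(1, 1.82, 0.28, 16.5, 1.49, 11.2, 20.6, 1.19),
    cc_rcc_nests_erythrocytes = preset_row(1, 1.94, 0.40, 14.29, 1.71, 9.11, 22.25, 1.71),
    cc_rcc_low_density_cystic = preset_row(1, 2.24, 0.57, 10.35, 1.90, 6.22, 12.46, 1.68),
    cc_rcc_hemorrhage = preset_row(1, 2.01, 0.46, 16.62, 1.71, 12.43, 16.09, 1.49),
    cc_rcc_cystic_solid = preset_row(1, 2.20, 0.45, 8.69, 1.97, 6.25, 15.31, 1.69),
    cc_rcc_microcystic = preset_row(1, 2.17, 0.36, 7.95, 2.39, 2.83, 31.72, 1.68),
    p_rcc = preset_row(2, 1.68, 0.50, 11.3, 1.36, 6.56, 16.3, 1.14,
                       sd = c(0.20, 0.01, 3.8, 0.06, 1.80, 2.88, 0.06)),
    hemangioma = preset_row(1, 2.38, 0.61, 6.06, 2.45, 2.99, 22.6, 1.99),
    oncocytoma = preset_row(1, 1.98, 0.34, 17.1, 1.63, 12.5, 19.2, 1.36)
  )
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) {
    stop("unknown tissue preset \"", name, "\"; available: ",
         paste(names(lib), collapse = ", "))
  }
  lib[[name]]
}

#' Tri-exponential parameters of a preset
#'
#' Converts a preset's percent fractions and slow diffusivity into a
#' [triexp_params()] using the default (or supplied) fast/intermediate
#' pseudo-diffusion coefficients.
#'
#' @param name preset name, see [tissue_presets()].
#' @param S0 b = 0 signal.
#' @param D_fast,D_interm pseudo-diffusion coefficients (1e-3 mm^2/s).
#' @return a [triexp_params()].
#' @export
preset_triexp <- function(name, S0 = 100,
                          D_fast = pseudo_diffusion_defaults()[["D_fast"]],
                          D_interm = pseudo_diffusion_defaults()[["D_interm"]]) {
  m <- tissue_presets(name)$mean
  triexp_params(S0, f_fast = m[["f_fast"]] / 100, D_fast = D_fast,
                f_interm = m[["f_interm"]] / 100, D_interm = D_interm,
                D_tri = m[["D_tri"]])
}

#' Bi-exponential parameters of a preset
#'
#' @inheritParams preset_triexp
#' @param D_star pseudo-diffusion coefficient (1e-3 mm^2/s).
#' @return a [biexp_params()].
#' @export
preset_biexp <- function(name, S0 = 100,
                         D_star = pseudo_diffusion_defaults()[["D_star"]]) {
  m <- tissue_presets(name)$mean
  biexp_params(S0, f_star = m[["f_star"]] / 100, D_star = D_star,
               D_bi = m[["D_bi"]])
}

#' Ground-truth tensor of a preset
#'
#' @inheritParams preset_triexp
#' @param axis principal eigenvector of the axially symmetric tensor.
#' @return a [tensor_fit()].
#' @export
preset_tensor <- function(name, S0 = 100, axis = c(1, 0, 0)) {
  m <- tissue_presets(name)$mean
  tensor_from_md_fa(m[["MD"]], m[["FA"]], axis = axis, S0 = S0)
}
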