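# Forward models of the diffusion-weighted signal.
#
# Unit convention: diffusivities are stored and reported in 1e-3 mm^2/s (the
# conventional unit for tissue water); b-values in s/mm^2. Model evaluation
# multiplies by 1e-3 so that b * D is dimensionless.

D_UNIT <- 1e-3

#' Mono-exponential decay parameters
#'
#' @param S0 non-negative signal at b = 0.
#' @param D_mono diffusivity in 1e-3 mm^2/s, non-negative.
#' @return list of class `mono_params`.
#' @export
mono_params <- function(S0, D_mono) {
  if (S0 < 0) stop("S0 must be non-negative")
  if (D_mono < 0) stop("D_mono must be non-negative")
  structure(list(S0 = S0, D_mono = D_mono), class = "mono_params")
}

#' Bi-exponential (IVIM) decay parameters
#'
#' Two-compartment model separating tissue diffusion (`D_bi`) from capillary
#' pseudo-diffusion (fraction `f_star`, coefficient `D_star`). The ordering
#' `D_star > D_bi` is enforced to prevent compartment label switching.
#'
#' @param S0 signal at b = 0.
#' @param f_star pseudo-diffusion signal fraction, proportion in [0, 1].
#' @param D_star pseudo-diffusion coefficient, 1e-3 mm^2/s.
#' @param D_bi tissue diffusivity, 1e-3 mm^2/s.
#' @return list of class `biexp_params`.
#' @export
biexp_params <- function(S0, f_star, D_star, D_bi) {
  if (S0 < 0) stop("S0 must be non-negative")
  if (f_star < 0 || f_star > 1) stop("f_star must lie in [0, 1]")
  if (D_bi < 0) stop("D_bi must be non-negative")
  if (D_star <= D_bi) stop("compartment ordering requires D_star > D_bi")
  structure(list(S0 = S0, f_star = f_star, D_star = D_star, D_bi = D_bi),
            class = "biexp_params")
}

#' Tri-exponential decay parameters
#'
#' Three-compartment model: fast pseudo-diffusion (perfusion; `f_fast`,
#' `D_fast`), intermediate free-water-scale motion (`f_interm`, `D_interm`)
#' and slow tissue diffusion (`D_tri`). The slow fraction is derived:
#' `f_slow = 1 - f_fast - f_interm`.
#'
#' @param S0 signal at b = 0.
#' @param f_fast,f_interm signal fractions (proportions); non-negative with
#'   `f_fast + f_interm <= 1`.
#' @param D_fast,D_interm,D_tri diffusivities in 1e-3 mm^2/s, ordered
#'   `D_fast > D_interm > D_tri >= 0`.
#' @return list of class `triexp_params` with derived element `f_slow`.
#' @export
triexp_params <- function(S0, f_fast, D_fast, f_interm, D_interm, D_tri) {
  if (S0 < 0) stop("S0 must be non-negative")
  if (f_fast < 0 || f_interm < 0) stop("fractions must be non-negative")
  if (f_fast + f_interm > 1 + 1e-12) {
    stop("fraction sum violation: f_fast + f_interm must be <= 1")
  }
  if (D_tri < 0) stop("D_tri must be non-negative")
  if (!(D_fast > D_interm && D_interm > D_tri)) {
    stop("compartment ordering requires D_fast > D_interm > D_tri")
  }
  structure(list(S0 = S0, f_fast = f_fast, D_fast = D_fast,
                 f_interm = f_interm, D_interm = D_interm, D_tri = D_tri,
                 f_slow = 1 - f_fast - f_interm),
            class = "triexp_params")
}

#' Diffusion tensor fit
#'
#' Stores S0 and the six unique elements of the symmetric diffusion tensor in
#' 1e-3 mm^2/s. Mean diffusivity and fractional anisotropy are derived via
#' [tensor_md()] and [tensor_fa()], never stored.
#'
#' @param S0 signal at b = 0.
#' @param tensor either a length-6 numeric vector (Dxx, Dyy, Dzz, Dxy, Dxz,
#'   Dyz) or a symmetric 3x3 matrix, in 1e-3 mm^2/s.
#' @return list of class `tensor_fit` with `tensor` stored as the length-6
#'   vector.
#' @export
tensor_fit <- function(S0, tensor) {
  if (S0 < 0) stop("S0 must be non-negative")
  if (is.matrix(tensor)) {
    if (!all(dim(tensor) == c(3L, 3L)) || max(abs(tensor - t(tensor))) > 1e-9) {
      stop("tensor matrix must be symmetric 3x3")
    }
    tensor <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
                tensor[1, 2], tensor[1, 3], tensor[2, 3])
  }
  if (length(tensor) != 6L) stop("tensor must have 6 unique elements")
  names(tensor) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  structure(list(S0 = S0, tensor = tensor), class = "tensor_fit")
}

#' @rdname tensor_fit
#' @param fit a `tensor_fit`.
#' @return `tensor_matrix()`: the symmetric 3x3 tensor matrix.
#' @export
tensor_matrix <- function(fit) {
  d <- fit$tensor
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3L, 3L)
}

check_b <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be non-negative")
  b
}

#' Predict the mono-exponential signal
#'
#' S(b) = S0 * exp(-b * D_mono).
#'
#' @param params a [mono_params()].
#' @param b b-value(s) in s/mm^2, non-negative.
#' @return predicted signal, same length as `b`.
#' @examples
#' predict_mono(mono_params(1, 1), 1000)  # exp(-1)
#' @export
predict_mono <- function(params, b) {
  check_b(b)
  params$S0 * exp(-b * params$D_mono * D_UNIT)
}

#' Predict the bi-exponential (IVIM) signal
#'
#' S(b) = S0 * (f_star exp(-b D_star) + (1 - f_star) exp(-b D_bi)).
#'
#' @param params a [biexp_params()].
#' @param b b-value(s) in s/mm^2.
#' @return predicted signal.
#' @export
predict_biexp <- function(params, b) {
  check_b(b)
  params$S0 * (params$f_star * exp(-b * params$D_star * D_UNIT) +
               (1 - params$f_star) * exp(-b * params$D_bi * D_UNIT))
}

#' Predict the tri-exponential signal
#'
#' S(b) = S0 * (f_fast exp(-b D_fast) + f_interm exp(-b D_interm) +
#' f_slow exp(-b D_tri)) with f_slow = 1 - f_fast - f_interm.
#'
#' @param params a [triexp_params()].
#' @param b b-value(s) in s/mm^2.
#' @return predicted signal.
#' @export
predict_triexp <- function(params, b) {
  check_b(b)
  params$S0 * (params$f_fast * exp(-b * params$D_fast * D_UNIT) +
               params$f_interm * exp(-b * params$D_interm * D_UNIT) +
               params$f_slow * exp(-b * params$D_tri * D_UNIT))
}

#' Predict the diffusion tensor signal
#'
#' S(b, g) = S0 * exp(-b g' D g) for a unit gradient direction g.
#'
#' @param fit a [tensor_fit()].
#' @param b b-value(s) in s/mm^2.
#' @param g gradient direction: a unit 3-vector, or a matrix with one row per
#'   entry of `b`. Must be unit-norm wherever b > 0.
#' @return predicted signal.
#' @export
predict_tensor <- function(fit, b, g) {
  check_b(b)
  if (is.null(dim(g))) g <- matrix(g, nrow = length(b), ncol = 3L, byrow = TRUE)
  nrm <- sqrt(rowSums(g^2))
  if (any(b > 0 & abs(nrm - 1) > 1e-6)) {
    stop("gradient directions must be unit vectors where b > 0")
  }
  D <- tensor_matrix(fit)
  quad <- rowSums((g %*% D) * g)          # g' D g, per row
  fit$S0 * exp(-b * quad * D_UNIT)
}

tensor_eigenvalues <- function(fit, clip = TRUE) {
  ev <- eigen(tensor_matrix(fit), symmetric = TRUE, only.values = TRUE)$values
  if (clip) ev <- pmax(ev, 0)
  ev
}

#' Mean diffusivity of a tensor fit
#'
#' MD = trace(D) / 3, invariant under rotation.
#'
#' @param fit a [tensor_fit()].
#' @return MD in 1e-3 mm^2/s.
#' @export
tensor_md <- function(fit) {
  sum(fit$tensor[1:3]) / 3
}

#' Fractional anisotropy of a tensor fit
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - MD)^2) / sum(lambda_i^2)) over the
#' tensor eigenvalues; lies in [0, 1] (negative eigenvalues are clipped to 0
#' first). Errors on the zero tensor, for which FA is undefined.
#'
#' @param fit a [tensor_fit()].
#' @return FA, dimensionless in [0, 1].
#' @export
tensor_fa <- function(fit) {
  ev <- tensor_eigenvalues(fit)
  s2 <- sum(ev^2)
  if (s2 <= 0) stop("FA undefined: all tensor eigenvalues are zero")
  md <- mean(ev)
  fa <- sqrt(1.5 * sum((ev - md)^2) / s2)
  min(max(fa, 0), 1)
}

#' Axially symmetric tensor with given MD and FA
#'
#' Builds a prolate, axially symmetric tensor whose mean diffusivity and
#' fractional anisotropy match the requested values, with the principal
#' eigenvector along `axis`. Used to turn published MD/FA pairs into
#' ground-truth tensors for simulation.
#'
#' @param md mean diffusivity, 1e-3 mm^2/s.
#' @param fa fractional anisotropy in [0, 1).
#' @param axis principal direction (need not be normalized).
#' @param S0 b = 0 signal.
#' @return a [tensor_fit()].
#' @export
tensor_from_md_fa <- function(md, fa, axis = c(1, 0, 0), S0 = 1) {
  if (md < 0) stop("MD must be non-negative")
  if (fa < 0 || fa >= 1) stop("FA must lie in [0, 1)")
  # lambda_1 = md (1 + 2 delta), lambda_2 = lambda_3 = md (1 - delta)
  # gives FA = 3 delta / sqrt(3 + 6 delta^2)  =>  delta below.
  delta <- fa / sqrt(3 - 2 * fa^2)
  ev <- md * c(1 + 2 * delta, 1 - delta, 1 - delta)
  v1 <- axis / sqrt(sum(axis^2))
  # complete an orthonormal basis around v1
  helper <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- helper - sum(helper * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  V <- cbind(v1, v2, v3)
  D <- V %*% diag(ev) %*% t(V)
  D <- (D + t(D)) / 2
  tensor_fit(S0, D)
}
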