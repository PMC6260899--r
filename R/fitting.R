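# Voxel-wise estimators.
#
# - mono-exponential: weighted log-linear least squares (weights S^2, undoing
#   the log-transform noise distortion);
# - diffusion tensor: iterative WLLS with residual z-score outlier rejection;
# - bi-/tri-exponential: bound-constrained nonlinear least squares (L-BFGS-B)
#   with cascaded initialization (high-b mono fit seeds the tissue component,
#   the b = 0 intercept gap seeds the pseudo-diffusion fractions).
#
# The fraction-sum constraint of the tri-exponential model is handled by
# reparameterization: the optimizer works on u = f_interm / (1 - f_fast) in
# [0, 1], so any iterate inside the box satisfies f_fast + f_interm <= 1.

#' Fit configuration
#'
#' @param model `"mono"`, `"tensor"`, `"biexp"` or `"triexp"`.
#' @param bounds named list overriding default parameter bounds, each entry a
#'   `c(lower, upper)` pair. Defaults: `D_mono`/`D_bi`/`D_tri` in \[0, 4\],
#'   `D_interm` in \[3, 15\], `D_fast`/`D_star` in \[15, 500\]
#'   (1e-3 mm^2/s), fractions in \[0, 1\].
#' @param max_iterations iteration cap for the tensor outlier-rejection loop
#'   and the NLLS optimizer.
#' @param tol convergence tolerance on relative parameter change.
#' @param outlier_z residual z-score threshold for tensor outlier rejection.
#' @param averaging how multi-direction signals are reduced per b-value for
#'   the scalar decay models: `"geometric"` (default), `"arithmetic"` or
#'   `"none"`.
#' @param pseudo_diffusion `"fixed"` (D_fast/D_interm/D_star held at the
#'   configured values; default) or `"free"` (fitted within bounds).
#' @param D_fast,D_interm,D_star pseudo-diffusion coefficients used in fixed
#'   mode and as initial values in free mode (1e-3 mm^2/s).
#' @param init `"cascaded"` (default) or `"flat"` (midpoint-of-bounds)
#'   initialization.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(model = c("triexp", "mono", "tensor", "biexp"),
                       bounds = list(),
                       max_iterations = 10L,
                       tol = 1e-8,
                       outlier_z = 3,
                       averaging = c("geometric", "arithmetic", "none"),
                       pseudo_diffusion = c("fixed", "free"),
                       D_fast = pseudo_diffusion_defaults()[["D_fast"]],
                       D_interm = pseudo_diffusion_defaults()[["D_interm"]],
                       D_star = pseudo_diffusion_defaults()[["D_star"]],
                       init = c("cascaded", "flat")) {
  model <- match.arg(model)
  averaging <- match.arg(averaging)
  pseudo_diffusion <- match.arg(pseudo_diffusion)
  init <- match.arg(init)
  if (tol <= 0) stop("tolerance must be positive")
  b <- list(D_mono = c(0, 4), D_bi = c(0, 4), D_tri = c(0, 4),
            D_interm = c(3, 15), D_fast = c(15, 500), D_star = c(15, 500),
            f_star = c(0, 1), f_fast = c(0, 1), f_interm = c(0, 1))
  for (nm in names(bounds)) {
    if (!nm %in% names(b)) stop("unknown bound name: ", nm)
    b[[nm]] <- bounds[[nm]]
  }
  for (nm in names(b)) {
    if (b[[nm]][1] >= b[[nm]][2]) stop("bound lower >= upper for ", nm)
  }
  structure(list(model = model, bounds = b,
                 max_iterations = as.integer(max_iterations), tol = tol,
                 outlier_z = outlier_z, averaging = averaging,
                 pseudo_diffusion = pseudo_diffusion,
                 D_fast = D_fast, D_interm = D_interm, D_star = D_star,
                 init = init),
            class = "fit_config")
}

voxel_fit <- function(params, rss, converged, iterations, excluded = integer()) {
  structure(list(params = params, rss = rss, converged = converged,
                 iterations = iterations, excluded = excluded),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat("Voxel fit (", class(x$params)[1], "), rss = ",
      formatC(x$rss, format = "g"), if (!x$converged) ", NOT converged", "\n",
      sep = "")
  print(unlist(x$params))
  invisible(x)
}

#' Reduce multi-direction signals to one value per b-value
#'
#' Scalar decay models apply to the direction-averaged signal. Geometric
#' averaging (`exp(mean(log S))`) is the default because for a tensor
#' compartment it yields the decay of the mean diffusivity; it falls back to
#' arithmetic averaging (with a warning) when a non-positive signal makes the
#' log undefined.
#'
#' @param signals numeric vector, one entry per volume in `scheme`.
#' @param scheme an [acq_scheme()].
#' @param mode `"geometric"`, `"arithmetic"` or `"none"` (no reduction;
#'   returns the input with its per-volume b-values).
#' @return list with `signal` and `bvalues`, sorted by b.
#' @export
average_directions <- function(signals, scheme, mode = c("geometric", "arithmetic", "none")) {
  mode <- match.arg(mode)
  if (length(signals) != length(scheme)) {
    stop("signals length ", length(signals), " does not match scheme length ",
         length(scheme))
  }
  if (mode == "none") {
    ord <- order(scheme$bvalues)
    return(list(signal = signals[ord], bvalues = scheme$bvalues[ord]))
  }
  ub <- sort(unique(scheme$bvalues))
  out <- vapply(ub, function(b) {
    s <- signals[scheme$bvalues == b]
    if (mode == "geometric") {
      if (any(s <= 0)) {
        warning("non-positive signal at b = ", b,
                "; falling back to arithmetic averaging")
        return(mean(s))
      }
      exp(mean(log(s)))
    } else {
      mean(s)
    }
  }, numeric(1))
  list(signal = out, bvalues = ub)
}

# Weighted log-linear mono-exponential solve; returns c(log S0, D) with D in
# 1e-3 mm^2/s. Weights default to S^2.
mono_wlls <- function(signals, bvalues, weights = signals^2) {
  X <- cbind(1, -bvalues * D_UNIT)
  y <- log(signals)
  fit <- stats::lm.wfit(X, y, w = weights)
  unname(fit$coefficients)
}

#' Mono-exponential fit
#'
#' Weighted log-linear least squares of `log S` on `-b`, with weights `S^2`
#' to undo the distortion of the log transform. Exact on noise-free
#' mono-exponential data.
#'
#' @param signals positive signal values (already direction-averaged).
#' @param bvalues matching b-values (s/mm^2); at least two distinct values.
#' @param config a [fit_config()].
#' @return a `voxel_fit` whose `params` is a [mono_params()].
#' @export
fit_mono <- function(signals, bvalues, config = fit_config("mono")) {
  if (length(signals) != length(bvalues)) stop("signals/bvalues length mismatch")
  if (length(unique(bvalues)) < 2L) {
    stop("rank-deficient mono fit: need at least 2 distinct b-values")
  }
  if (any(signals <= 0)) stop("mono fit requires positive signals")
  beta <- mono_wlls(signals, bvalues)
  lim <- config$bounds$D_mono
  D <- min(max(beta[2], lim[1]), lim[2])
  p <- mono_params(S0 = exp(beta[1]), D_mono = D)
  rss <- sum((signals - predict_mono(p, bvalues))^2)
  voxel_fit(p, rss, TRUE, 1L)
}

#' Diffusion tensor fit by iterative WLLS with outlier rejection
#'
#' Iterates: (1) weighted linear least squares on the log signal with
#' weights equal to the squared predicted signal (first pass: squared
#' observed signal); (2) z-scores of the weighted residuals; (3) exclusion of
#' measurements with |z| above `config$outlier_z`; until the estimate is
#' stable or `max_iterations` is reached. Negative eigenvalues of the
#' resulting tensor are clipped to zero.
#'
#' @param signals positive signal values, one per volume of `scheme`.
#' @param scheme an [acq_scheme()]; needs >= 7 usable measurements spanning
#'   at least 6 non-collinear directions plus b = 0.
#' @param config a [fit_config()].
#' @return a `voxel_fit` whose `params` is a [tensor_fit()]; `excluded`
#'   holds the indices of rejected measurements; `converged = FALSE` flags a
#'   failed fit (e.g. too few measurements left).
#' @export
fit_tensor_wlls <- function(signals, scheme, config = fit_config("tensor")) {
  n <- length(scheme)
  if (length(signals) != n) stop("signals length does not match scheme")
  if (n < 7L) stop("tensor fit needs at least 7 measurements")
  g <- scheme$directions
  bb <- scheme$bvalues * D_UNIT
  X <- cbind(1, -bb * g[, 1]^2, -bb * g[, 2]^2, -bb * g[, 3]^2,
             -2 * bb * g[, 1] * g[, 2], -2 * bb * g[, 1] * g[, 3],
             -2 * bb * g[, 2] * g[, 3])
  usable <- which(is.finite(signals) & signals > 0)
  if (length(usable) < 7L) {
    return(voxel_fit(tensor_fit(0, rep(0, 6)), NA_real_, FALSE, 0L,
                     setdiff(seq_len(n), usable)))
  }
  y <- log(signals)
  keep <- usable
  # robust start: the first pass is unweighted, so a spiked measurement
  # cannot dominate the fit through its squared-signal weight
  w <- rep(1, length(keep))
  beta_old <- rep(Inf, 7L)
  beta <- NULL
  iterations <- 0L
  for (it in seq_len(config$max_iterations)) {
    iterations <- it
    fit <- try(stats::lm.wfit(X[keep, , drop = FALSE], y[keep], w = w),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(voxel_fit(tensor_fit(0, rep(0, 6)), NA_real_, FALSE, it,
                       setdiff(seq_len(n), keep)))
    }
    beta <- unname(fit$coefficients)
    # robust residual z-scores over ALL usable measurements under the current
    # estimate (median/MAD scale, so a high-leverage spike cannot mask itself
    # or drag clean measurements over the threshold); the keep set is rebuilt
    # each iteration, so measurements can be re-included
    pred_log <- drop(X[usable, , drop = FALSE] %*% beta)
    r <- exp(pred_log) * (y[usable] - pred_log)   # weighted by predicted S
    scale_r <- stats::mad(r)
    sig_scale <- stats::median(exp(pred_log))
    if (is.finite(scale_r) && scale_r > 1e-8 * sig_scale) {
      z <- (r - stats::median(r)) / scale_r
      new_keep <- usable[abs(z) <= config$outlier_z]
    } else {
      # numerically perfect fit: judge by absolute residual so that clean
      # measurements rejected in an earlier, still-biased pass are re-included
      new_keep <- usable[abs(r - stats::median(r)) <= 1e-6 * sig_scale]
    }
    if (length(new_keep) < 7L) {
      warning("tensor fit failure: fewer than 7 usable measurements after ",
              "outlier rejection")
      return(voxel_fit(wlls_beta_to_tensor(beta), NA_real_, FALSE, it,
                       setdiff(seq_len(n), keep)))
    }
    changed <- !identical(sort(new_keep), sort(keep))
    keep <- new_keep
    w_new <- exp(drop(X[keep, , drop = FALSE] %*% beta))^2
    delta <- if (any(!is.finite(beta_old))) Inf else
      max(abs(beta - beta_old) / pmax(abs(beta_old), 1))
    beta_old <- beta
    w <- w_new
    if (!changed && delta < config$tol) break
  }
  p <- wlls_beta_to_tensor(beta)
  rss <- sum((signals[keep] -
              predict_tensor(p, scheme$bvalues[keep], g[keep, , drop = FALSE]))^2)
  voxel_fit(p, rss, TRUE, iterations, setdiff(seq_len(n), keep))
}

# beta = (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz); clip negative eigenvalues.
wlls_beta_to_tensor <- function(beta) {
  p <- tensor_fit(exp(beta[1]), beta[2:7])
  D <- tensor_matrix(p)
  e <- eigen(D, symmetric = TRUE)
  if (any(e$values < 0)) {
    D <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    D <- (D + t(D)) / 2
    p <- tensor_fit(p$S0, D)
  }
  p
}

bounded_nlls <- function(objective, theta0, lower, upper, config) {
  theta0 <- pmin(pmax(theta0, lower), upper)
  res <- stats::optim(theta0, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500L, factr = 1e4, pgtol = 1e-14))
  # polish: L-BFGS-B occasionally stalls near bounds; one restart from the
  # solution costs little and tightens noise-free recovery
  res2 <- stats::optim(res$par, objective, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 500L, factr = 1e4, pgtol = 1e-14))
  # L-BFGS-B reports an abnormal line search when it cannot improve the
  # objective at machine precision; a restart that yields no improvement
  # therefore also counts as converged
  improvement <- res$value - res2$value
  converged <- res$convergence == 0L || res2$convergence == 0L ||
    improvement <= 1e-10 * max(1, abs(res$value))
  if (res2$value <= res$value) res <- res2
  list(par = res$par, value = res$value,
       converged = converged,
       iterations = res$counts[["function"]])
}

#' Bi-exponential (IVIM) fit
#'
#' Bound-constrained nonlinear least squares. Cascaded initialization fits a
#' mono-exponential to the high-b tail (b >= 200 s/mm^2) to seed the tissue
#' diffusivity and tissue S0; the gap between the measured b = 0 signal and
#' the tail intercept seeds `f_star`. In `"fixed"` pseudo-diffusion mode
#' `D_star` is held at `config$D_star`.
#'
#' @param signals positive direction-averaged signal values.
#' @param bvalues matching b-values; >= 4 distinct values including b = 0 and
#'   a b >= 500 s/mm^2.
#' @param config a [fit_config()].
#' @return a `voxel_fit` whose `params` is a [biexp_params()].
#' @export
fit_biexp <- function(signals, bvalues, config = fit_config("biexp")) {
  check_decay_input(signals, bvalues, min_b = 4L, need_high = 500)
  s0_obs <- mean(signals[bvalues == 0])
  init <- cascade_init(signals, bvalues, config)
  bnd <- config$bounds
  if (config$pseudo_diffusion == "fixed") {
    D_star <- config$D_star
    lower <- c(0, bnd$f_star[1], bnd$D_bi[1])
    upper <- c(2 * max(signals), bnd$f_star[2], min(bnd$D_bi[2], D_star * 0.999))
    theta0 <- if (config$init == "cascaded") {
      c(s0_obs, init$f_pseudo, init$D_tissue)
    } else {
      (lower + upper) / 2
    }
    obj <- function(th) {
      m <- th[1] * (th[2] * exp(-bvalues * D_star * D_UNIT) +
                    (1 - th[2]) * exp(-bvalues * th[3] * D_UNIT))
      sum((signals - m)^2)
    }
    sol <- bounded_nlls(obj, theta0, lower, upper, config)
    p <- biexp_params(sol$par[1], sol$par[2], D_star, sol$par[3])
  } else {
    lower <- c(0, bnd$f_star[1], bnd$D_star[1], bnd$D_bi[1])
    upper <- c(2 * max(signals), bnd$f_star[2], bnd$D_star[2],
               min(bnd$D_bi[2], bnd$D_star[1] * 0.999))
    theta0 <- if (config$init == "cascaded") {
      c(s0_obs, init$f_pseudo, config$D_star, init$D_tissue)
    } else {
      (lower + upper) / 2
    }
    obj <- function(th) {
      m <- th[1] * (th[2] * exp(-bvalues * th[3] * D_UNIT) +
                    (1 - th[2]) * exp(-bvalues * th[4] * D_UNIT))
      sum((signals - m)^2)
    }
    sol <- bounded_nlls(obj, theta0, lower, upper, config)
    p <- biexp_params(sol$par[1], sol$par[2], sol$par[3], sol$par[4])
  }
  if (!sol$converged) warning("bi-exponential fit did not converge; returning best iterate")
  voxel_fit(p, sol$value, sol$converged, sol$iterations)
}

#' Tri-exponential fit
#'
#' Bound-constrained nonlinear least squares for the three-compartment decay.
#' In `"fixed"` pseudo-diffusion mode (default, recommended for the sparse
#' 10-b-value protocol) `D_fast` and `D_interm` are held at their configured
#' values and only S0, `f_fast`, `f_interm` and `D_tri` are free. The
#' fraction-sum constraint is enforced by optimizing
#' `u = f_interm / (1 - f_fast)` in \[0, 1\]. Initialization cascades from
#' the bi-exponential fit.
#'
#' @param signals positive direction-averaged signal values.
#' @param bvalues matching b-values; >= 6 distinct values including b = 0 and
#'   a b >= 500 s/mm^2 (the full 10-b protocol is recommended).
#' @param config a [fit_config()].
#' @return a `voxel_fit` whose `params` is a [triexp_params()].
#' @export
fit_triexp <- function(signals, bvalues, config = fit_config("triexp")) {
  check_decay_input(signals, bvalues, min_b = 6L, need_high = 500)
  s0_obs <- mean(signals[bvalues == 0])
  bnd <- config$bounds
  bi_cfg <- config
  bi_cfg$model <- "biexp"
  bi_cfg$D_star <- config$D_fast
  bi <- try(fit_biexp(signals, bvalues, bi_cfg), silent = TRUE)
  if (inherits(bi, "try-error")) bi <- NULL

  fixed <- config$pseudo_diffusion == "fixed"
  # theta = (S0, f_fast, u, D_tri [, D_fast, D_interm])
  lower <- c(0, bnd$f_fast[1], 0, bnd$D_tri[1])
  upper <- c(2 * max(signals), bnd$f_fast[2], 1, bnd$D_tri[2])
  if (!fixed) {
    lower <- c(lower, bnd$D_fast[1], bnd$D_interm[1])
    upper <- c(upper, bnd$D_fast[2], bnd$D_interm[2])
  }
  if (config$init == "cascaded" && !is.null(bi)) {
    f0 <- bi$params$f_star
    th0 <- c(s0_obs, f0 * 0.6, min(0.3 / max(1 - f0 * 0.6, 1e-6), 1),
             min(bi$params$D_bi, upper[4]))
  } else {
    th0 <- (lower + upper) / 2
  }
  if (!fixed) th0 <- c(th0[1:4], config$D_fast, config$D_interm)

  obj <- function(th) {
    Df <- if (fixed) config$D_fast else th[5]
    Di <- if (fixed) config$D_interm else th[6]
    ff <- th[2]
    fi <- th[3] * (1 - ff)
    m <- th[1] * (ff * exp(-bvalues * Df * D_UNIT) +
                  fi * exp(-bvalues * Di * D_UNIT) +
                  (1 - ff - fi) * exp(-bvalues * th[4] * D_UNIT))
    # soft penalty keeps the slow coefficient below the intermediate one
    pen <- if (th[4] >= Di) 1e6 * (th[4] - Di + 1)^2 else 0
    sum((signals - m)^2) + pen
  }
  sol <- bounded_nlls(obj, th0, lower, upper, config)
  Df <- if (fixed) config$D_fast else sol$par[5]
  Di <- if (fixed) config$D_interm else sol$par[6]
  Di <- min(Di, Df * 0.999)
  D_tri <- min(sol$par[4], Di * 0.999999)
  p <- triexp_params(sol$par[1], f_fast = sol$par[2], D_fast = Df,
                     f_interm = sol$par[3] * (1 - sol$par[2]),
                     D_interm = Di, D_tri = D_tri)
  if (!sol$converged) warning("tri-exponential fit did not converge; returning best iterate")
  voxel_fit(p, sol$value, sol$converged, sol$iterations)
}

check_decay_input <- function(signals, bvalues, min_b, need_high) {
  if (length(signals) != length(bvalues)) stop("signals/bvalues length mismatch")
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    stop("decay fit requires finite positive signals")
  }
  ub <- unique(bvalues)
  if (length(ub) < min_b) {
    stop("need at least ", min_b, " distinct b-values, got ", length(ub))
  }
  if (!any(bvalues == 0)) stop("decay fit requires a b = 0 measurement")
  if (max(bvalues) < need_high) {
    stop("decay fit requires a b-value of at least ", need_high, " s/mm^2")
  }
  invisible(TRUE)
}

# High-b mono seed shared by the exponential fitters.
cascade_init <- function(signals, bvalues, config) {
  hi <- bvalues >= 200
  if (sum(hi) < 2L || length(unique(bvalues[hi])) < 2L) {
    hi <- bvalues >= stats::median(bvalues)
  }
  beta <- mono_wlls(signals[hi], bvalues[hi])
  D_t <- min(max(beta[2], 1e-3), config$bounds$D_bi[2])
  s0_tissue <- exp(beta[1])
  s0_obs <- mean(signals[bvalues == 0])
  f <- min(max(1 - s0_tissue / s0_obs, 0), 0.5)
  list(D_tissue = D_t, f_pseudo = f)
}

#' Fit every voxel of a masked 4D volume
#'
#' Applies the configured voxel-wise fit to each in-mask voxel and assembles
#' 3D parameter maps. Scalar decay models (`mono`, `biexp`, `triexp`) reduce
#' directions per [average_directions()] first; the tensor model uses all
#' volumes. Voxels outside the mask (or with non-finite input) are NaN in
#' every map and flagged.
#'
#' @param volume 4D array `(x, y, z, volume)`.
#' @param scheme matching [acq_scheme()].
#' @param mask 3D logical/0-1 array; must contain at least one voxel.
#' @param config a [fit_config()]; `config$model` picks the estimator.
#' @return list of class `param_maps`: named list of 3D maps (model
#'   parameters plus `rss` and `converged`), with attribute `model`.
#' @export
fit_volume <- function(volume, scheme, mask, config = fit_config("triexp")) {
  dims <- dim(volume)
  if (length(dims) != 4L) stop("volume must be 4D")
  if (dims[4] != length(scheme)) stop("volume/scheme length mismatch")
  if (!all(dim(mask) == dims[1:3])) stop("mask must match volume grid")
  mask <- array(as.logical(mask), dims[1:3])
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")

  par_names <- switch(config$model,
    mono = c("S0", "D_mono"),
    biexp = c("S0", "f_star", "D_star", "D_bi"),
    triexp = c("S0", "f_fast", "f_interm", "f_slow", "D_fast", "D_interm", "D_tri"),
    tensor = c("S0", "MD", "FA", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"))
  maps <- stats::setNames(
    lapply(c(par_names, "rss"), function(nm) array(NaN, dims[1:3])),
    c(par_names, "rss"))
  maps$converged <- array(NA, dims[1:3])

  vmat <- matrix(volume, prod(dims[1:3]), dims[4])
  n_fallback <- 0L
  for (v in idx) {
    sig <- vmat[v, ]
    if (any(!is.finite(sig))) {
      maps$converged[v] <- FALSE
      next
    }
    res <- if (config$model == "tensor") {
      try(fit_tensor_wlls(sig, scheme, config), silent = TRUE)
    } else {
      avg <- withCallingHandlers(
        average_directions(sig, scheme, config$averaging),
        warning = function(w) {
          n_fallback <<- n_fallback + 1L
          invokeRestart("muffleWarning")
        })
      switch(config$model,
        mono = try(fit_mono(avg$signal, avg$bvalues, config), silent = TRUE),
        biexp = try(suppressWarnings(fit_biexp(avg$signal, avg$bvalues, config)),
                    silent = TRUE),
        triexp = try(suppressWarnings(fit_triexp(avg$signal, avg$bvalues, config)),
                     silent = TRUE))
    }
    if (inherits(res, "try-error")) {
      maps$converged[v] <- FALSE
      next
    }
    p <- res$params
    vals <- switch(config$model,
      mono = c(p$S0, p$D_mono),
      biexp = c(p$S0, p$f_star, p$D_star, p$D_bi),
      triexp = c(p$S0, p$f_fast, p$f_interm, p$f_slow, p$D_fast, p$D_interm,
                 p$D_tri),
      tensor = c(p$S0, tensor_md(p), tensor_fa(p), p$tensor))
    for (k in seq_along(par_names)) maps[[par_names[k]]][v] <- vals[k]
    maps$rss[v] <- res$rss
    maps$converged[v] <- res$converged
  }
  if (n_fallback > 0L) {
    warning(n_fallback,
            " voxel(s) fell back to arithmetic direction averaging ",
            "(non-positive signal)")
  }
  structure(maps, model = config$model, class = c("param_maps", "list"))
}
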