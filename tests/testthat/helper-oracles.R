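# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own computation paths.

# term-by-term tri-exponential evaluation (independent of predict_triexp)
oracle_triexp <- function(S0, f_fast, D_fast, f_interm, D_interm, D_tri, b) {
  terms <- cbind(f_fast * exp(-b * D_fast * 1e-3),
                 f_interm * exp(-b * D_interm * 1e-3),
                 (1 - f_fast - f_interm) * exp(-b * D_tri * 1e-3))
  S0 * rowSums(terms)
}

# exhaustive grid-search oracle for the fixed-D_star bi-exponential fit
oracle_biexp_grid <- function(signals, bvalues, D_star, S0,
                              f_grid = seq(0, 0.5, by = 0.005),
                              D_grid = seq(0.5, 3.5, by = 0.005)) {
  best <- Inf
  for (f in f_grid) {
    mf <- f * exp(-bvalues * D_star * 1e-3)
    for (D in D_grid) {
      m <- S0 * (mf + (1 - f) * exp(-bvalues * D * 1e-3))
      rss <- sum((signals - m)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# exact two-sided signed-rank p by direct enumeration over sign vectors
# (grid expansion, structurally different from the package's subset-sum scan)
oracle_wilcoxon_exact <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  w_obs <- sum(r[d > 0])
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random symmetric positive semi-definite tensor (1e-3 mm^2/s scale)
random_psd_tensor <- function() {
  A <- matrix(rnorm(9), 3, 3)
  D <- crossprod(A)
  D / max(diag(D)) * runif(1, 0.5, 3)
}

# two-tissue noise-free phantom on the IVIM scheme, small enough for tests
tiny_phantom <- function(shape = c(6, 6, 2)) {
  spec <- phantom_spec(
    shape = shape,
    tissues = list(
      cortex = list(preset = "healthy_cortex",
                    region = list("box", c(1, shape[1] %/% 2), c(1, shape[2]),
                                  c(1, shape[3]))),
      cyst = list(preset = "cyst",
                  region = list("box", c(shape[1] %/% 2 + 1, shape[1]),
                                c(1, shape[2]), c(1, shape[3])))),
    snr = Inf)
  make_phantom(spec, scheme = paper_scheme("ivim"))
}

PARAM7 <- c("MD", "FA", "f_star", "D_bi", "f_fast", "f_interm", "D_tri")
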