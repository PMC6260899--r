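#' Diffusion acquisition scheme
#'
#' An acquisition scheme pairs one b-value (s/mm^2) with one gradient
#' direction per acquired volume. Directions must be unit vectors wherever
#' b > 0; b = 0 entries conventionally carry zero-vectors.
#'
#' @param bvalues numeric vector of b-values in s/mm^2, one per volume.
#' @param directions numeric matrix with 3 columns (x, y, z), one row per
#'   volume. Rows at b > 0 must have Euclidean norm 1 (tolerance 1e-6).
#' @return An object of class `acq_scheme`: a list with elements `bvalues`,
#'   `directions` and `n_b0`.
#' @examples
#' sch <- acq_scheme(c(0, 500), rbind(c(0, 0, 0), c(1, 0, 0)))
#' sch$n_b0
#' @export
acq_scheme <- function(bvalues, directions) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) {
    stop("directions must have 3 columns, got ", ncol(directions))
  }
  if (length(bvalues) != nrow(directions)) {
    stop("scheme length mismatch: ", length(bvalues), " b-values vs ",
         nrow(directions), " directions")
  }
  if (any(!is.finite(bvalues)) || any(bvalues < 0)) {
    stop("b-values must be finite and non-negative")
  }
  if (!any(bvalues == 0)) {
    stop("scheme must contain at least one b = 0 volume")
  }
  nrm <- sqrt(rowSums(directions^2))
  bad <- bvalues > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    stop("non-unit gradient direction at b > 0 (volume ",
         paste(which(bad), collapse = ", "), ")")
  }
  structure(
    list(bvalues = bvalues, directions = directions,
         n_b0 = sum(bvalues == 0)),
    class = "acq_scheme"
  )
}

#' @export
print.acq_scheme <- function(x, ...) {
  ub <- sort(unique(x$bvalues))
  cat("Acquisition scheme: ", length(x$bvalues), " volumes\n", sep = "")
  cat("  b-values (s/mm^2): ", paste(ub, collapse = ", "), "\n", sep = "")
  cat("  b = 0 volumes: ", x$n_b0, "\n", sep = "")
  invisible(x)
}

#' @export
length.acq_scheme <- function(x) length(x$bvalues)

is_scheme <- function(x) inherits(x, "acq_scheme")

#' Published renal DWI acquisition schemes
#'
#' Construct the two protocols used throughout this package:
#' `"ivim"` is the multi-b-value DWI protocol (b = 0, 10, 25, 40, 75, 100,
#' 200, 300, 500, 700 s/mm^2, six gradient directions per non-zero shell,
#' plus a single averaged b = 0 volume); `"dti"` is the tensor protocol
#' (b = 100 and 300 s/mm^2 in 15 directions each, plus one b = 0 volume,
#' 31 volumes in total).
#'
#' Directions are generated deterministically by electrostatic repulsion on
#' the unit sphere so that no two directions are collinear.
#'
#' @param kind `"ivim"` or `"dti"`.
#' @return An [acq_scheme()].
#' @examples
#' sch <- paper_scheme("ivim")
#' max(sch$bvalues)
#' @export
paper_scheme <- function(kind = c("ivim", "dti")) {
  kind <- match.arg(kind)
  if (kind == "ivim") {
    shells <- c(10, 25, 40, 75, 100, 200, 300, 500, 700)
    dirs <- spread_directions(6L)
    bvalues <- c(0, rep(shells, each = 6L))
    directions <- rbind(c(0, 0, 0), dirs[rep(seq_len(6L), times = length(shells)), ])
  } else {
    dirs <- spread_directions(15L)
    bvalues <- c(0, rep(c(100, 300), each = 15L))
    directions <- rbind(c(0, 0, 0), dirs[rep(seq_len(15L), times = 2L), ])
  }
  acq_scheme(bvalues, directions)
}

# Deterministic electrostatically spread unit directions: start from a
# Fibonacci hemisphere and relax antipodally-symmetric point pairs.
spread_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n                       # hemisphere: z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  # a few rounds of pairwise repulsion treating +/-v as the same direction
  for (iter in seq_len(200L)) {
    f <- matrix(0, n, 3L)
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        d <- p[a, ] - p[b, ]
        d2 <- p[a, ] + p[b, ]       # antipode of b
        ns <- sum(d^2)
        if (ns > 1e-12) {
          push <- d / ns
          f[a, ] <- f[a, ] + push
          f[b, ] <- f[b, ] - push
        }
        # antipodal image of b: force on b is the mirror of the force on -b
        ns2 <- sum(d2^2)
        if (ns2 > 1e-12) {
          push <- d2 / ns2
          f[a, ] <- f[a, ] + push
          f[b, ] <- f[b, ] + push
        }
      }
    }
    p <- p + 0.02 * f
    p <- p / sqrt(rowSums(p^2))
  }
  p
}
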