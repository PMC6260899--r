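# ROI-level analysis: per-region parameter statistics, merged fraction maps,
# and the lesion-level table behind scatter/box plots.

#' Per-region summary of parameter maps
#'
#' For every nonzero label and every map, the mean, sample SD (n - 1
#' denominator) and voxel count over the finite in-label voxels. NaN voxels
#' (outside a fit mask, failed fits) are excluded from the count.
#'
#' @param maps named list of 3D parameter maps (e.g. from [fit_volume()];
#'   non-numeric entries such as `converged` are ignored).
#' @param labels a [labeled_volume()] on the same grid.
#' @param parameters optional character vector restricting which maps are
#'   summarized.
#' @return data frame of class `roi_summary` with columns `region`, `label`,
#'   `parameter`, `mean`, `sd`, `n`.
#' @export
roi_summary <- function(maps, labels, parameters = NULL) {
  stopifnot(inherits(labels, "labeled_volume"))
  maps <- Filter(function(m) is.numeric(m) && !is.null(dim(m)), maps)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, names(maps))
    if (length(missing)) stop("no such map(s): ", paste(missing, collapse = ", "))
    maps <- maps[parameters]
  }
  grid <- dim(labels$voxels)
  for (nm in names(maps)) {
    if (!all(dim(maps[[nm]]) == grid)) {
      stop("map \"", nm, "\" grid ", paste(dim(maps[[nm]]), collapse = "x"),
           " does not match label grid ", paste(grid, collapse = "x"))
    }
  }
  ids <- sort(unique(as.vector(labels$voxels)))
  ids <- ids[ids != 0]
  rows <- list()
  for (id in ids) {
    vox <- labels$voxels == id
    region <- labels$labels[[as.character(id)]]
    for (nm in names(maps)) {
      v <- maps[[nm]][vox]
      v <- v[is.finite(v)]
      if (!length(v)) {
        stop("label ", id, " (", region, ") has no finite voxels in map \"",
             nm, "\"")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, label = id, parameter = nm,
        mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_summary", "data.frame")
  out
}

#' Merged signal-fraction RGB map
#'
#' Colour-codes the tri-exponential fractions per voxel: red = f_fast,
#' blue = f_interm, green = f_slow = 1 - f_fast - f_interm. Where the input
#' fractions are valid the three channels sum to 1. Fractions outside [0, 1]
#' are clipped and counted in a warning.
#'
#' @param f_fast,f_interm 3D fraction maps (proportions in [0, 1]).
#' @return 4D array `(x, y, z, channel)` with channels (R, G, B); attribute
#'   `n_clipped` records how many voxels needed clipping.
#' @export
merged_fraction_map <- function(f_fast, f_interm) {
  if (!all(dim(f_fast) == dim(f_interm))) stop("fraction maps must share a grid")
  finite <- is.finite(f_fast) & is.finite(f_interm)
  bad <- finite & (f_fast < 0 | f_fast > 1 | f_interm < 0 | f_interm > 1 |
                   f_fast + f_interm > 1)
  n_clipped <- sum(bad)
  ff <- pmin(pmax(f_fast, 0), 1)
  fi <- pmin(pmax(f_interm, 0), 1)
  over <- finite & (ff + fi > 1)
  tot <- ff + fi
  ff[over] <- ff[over] / tot[over]
  fi[over] <- fi[over] / tot[over]
  fs <- pmax(1 - ff - fi, 0)
  rgb <- array(NaN, c(dim(f_fast), 3L))
  rgb[, , , 1] <- ff
  rgb[, , , 2] <- fs
  rgb[, , , 3] <- fi
  if (n_clipped > 0L) {
    warning(n_clipped, " voxel(s) had fractions outside [0, 1] and were clipped")
  }
  attr(rgb, "n_clipped") <- n_clipped
  rgb
}

#' Lesion-level parameter table
#'
#' Flattens per-lesion ROI summaries into one row per lesion carrying the
#' mean of each diffusion parameter — the data behind per-lesion scatter and
#' box plots.
#'
#' @param summaries named list of `roi_summary` objects (one per lesion; the
#'   element name is the lesion id) or a cohort `lesions` data frame from
#'   [sample_cohort()] (returned with an `id` column prepended).
#' @param types optional named character vector mapping lesion id to type.
#' @return data frame with columns `lesion_id`, `type` and one column per
#'   parameter mean.
#' @export
lesion_scatter_table <- function(summaries, types = NULL) {
  if (is.data.frame(summaries)) {
    out <- summaries
    if (!"lesion_id" %in% names(out)) out$lesion_id <- seq_len(nrow(out))
    return(out)
  }
  if (!length(summaries)) stop("need at least one lesion summary")
  ids <- names(summaries)
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    wide <- stats::setNames(as.list(s$mean), s$parameter)
    cbind(data.frame(lesion_id = ids[i],
                     type = if (is.null(types)) NA_character_ else types[[ids[i]]],
                     stringsAsFactors = FALSE),
          as.data.frame(wide))
  })
  do.call(rbind, rows)
}
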