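#' Composition fractions of a region of interest
#'
#' Computes the area fractions of extracellular space (`V_e`), fibroblasts
#' (`V_f`) and myofibroblasts (`V_mf`) by pixel counting, and the non-myocyte
#' fraction as their sum:
#' `V_nm = V_e + V_f + V_mf`.
#'
#' @param image a [tissue_image()].
#' @param roi optional region of interest as `list(rows = c(r0, r1),
#'   cols = c(c0, c1))` in pixel indices; `NULL` uses the whole image.
#' @return List of class `composition_fractions` with `V_e`, `V_f`, `V_mf`,
#'   `V_nm` (fractions), `roi_area_um2` and `n_pixels`.
#' @export
compute_fractions <- function(image, roi = NULL) {
  stopifnot(inherits(image, "tissue_image"))
  idx <- roi_indices(image, roi)
  es <- image$es[idx$rows, idx$cols]
  fb <- image$fib[idx$rows, idx$cols]
  mf <- image$myofib[idx$rows, idx$cols]
  if (length(es) == 0) stop("empty region of interest")
  if (any(fb & mf)) stop("fibroblast and myofibroblast masks overlap in roi")
  n <- length(es)
  out <- list(
    V_e = sum(es) / n,
    V_f = sum(fb) / n,
    V_mf = sum(mf) / n,
    roi_area_um2 = n * (image$pixel_size_nm / 1000)^2,
    n_pixels = n
  )
  out$V_nm <- out$V_e + out$V_f + out$V_mf
  class(out) <- "composition_fractions"
  out
}

roi_indices <- function(image, roi) {
  d <- dim(image$es)
  if (is.null(roi)) {
    return(list(rows = seq_len(d[1]), cols = seq_len(d[2])))
  }
  r <- as.integer(roi$rows); cc <- as.integer(roi$cols)
  if (length(r) != 2 || length(cc) != 2 || r[1] > r[2] || cc[1] > cc[2] ||
      r[1] < 1 || cc[1] < 1 || r[2] > d[1] || cc[2] > d[2]) {
    stop("roi out of image bounds")
  }
  list(rows = r[1]:r[2], cols = cc[1]:cc[2])
}

#' Fibrosis measure relative to the donor mean
#'
#' Fibrosis in a sample is defined as the increase of its non-myocyte
#' fraction over the average donor non-myocyte fraction:
#' `fibrosis = V_nm_sample - mean(V_nm_donors)`. Negative values (samples
#' below the donor mean) are reported as-is.
#'
#' @param Vnm_sample,donor_mean_Vnm fractions in `[0, 1]`.
#' @return The fibrosis fraction (may be negative).
#' @export
compute_fibrosis <- function(Vnm_sample, donor_mean_Vnm) {
  stopifnot(
    all(Vnm_sample >= 0 & Vnm_sample <= 1),
    donor_mean_Vnm >= 0, donor_mean_Vnm <= 1
  )
  Vnm_sample - donor_mean_Vnm
}

#' Tile-based intra-subject heterogeneity profile
#'
#' Divides the region of interest into non-overlapping square tiles (50 um by
#' default), anchored at the roi origin with incomplete edge tiles discarded,
#' and computes the non-myocyte fraction of each tile. The heterogeneity
#' measure `sigma_intra` is the sample SD (n-1 denominator) of the tile
#' fractions, in percentage points.
#'
#' @inheritParams compute_fractions
#' @param tile_edge_um tile edge length in micrometres.
#' @param n_bins number of histogram bins over `[0, 1]` (probability per bin).
#' @return List of class `heterogeneity_profile` with `tile_Vnm` (matrix,
#'   tile row x tile column), `mean_Vnm`, `sigma_intra` (percent),
#'   `tile_edge_um`, `n_tiles` and `histogram`.
#' @export
heterogeneity_profile <- function(image, roi = NULL, tile_edge_um = 50,
                                  n_bins = 20) {
  stopifnot(inherits(image, "tissue_image"))
  idx <- roi_indices(image, roi)
  nm <- image$es[idx$rows, idx$cols] | image$fib[idx$rows, idx$cols] |
    image$myofib[idx$rows, idx$cols]
  by <- tile_boundaries(nrow(nm), image$pixel_size_nm, tile_edge_um)
  bx <- tile_boundaries(ncol(nm), image$pixel_size_nm, tile_edge_um)
  nty <- length(by) - 1L; ntx <- length(bx) - 1L
  tiles <- matrix(NA_real_, nty, ntx)
  for (i in seq_len(nty)) {
    for (j in seq_len(ntx)) {
      blk <- nm[(by[i] + 1L):by[i + 1L], (bx[j] + 1L):bx[j + 1L]]
      tiles[i, j] <- mean(blk)
    }
  }
  v <- as.numeric(tiles)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(n_bins, pmax(1L, findInterval(v, breaks,
    rightmost.closed = TRUE))), nbins = n_bins)
  structure(
    list(
      tile_Vnm = tiles,
      tile_edge_um = tile_edge_um,
      n_tiles = length(v),
      mean_Vnm = mean(v),
      sigma_intra = 100 * sd(v),
      histogram = list(breaks = breaks, probability = counts / length(v))
    ),
    class = "heterogeneity_profile"
  )
}

#' @export
print.heterogeneity_profile <- function(x, ...) {
  cat(sprintf(
    "heterogeneity_profile: %d tiles of %g um, mean V_nm = %.2f%%, sigma_intra = %.2f%%\n",
    x$n_tiles, x$tile_edge_um, 100 * x$mean_Vnm, x$sigma_intra
  ))
  invisible(x)
}

#' Geometry of fibrotic patches
#'
#' Extracts 8-connected components of the binary non-myocyte mask, discards
#' components smaller than `min_area_um2` (150 um^2 by default), and for the
#' survivors computes the area and the major/minor axes of the ellipse with
#' the same second central moments as the component. Two shape measures are
#' reported: `axis_ratio` (major/minor, the definition used for patch
#' "eccentricity" throughout this package's tables) and the standard ellipse
#' `eccentricity` `sqrt(1 - (minor/major)^2)`.
#'
#' @param x a [tissue_image()] (its combined non-myocyte mask is analyzed) or
#'   a binary matrix.
#' @param pixel_size_nm pixel size; taken from `x` when it is a tissue image.
#' @param min_area_um2 minimum patch area retained.
#' @return List of class `patch_features`: `n_patches`, `largest_area_um2`,
#'   `mean_area_um2`, `mean_major_axis_um`, `mean_minor_axis_um`,
#'   `mean_axis_ratio`, `mean_eccentricity`, and a per-patch data frame
#'   `patches`. With no surviving component, `n_patches` is 0 and the summary
#'   fields are `NA`.
#' @export
patch_geometry <- function(x, pixel_size_nm = NULL, min_area_um2 = 150) {
  if (inherits(x, "tissue_image")) {
    mask <- x$es | x$fib | x$myofib
    pixel_size_nm <- x$pixel_size_nm
  } else {
    mask <- x != 0
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required for a bare mask")
  }
  px_um <- pixel_size_nm / 1000
  empty <- list(
    n_patches = 0L, largest_area_um2 = NA_real_, mean_area_um2 = NA_real_,
    mean_major_axis_um = NA_real_, mean_minor_axis_um = NA_real_,
    mean_axis_ratio = NA_real_, mean_eccentricity = NA_real_,
    patches = data.frame(
      area_um2 = numeric(0), major_axis_um = numeric(0),
      minor_axis_um = numeric(0), axis_ratio = numeric(0),
      eccentricity = numeric(0)
    )
  )
  class(empty) <- "patch_features"
  if (!any(mask)) return(empty)

  lab <- label_components8(mask)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  n_px <- tabulate(labs)
  keep <- which(n_px * px_um^2 >= min_area_um2)
  if (length(keep) == 0) return(empty)

  feats <- lapply(keep, function(l) {
    sel <- labs == l
    xx <- cols[sel]; yy <- rows[sel]
    n <- length(xx)
    # central second moments with the 1/12 per-pixel (unit square) correction
    mu20 <- sum((xx - mean(xx))^2) / n + 1 / 12
    mu02 <- sum((yy - mean(yy))^2) / n + 1 / 12
    mu11 <- sum((xx - mean(xx)) * (yy - mean(yy))) / n
    tr <- mu20 + mu02
    det_half <- sqrt(max(0, (mu20 - mu02)^2 / 4 + mu11^2))
    l1 <- tr / 2 + det_half
    l2 <- max(tr / 2 - det_half, 1e-12)
    major <- 4 * sqrt(l1) * px_um
    minor <- 4 * sqrt(l2) * px_um
    c(
      area_um2 = n * px_um^2,
      major_axis_um = major,
      minor_axis_um = minor,
      axis_ratio = major / minor,
      eccentricity = sqrt(max(0, 1 - (minor / major)^2))
    )
  })
  patches <- as.data.frame(do.call(rbind, feats))
  out <- list(
    n_patches = nrow(patches),
    largest_area_um2 = max(patches$area_um2),
    mean_area_um2 = mean(patches$area_um2),
    mean_major_axis_um = mean(patches$major_axis_um),
    mean_minor_axis_um = mean(patches$minor_axis_um),
    mean_axis_ratio = mean(patches$axis_ratio),
    mean_eccentricity = mean(patches$eccentricity),
    patches = patches
  )
  class(out) <- "patch_features"
  out
}

#' Per-subject quantification table for a cohort
#'
#' Runs [compute_fractions()], [heterogeneity_profile()] and
#' [patch_geometry()] on every image and assembles one row per subject.
#'
#' @param images list of [tissue_image()]s, e.g. from [generate_cohort()].
#' @param groups optional group labels; defaults to `attr(images, "groups")`
#'   or the images' own group fields.
#' @return A data frame with columns `subject`, `group`, `V_e`, `V_f`,
#'   `V_mf`, `V_nm`, `sigma_intra`, `n_patches`, `largest_patch_area_um2`,
#'   `mean_patch_area_um2`, `mean_major_axis_um`, `mean_minor_axis_um`,
#'   `mean_axis_ratio`.
#' @export
quantify_cohort <- function(images, groups = NULL) {
  if (is.null(groups)) groups <- attr(images, "groups")
  if (is.null(groups)) groups <- vapply(images, function(i) i$group, character(1))
  rows <- lapply(seq_along(images), function(i) {
    fr <- compute_fractions(images[[i]])
    hp <- heterogeneity_profile(images[[i]])
    pg <- patch_geometry(images[[i]])
    data.frame(
      subject = i, group = groups[i],
      V_e = fr$V_e, V_f = fr$V_f, V_mf = fr$V_mf, V_nm = fr$V_nm,
      sigma_intra = hp$sigma_intra,
      n_patches = pg$n_patches,
      largest_patch_area_um2 = pg$largest_area_um2,
      mean_patch_area_um2 = pg$mean_area_um2,
      mean_major_axis_um = pg$mean_major_axis_um,
      mean_minor_axis_um = pg$mean_minor_axis_um,
      mean_axis_ratio = pg$mean_axis_ratio
    )
  })
  do.call(rbind, rows)
}
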