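#' Specification for one synthetic tissue image
#'
#' Describes the target composition, heterogeneity and fibrosis pattern mix of
#' a synthetic segmented tissue image. The generator emulates the three study
#' conditions: donor tissue (low non-myocyte fraction, low tile-to-tile
#' variability, interstitial clefts), nonischemic cardiomyopathy (NIC;
#' interstitial/diffuse strands, moderate variability) and ischemic
#' cardiomyopathy (IC; large patchy/compact regions, high variability).
#'
#' @param group `"donor"`, `"NIC"` or `"IC"`; selects default targets and
#'   pattern weights when they are not given explicitly.
#' @param target_Vnm target non-myocyte area fraction in `[0, 1]`.
#' @param target_sigma_intra target intra-image heterogeneity: the SD of the
#'   non-myocyte fraction across 50-um tiles, in percentage points. `NULL`
#'   lets the pattern weights determine the heterogeneity.
#' @param pattern_weights named nonnegative weights over
#'   `c("interstitial", "diffuse", "stringy", "patchy", "compact")`;
#'   normalized to sum to 1.
#' @param target_Vf_plus_Vmf combined fibroblast + myofibroblast area fraction.
#' @param image_edge_um image edge length in micrometres (square image).
#' @param pixel_size_nm pixel edge in nanometres (378 mirrors the confocal
#'   acquisition; coarser pixels give faster, smaller images).
#' @param tile_edge_um tile edge used to define heterogeneity (50 um).
#' @param rng_seed integer seed; the whole image is a deterministic function
#'   of the spec including this seed.
#'
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(group = c("donor", "NIC", "IC"),
                        target_Vnm = NULL,
                        target_sigma_intra = NULL,
                        pattern_weights = NULL,
                        target_Vf_plus_Vmf = NULL,
                        image_edge_um = 1000,
                        pixel_size_nm = 378,
                        tile_edge_um = 50,
                        rng_seed = 1L) {
  group <- match.arg(group)
  defaults <- group_profile(group)
  if (is.null(target_Vnm)) target_Vnm <- defaults$Vnm_mean / 100
  if (is.null(pattern_weights)) pattern_weights <- defaults$weights
  if (is.null(target_Vf_plus_Vmf)) target_Vf_plus_Vmf <- defaults$Vfmf_mean / 100
  if (!is.numeric(target_Vnm) || target_Vnm < 0 || target_Vnm > 1) {
    stop("target_Vnm must be a fraction in [0, 1]")
  }
  if (!is.null(target_sigma_intra) && target_sigma_intra < 0) {
    stop("target_sigma_intra must be >= 0 (percentage points)")
  }
  if (pixel_size_nm <= 0 || image_edge_um <= 0) stop("lengths must be positive")
  all_pat <- c("interstitial", "diffuse", "stringy", "patchy", "compact")
  w <- setNames(numeric(5), all_pat)
  if (is.null(names(pattern_weights)) ||
      !all(names(pattern_weights) %in% all_pat)) {
    stop("pattern_weights must be named with pattern names")
  }
  w[names(pattern_weights)] <- as.numeric(pattern_weights)
  if (any(w < 0) || sum(w) <= 0) stop("pattern weights must be nonnegative, not all zero")
  w <- w / sum(w)
  if (target_Vf_plus_Vmf < 0 || target_Vf_plus_Vmf > target_Vnm) {
    stop("target_Vf_plus_Vmf must lie in [0, target_Vnm]")
  }
  structure(
    list(
      group = group, target_Vnm = target_Vnm,
      target_sigma_intra = target_sigma_intra,
      pattern_weights = w,
      target_Vf_plus_Vmf = target_Vf_plus_Vmf,
      image_edge_um = image_edge_um,
      pixel_size_nm = pixel_size_nm,
      tile_edge_um = tile_edge_um,
      rng_seed = as.integer(rng_seed)
    ),
    class = "tissue_spec"
  )
}

# Study-condition defaults per group: group means/SDs of V_nm and
# sigma_intra (in %), fibroblast+myofibroblast fraction, and pattern mixes.
group_profile <- function(group) {
  switch(group,
    donor = list(
      Vnm_mean = 22.09, Vnm_sd = 2.72,
      sigma_mean = 7.47, sigma_sd = 1.37,
      Vfmf_mean = 2.0, Vfmf_sd = 0.23,
      weights = c(interstitial = 0.75, diffuse = 0.25)
    ),
    NIC = list(
      Vnm_mean = 32.16, Vnm_sd = 6.55,
      sigma_mean = 15.69, sigma_sd = 5.76,
      Vfmf_mean = 2.5, Vfmf_sd = 0.5,
      weights = c(interstitial = 0.35, diffuse = 0.35, stringy = 0.15, patchy = 0.15)
    ),
    IC = list(
      Vnm_mean = 47.2, Vnm_sd = 16.18,
      sigma_mean = 27.1, sigma_sd = 6.03,
      Vfmf_mean = 2.5, Vfmf_sd = 0.5,
      weights = c(interstitial = 0.10, diffuse = 0.10, patchy = 0.45, compact = 0.35)
    ),
    stop("unknown group: ", group)
  )
}

#' Calibrate the tile-level mixture of the tissue generator
#'
#' The generator controls composition and heterogeneity through a two-component
#' tile mixture: a fraction `p_hi` of "saturated" tiles at a high non-myocyte
#' fraction `v_hi` (fed by the patchy/compact weights) and the remaining tiles
#' at a base level `b` with texture SD `s0`. This function solves for
#' `(p_hi, b, s0)` so that the mixture mean equals `target_Vnm` and (when a
#' heterogeneity target is given) the mixture SD equals `target_sigma_intra`.
#'
#' @param spec a [tissue_spec()].
#' @param tolerance acceptable miss, in percentage points, on the achieved
#'   mean and SD before the combination is reported infeasible.
#' @return List with mixture parameters, the analytically achieved mean/SD
#'   (in %), and `converged`.
#' @export
calibrate_generator <- function(spec, tolerance = 1) {
  stopifnot(inherits(spec, "tissue_spec"))
  m <- spec$target_Vnm
  w <- spec$pattern_weights
  h <- w[["patchy"]] + w[["compact"]]
  v_hi <- if (h > 0) (0.85 * w[["patchy"]] + 1.0 * w[["compact"]]) / h else 1.0
  if (v_hi < m + 0.02) v_hi <- 1.0
  s_target <- if (is.null(spec$target_sigma_intra)) NULL else spec$target_sigma_intra / 100
  s0 <- 0.025 + 0.05 * (w[["diffuse"]] + w[["stringy"]]) + 0.03 * w[["patchy"]]

  b_of <- function(p) (m - p * v_hi) / (1 - p)
  sd_of <- function(p, s0) {
    b <- b_of(p)
    sqrt(p * (v_hi - m)^2 + (1 - p) * ((b - m)^2 + s0^2))
  }
  p_max <- if (v_hi > 0.01) max(0, min(0.98, (m - 0.005) / (v_hi - 0.005))) else 0

  if (is.null(s_target)) {
    # heterogeneity determined by the pattern mix: more patchy/compact mass
    # means more saturated tiles, hence larger tile-to-tile SD
    p <- min(p_max, 0.45 * h)
  } else if (s_target <= s0) {
    s0 <- s_target
    p <- 0
  } else if (sd_of(p_max, s0) <= s_target) {
    p <- p_max
  } else {
    p <- stats::uniroot(function(p) sd_of(p, s0) - s_target,
                        lower = 0, upper = p_max, tol = 1e-10)$root
  }
  b <- b_of(p)
  if (b < 0) { b <- 0; p <- min(p_max, m / max(v_hi, 1e-9)) }
  ach_mean <- p * v_hi + (1 - p) * b
  ach_sd <- sd_of(p, s0)
  converged <- abs(ach_mean - m) * 100 <= tolerance &&
    (is.null(s_target) || abs(ach_sd - s_target) * 100 <= tolerance)
  if (!converged) {
    warning(sprintf(
      "target combination not reachable; closest achieved V_nm = %.2f%%, sigma_intra = %.2f%%",
      100 * ach_mean, 100 * ach_sd
    ))
  }
  list(
    p_hi = p, v_hi = v_hi, base_mean = b, base_sd = s0,
    achieved_Vnm = 100 * ach_mean, achieved_sigma_intra = 100 * ach_sd,
    converged = converged
  )
}

# Nearest-pixel tile boundaries for a tile grid in physical units, anchored
# at the image origin; returns 0-based pixel offsets of the K+1 boundaries of
# the K complete tiles (incomplete edge tiles are dropped).
tile_boundaries <- function(n_px, pixel_size_nm, tile_edge_um) {
  tile_px <- tile_edge_um * 1000 / pixel_size_nm
  k_max <- 0L
  while (round((k_max + 1L) * tile_px) <= n_px) k_max <- k_max + 1L
  if (k_max < 1L) stop("region smaller than one tile")
  as.integer(round((0:k_max) * tile_px))
}

# ---- pattern priority fields ------------------------------------------------
# Each field assigns every pixel a "fill priority" in micrometres (smaller =
# converted to non-myocyte space earlier). Tiles are filled to their target
# fraction by taking the lowest-priority pixels, so the field shape sets the
# fibrosis texture while tile targets set composition exactly.

dist_to_skeleton <- function(skel, px_um) {
  # distance (um) of every pixel to the nearest skeleton pixel
  d <- EBImage::distmap(matrix(as.numeric(!skel), nrow(skel)))
  as.numeric(px_um) * EBImage::imageData(d)
}

field_cleft <- function(ny, nx, px_um) {
  # staggered myocyte lattice ~20 x 100 um aligned with x: priority is the
  # distance to the nearest cell outline, so ES grows as interstitial clefts
  y_um <- (seq_len(ny) - 0.5) * px_um
  x_um <- (seq_len(nx) - 0.5) * px_um
  skel <- matrix(FALSE, ny, nx)
  row_id <- floor(y_um / 20)
  # horizontal row boundaries (long myocyte edges)
  bdry_rows <- which(diff(c(-1, row_id)) != 0)
  skel[bdry_rows, ] <- TRUE
  # vertical end caps, staggered half a cell length per row, with jitter
  for (r in unique(row_id)) {
    yy <- which(row_id == r)
    off <- (r %% 2) * 50 + runif(1, -10, 10)
    xb <- seq(off %% 100, max(x_um) + 100, by = 100)
    cols <- unique(pmax(1L, pmin(nx, round(xb / px_um))))
    skel[yy, cols] <- TRUE
  }
  dist_to_skeleton(skel, px_um)
}

field_stringy <- function(ny, nx, px_um) {
  # long thin well-separated strands parallel to the myocyte axis
  skel <- matrix(FALSE, ny, nx)
  y_max <- ny * px_um
  y0 <- runif(1, 0, 25)
  for (yc in seq(y0, y_max, by = 25)) {
    rr <- round((yc + runif(1, -4, 4)) / px_um)
    if (rr >= 1 && rr <= ny) skel[rr, ] <- TRUE
  }
  dist_to_skeleton(skel, px_um)
}

field_diffuse <- function(ny, nx, px_um) {
  # short scattered strands (< 100 um), mostly along the myocyte axis
  skel <- matrix(FALSE, ny, nx)
  area_um2 <- ny * nx * px_um^2
  n_seg <- max(4L, round(area_um2 / 1e4 * 4))
  for (i in seq_len(n_seg)) {
    cx <- runif(1, 0, nx * px_um); cy <- runif(1, 0, ny * px_um)
    len <- runif(1, 20, 80); ang <- runif(1, -pi / 6, pi / 6)
    tt <- seq(-len / 2, len / 2, by = px_um / 2)
    cc <- round((cx + tt * cos(ang)) / px_um)
    rr <- round((cy + tt * sin(ang)) / px_um)
    ok <- cc >= 1 & cc <= nx & rr >= 1 & rr <= ny
    skel[cbind(rr[ok], cc[ok])] <- TRUE
  }
  dist_to_skeleton(skel, px_um)
}

field_patchy <- function(ny, nx, px_um, centers_rc) {
  # compact/patchy growth from seed points (typically the saturated-tile
  # cluster centres), giving large contiguous fibrotic regions
  skel <- matrix(FALSE, ny, nx)
  skel[centers_rc] <- TRUE
  dist_to_skeleton(skel, px_um)
}

# ---- generation -------------------------------------------------------------

#' Generate one synthetic segmented tissue image
#'
#' Deterministically (given the spec seed) renders ES, fibroblast and
#' myofibroblast masks whose whole-image non-myocyte fraction matches
#' `target_Vnm` to well under one percentage point and whose 50-um tile SD
#' matches `target_sigma_intra` (when given). Tile-level targets come from
#' the calibrated mixture of [calibrate_generator()]; pixels within each tile
#' are converted to non-myocyte space in the order of a pattern-specific
#' priority field (interstitial clefts, diffuse/stringy strands, patchy and
#' compact regions).
#'
#' @param spec a [tissue_spec()].
#' @return A [tissue_image()] with the spec attached as attribute `"spec"`.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$rng_seed, {
    px_um <- spec$pixel_size_nm / 1000
    n_px <- as.integer(round(spec$image_edge_um / px_um))
    ny <- nx <- n_px
    bx <- tile_boundaries(nx, spec$pixel_size_nm, spec$tile_edge_um)
    by <- tile_boundaries(ny, spec$pixel_size_nm, spec$tile_edge_um)
    ntx <- length(bx) - 1L; nty <- length(by) - 1L
    n_tiles <- ntx * nty

    cal <- suppressWarnings(calibrate_generator(spec))
    targets <- draw_tile_targets(spec, cal, ntx, nty)

    # saturated-tile cluster centres seed the patchy/compact field
    hi_rc <- which(targets$is_hi, arr.ind = TRUE)
    centers_rc <- if (nrow(hi_rc) > 0) {
      cbind(
        pmin(ny, pmax(1, round((by[hi_rc[, 1]] + by[hi_rc[, 1] + 1L]) / 2))),
        pmin(nx, pmax(1, round((bx[hi_rc[, 2]] + bx[hi_rc[, 2] + 1L]) / 2)))
      )
    } else {
      cbind(round(ny / 2), round(nx / 2))
    }

    cleft <- field_cleft(ny, nx, px_um)
    need <- function(p) any(targets$pattern == p)
    fields <- list(interstitial = cleft)
    if (need("diffuse")) fields$diffuse <- pmin(field_diffuse(ny, nx, px_um), cleft + 1.5)
    if (need("stringy")) fields$stringy <- pmin(field_stringy(ny, nx, px_um), cleft + 1.5)
    if (need("patchy") || need("compact")) {
      fp <- field_patchy(ny, nx, px_um, centers_rc)
      fields$patchy <- pmin(fp, cleft + 2)
      fields$compact <- fields$patchy
    }

    nm <- matrix(FALSE, ny, nx)
    tie <- matrix(runif(ny * nx, 0, 1e-3), ny, nx)
    for (ti in seq_len(nty)) {
      rows <- (by[ti] + 1L):by[ti + 1L]
      for (tj in seq_len(ntx)) {
        cols <- (bx[tj] + 1L):bx[tj + 1L]
        tgt <- targets$value[ti, tj]
        npix <- length(rows) * length(cols)
        k <- round(tgt * npix)
        if (k <= 0) next
        if (k >= npix) {
          nm[rows, cols] <- TRUE
          next
        }
        f <- fields[[targets$pattern[ti, tj]]]
        p <- f[rows, cols] + tie[rows, cols]
        sel <- order(p)[seq_len(k)]
        blk <- matrix(FALSE, length(rows), length(cols))
        blk[sel] <- TRUE
        nm[rows, cols] <- blk
      }
    }
    # pixels beyond the last complete tile keep the overall target level
    if (by[nty + 1L] < ny || bx[ntx + 1L] < nx) {
      rem <- matrix(TRUE, ny, nx)
      rem[seq_len(by[nty + 1L]), seq_len(bx[ntx + 1L])] <- FALSE
      idx <- which(rem)
      k <- round(spec$target_Vnm * length(idx))
      if (k > 0) {
        p <- cleft[idx] + tie[idx]
        nm[idx[order(p)[seq_len(k)]]] <- TRUE
      }
    }

    cells <- place_cell_masks(nm, spec$target_Vf_plus_Vmf, px_um)
    img <- tissue_image(
      es_mask = nm & !cells$fib & !cells$myofib,
      fibroblast_mask = cells$fib,
      myofibroblast_mask = cells$myofib,
      pixel_size_nm = spec$pixel_size_nm,
      myocyte_axis = "x-aligned",
      group = spec$group,
      provenance = sprintf("synthetic(group=%s, seed=%d)", spec$group, spec$rng_seed)
    )
    attr(img, "spec") <- spec
    attr(img, "calibration") <- cal
    img
  })
}

# Draw per-tile target fractions from the calibrated mixture, with saturated
# tiles spatially clustered, then correct the sample mean (and SD, when a
# heterogeneity target is set) to the spec targets.
draw_tile_targets <- function(spec, cal, ntx, nty) {
  n <- ntx * nty
  w <- spec$pattern_weights
  h <- w[["patchy"]] + w[["compact"]]
  n_hi <- round(cal$p_hi * n)
  is_hi <- matrix(FALSE, nty, ntx)
  value <- matrix(0, nty, ntx)

  if (n_hi > 0) {
    cl_size <- if (h > 0) 6 + 20 * w[["compact"]] / h else 8
    n_cl <- max(1L, round(n_hi / cl_size))
    ctr <- cbind(runif(n_cl, 1, nty), runif(n_cl, 1, ntx))
    tc <- expand.grid(r = seq_len(nty), c = seq_len(ntx))
    d <- apply(cbind(tc$r, tc$c), 1, function(p) {
      min(sqrt((p[1] - ctr[, 1])^2 + (p[2] - ctr[, 2])^2))
    })
    hi_idx <- order(d + runif(n, 0, 1.5))[seq_len(n_hi)]
    is_hi[cbind(tc$r[hi_idx], tc$c[hi_idx])] <- TRUE
    frac_compact <- if (h > 0) w[["compact"]] / h else 0
    hv <- ifelse(runif(n_hi) < frac_compact, 1.0,
                 pmin(1, pmax(0.6, rnorm(n_hi, cal$v_hi, 0.04))))
    value[is_hi] <- hv
  }
  n_lo <- n - n_hi
  value[!is_hi] <- pmin(1, pmax(0.005, rnorm(n_lo, cal$base_mean, cal$base_sd)))

  # pattern per tile: saturated tiles are patchy/compact, background tiles
  # split among interstitial/diffuse/stringy by weight
  pattern <- matrix("interstitial", nty, ntx)
  if (n_hi > 0) {
    frac_compact <- if (h > 0) w[["compact"]] / h else 0
    pattern[is_hi] <- ifelse(value[is_hi] >= 0.999, "compact", "patchy")
  }
  lo_w <- w[c("interstitial", "diffuse", "stringy")]
  if (sum(lo_w) <= 0) lo_w <- c(interstitial = 1, diffuse = 0, stringy = 0)
  pattern[!is_hi] <- sample(names(lo_w), n_lo, replace = TRUE, prob = lo_w / sum(lo_w))

  # moment correction on the background tiles: iterate mean shifts and
  # deviation rescaling (clipping to [0, 0.97] each round) until the sample
  # mean and SD sit on the targets or the adjustment stalls
  m <- spec$target_Vnm
  s <- if (is.null(spec$target_sigma_intra)) NULL else spec$target_sigma_intra / 100
  lo <- !is_hi
  clip <- function(v) { v[v < 0] <- 0; v[v > 1] <- 1; v }
  if (any(lo)) {
    for (it in 1:40) {
      value[lo] <- clip(value[lo] + (m - mean(value)) * n / sum(lo))
      mean_ok <- abs(mean(value) - m) < 5e-4
      sd_ok <- TRUE
      if (!is.null(s) && n > 1) {
        cs <- sd(value)
        sd_ok <- abs(cs - s) < 2e-3
        if (!sd_ok && cs > 1e-9) {
          # rescale all tiles about the target mean; saturated tiles are
          # pushed into full saturation when extra variance is needed
          value <- clip(m + (value - m) * (s / cs))
        }
      }
      if (mean_ok && sd_ok) break
    }
    value[lo] <- pmin(1, pmax(0, value[lo] + (m - mean(value)) * n / sum(lo)))
  }
  list(value = value, is_hi = is_hi, pattern = pattern)
}

# Place fibroblast and myofibroblast masks as small (~50 um^2) blobs inside
# the non-myocyte region, half of the target fraction each.
place_cell_masks <- function(nm, target_frac, px_um) {
  ny <- nrow(nm); nx <- ncol(nm)
  fib <- matrix(FALSE, ny, nx)
  myofib <- matrix(FALSE, ny, nx)
  n_target <- round(target_frac / 2 * length(nm))
  if (n_target == 0 || !any(nm)) return(list(fib = fib, myofib = myofib))
  r_px <- max(1, sqrt(50 / pi) / px_um)
  rr <- ceiling(r_px)
  dd <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  dd <- dd[dd$dr^2 + dd$dc^2 <= r_px^2, ]
  pool <- which(nm)
  for (mask_name in c("fib", "myofib")) {
    mask <- matrix(FALSE, ny, nx)
    placed <- 0L
    guard <- 0L
    while (placed < n_target && guard < 20000L) {
      guard <- guard + 1L
      ctr <- pool[sample.int(length(pool), 1L)]
      cr <- ((ctr - 1L) %% ny) + 1L
      cc <- ((ctr - 1L) %/% ny) + 1L
      pr <- cr + dd$dr; pc <- cc + dd$dc
      ok <- pr >= 1 & pr <= ny & pc >= 1 & pc <= nx
      idx <- cbind(pr[ok], pc[ok])
      keep <- nm[idx] & !mask[idx] & !fib[idx] & !myofib[idx]
      idx <- idx[keep, , drop = FALSE]
      if (nrow(idx) == 0) next
      take <- min(nrow(idx), n_target - placed)
      mask[idx[seq_len(take), , drop = FALSE]] <- TRUE
      placed <- placed + take
    }
    if (mask_name == "fib") fib <- mask else myofib <- mask
  }
  list(fib = fib, myofib = myofib)
}

#' Generate a seeded cohort of synthetic tissue images
#'
#' Subject-level targets (non-myocyte fraction, heterogeneity, fibroblast +
#' myofibroblast fraction) are drawn from the group-level distributions the
#' study conditions define (donor 22.09 +/- 2.72% V_nm with sigma_intra
#' 7.47 +/- 1.37%; NIC 32.16 +/- 6.55% with 15.69 +/- 5.76%; IC
#' 47.2 +/- 16.18% with 27.1 +/- 6.03%), then one image is generated per
#' subject with a seed derived deterministically from `seed`.
#'
#' @param n_donor,n_nic,n_ic subject counts per group.
#' @param seed master seed for the cohort.
#' @param image_edge_um,pixel_size_nm image geometry passed to [tissue_spec()].
#' @return A list of [tissue_image()]s; each has its `tissue_spec` attached,
#'   and `attr(, "groups")` holds the group label vector.
#' @export
generate_cohort <- function(n_donor, n_nic, n_ic, seed,
                            image_edge_um = 1000, pixel_size_nm = 378) {
  stopifnot(n_donor >= 0, n_nic >= 0, n_ic >= 0)
  groups <- rep(c("donor", "NIC", "IC"), times = c(n_donor, n_nic, n_ic))
  if (length(groups) == 0) {
    out <- list()
    attr(out, "groups") <- character(0)
    return(out)
  }
  base_seed <- (as.integer(seed) %% 1000000L) * 1000L
  specs <- with_seed(seed, {
    lapply(seq_along(groups), function(i) {
      g <- groups[i]
      prof <- group_profile(g)
      vnm <- min(0.92, max(0.06, rnorm(1, prof$Vnm_mean, prof$Vnm_sd) / 100))
      sig_max <- 95 * sqrt(vnm * (1 - vnm))
      sig <- min(sig_max, max(1, rnorm(1, prof$sigma_mean, prof$sigma_sd)))
      vfmf <- min(0.8 * vnm, max(0.005, rnorm(1, prof$Vfmf_mean, prof$Vfmf_sd) / 100))
      tissue_spec(
        group = g, target_Vnm = vnm, target_sigma_intra = sig,
        target_Vf_plus_Vmf = vfmf,
        image_edge_um = image_edge_um, pixel_size_nm = pixel_size_nm,
        rng_seed = base_seed + i
      )
    })
  })
  out <- lapply(specs, generate_tissue)
  attr(out, "groups") <- groups
  out
}
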