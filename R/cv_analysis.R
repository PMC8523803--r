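#' Activation-time, upstroke and conduction-block maps
#'
#' For every active element the activation time is the time of maximal
#' upstroke velocity (first differences of the recorded membrane voltage)
#' restricted to the (-60, 0) mV window: a sampling interval qualifies when
#' it is rising and intersects the window (so a voltage-clamp step that
#' crosses the whole window between two samples still registers). Elements
#' with no qualifying interval are marked non-conductive. Times are
#' reported relative to stimulus onset.
#'
#' @param recording a `field_recording` from [simulate_bidomain()].
#' @return List of class `activation_map`: matrices `activation_ms`,
#'   `upstroke_V_per_s` (NA where non-conductive/passive), logical
#'   `non_conductive` (passive elements included), `block_labels`
#'   (8-connected labels of non-conductive regions), `n_blocked`.
#' @export
activation_map <- function(recording) {
  stopifnot(inherits(recording, "field_recording"))
  t_ms <- recording$times_ms
  if (length(t_ms) < 3) stop("recording stride too coarse to resolve the upstroke")
  dt_frame <- diff(t_ms)
  if (max(dt_frame) > 0.05) {
    warning(sprintf(
      "recording interval %.3g ms may under-resolve 200-300 V/s upstrokes; consider <= 0.005 ms",
      max(dt_frame)
    ))
  }
  V <- recording$Vm_mV
  nf <- ncol(V)
  V0 <- V[, -nf, drop = FALSE]
  V1 <- V[, -1, drop = FALSE]
  DV <- (V1 - V0) / rep(dt_frame, each = nrow(V))  # mV/ms == V/s
  eligible <- pmin(V0, V1) < 0 & pmax(V0, V1) > -60 & DV > 0
  DV[!eligible | is.na(DV)] <- -Inf
  best <- max.col(DV, ties.method = "first")
  has <- is.finite(DV[cbind(seq_len(nrow(DV)), best)])
  act <- ifelse(has, t_ms[best] - recording$stim_onset_ms, NA_real_)
  ups <- ifelse(has, DV[cbind(seq_len(nrow(DV)), best)], NA_real_)

  ny <- recording$ny; nx <- recording$nx
  act_m <- matrix(act, ny, nx)
  ups_m <- matrix(ups, ny, nx)
  ncond <- matrix(!has, ny, nx)
  blocks <- label_components8(ncond)
  structure(
    list(
      activation_ms = act_m,
      upstroke_V_per_s = ups_m,
      non_conductive = ncond,
      block_labels = blocks,
      n_blocked = max(blocks),
      ny = ny, nx = nx,
      element_edge_um = recording$element_edge_um,
      stimulus_edge = recording$stimulus_edge
    ),
    class = "activation_map"
  )
}

# stimulus edge -> conduction direction label of the resulting wave
edge_direction <- function(edge) {
  switch(edge, left = "+x", right = "-x", top = "+y", bottom = "-y")
}

#' Conduction-velocity vectors from an activation map
#'
#' Measures CV at L-shaped triplets of adjacent grid points (a corner point
#' plus its +x and +y neighbours, spacing `l` = one element edge). With
#' activation-time differences `tx` and `ty` along the two pairs, the
#' magnitude is `l / sqrt(tx^2 + ty^2)` and the tilt angle from the
#' direction normal to the line stimulus follows the direction-specific
#' branch: `+x: atan(ty/tx)`, `-x: 180 - atan(ty/tx)`, `+y: 90 -
#' atan(ty/tx)`, `-y: 90 + atan(ty/tx)`, evaluated with the two-argument
#' arctangent. A triplet touching a non-activated point is reported as
#' blocked, never as a number.
#'
#' @param amap an [activation_map()].
#' @param direction conduction direction `"+x"`, `"-x"`, `"+y"`, `"-y"`;
#'   defaults to the direction implied by the recorded stimulus edge.
#' @param locations integer matrix (rows: `row`, `col` of the triplet corner
#'   point); defaults to the four points of a centred 2x2 lattice over the
#'   mesh (quarter points).
#' @return Data frame of class `cv_measurements`: `row`, `col`,
#'   `direction`, `tx_s`, `ty_s`, `magnitude_m_per_s`, `angle_deg`,
#'   `blocked`.
#' @export
cv_vectors <- function(amap, direction = NULL, locations = NULL) {
  stopifnot(inherits(amap, "activation_map"))
  if (is.null(direction)) direction <- edge_direction(amap$stimulus_edge)
  direction <- match.arg(direction, c("+x", "-x", "+y", "-y"))
  ny <- amap$ny; nx <- amap$nx
  if (is.null(locations)) {
    locations <- as.matrix(expand.grid(
      row = pmax(1L, pmin(ny - 1L, round(c(0.25, 0.75) * ny))),
      col = pmax(1L, pmin(nx - 1L, round(c(0.25, 0.75) * nx)))
    ))
  }
  if (any(locations[, 1] < 1 | locations[, 1] > ny - 1 |
          locations[, 2] < 1 | locations[, 2] > nx - 1)) {
    stop("triplet location outside grid (needs +x and +y neighbours)")
  }
  l_m <- amap$element_edge_um * 1e-6
  t_ms <- amap$activation_ms
  rows <- lapply(seq_len(nrow(locations)), function(k) {
    r <- locations[k, 1]; cc <- locations[k, 2]
    t0 <- t_ms[r, cc]
    tx <- (t_ms[r, cc + 1L] - t0) * 1e-3  # s
    ty <- (t_ms[r + 1L, cc] - t0) * 1e-3
    blocked <- any(is.na(c(t0, tx, ty)))
    if (blocked || (tx == 0 && ty == 0)) {
      return(data.frame(
        row = r, col = cc, direction = direction,
        tx_s = if (blocked) NA_real_ else tx,
        ty_s = if (blocked) NA_real_ else ty,
        magnitude_m_per_s = NA_real_, angle_deg = NA_real_,
        blocked = blocked
      ))
    }
    mag <- l_m / sqrt(tx^2 + ty^2)
    base <- atan2(ty, tx) * 180 / pi
    ang <- switch(direction,
      "+x" = base, "-x" = 180 - base,
      "+y" = 90 - base, "-y" = 90 + base
    )
    # wrap to (-180, 180]
    ang <- ((ang + 180) %% 360) - 180
    if (ang == -180) ang <- 180
    data.frame(
      row = r, col = cc, direction = direction,
      tx_s = tx, ty_s = ty,
      magnitude_m_per_s = mag, angle_deg = ang, blocked = blocked
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cv_measurements", class(out))
  out
}

#' Measure CV vectors for a whole protocol run
#'
#' Convenience wrapper: builds activation maps and CV measurements for each
#' recording of [run_protocol()] at shared sampling locations.
#'
#' @param recordings named list of `field_recording`s.
#' @param locations see [cv_vectors()].
#' @return One `cv_measurements` data frame with an `edge` column.
#' @export
protocol_cv <- function(recordings, locations = NULL) {
  rows <- lapply(names(recordings), function(e) {
    m <- cv_vectors(activation_map(recordings[[e]]), locations = locations)
    m$edge <- e
    m
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cv_measurements", class(out))
  out
}

#' Pool CV measurements and summarize per subject and group
#'
#' Longitudinal measurements are the `+x`/`-x` directions and transverse the
#' `+y`/`-y` directions. Per subject the medians of |CVL|, |CVT|, |angle L|,
#' |angle T| and the anisotropy ratio median|CVL| / median|CVT| are
#' computed over non-blocked measurements; subjects whose measurements are
#' all blocked in a direction class are reported with `NA` and flagged.
#'
#' @param measurements a `cv_measurements` data frame with added columns
#'   `subject` and (optionally) `group`.
#' @return List with `per_subject` and `per_group` data frames.
#' @export
pool_and_summarize <- function(measurements) {
  stopifnot("subject" %in% names(measurements))
  if (!"group" %in% names(measurements)) measurements$group <- NA_character_
  is_long <- measurements$direction %in% c("+x", "-x")
  med <- function(x) if (length(x) == 0) NA_real_ else median(x)
  per_subject <- do.call(rbind, lapply(split(
    measurements, measurements$subject
  ), function(d) {
    ok <- !d$blocked & !is.na(d$magnitude_m_per_s)
    L <- ok & d$direction %in% c("+x", "-x")
    T_ <- ok & d$direction %in% c("+y", "-y")
    data.frame(
      subject = d$subject[1], group = d$group[1],
      median_CVL = med(d$magnitude_m_per_s[L]),
      median_CVT = med(d$magnitude_m_per_s[T_]),
      median_abs_angle_L = med(abs(d$angle_deg[L])),
      median_abs_angle_T = med(abs(d$angle_deg[T_])),
      n_blocked = sum(d$blocked),
      all_blocked = all(d$blocked)
    )
  }))
  per_subject$anisotropy <- per_subject$median_CVL / per_subject$median_CVT
  per_group <- do.call(rbind, lapply(split(
    per_subject, per_subject$group
  ), function(d) {
    data.frame(
      group = d$group[1], n = nrow(d),
      mean_CVL = mean(d$median_CVL, na.rm = TRUE),
      sd_CVL = sd(d$median_CVL, na.rm = TRUE),
      mean_CVT = mean(d$median_CVT, na.rm = TRUE),
      sd_CVT = sd(d$median_CVT, na.rm = TRUE),
      mean_anisotropy = mean(d$anisotropy, na.rm = TRUE)
    )
  }))
  rownames(per_subject) <- rownames(per_group) <- NULL
  list(per_subject = per_subject, per_group = per_group)
}

#' Boundary-effect error between original and extended-domain CV
#'
#' Compares CV vectors measured on a mesh with those measured at the same
#' sampling locations after embedding the mesh in a homogeneously extended
#' domain. Reports mean signed errors (extended minus original) and RMSE in
#' percent, normalized by the original magnitudes (angles are normalized by
#' a quarter turn, 90 degrees).
#'
#' @param cv_original,cv_extended `cv_measurements` at matched locations and
#'   directions.
#' @return List with `mean_error_magnitude`, `mean_error_angle`,
#'   `rmse_pct_magnitude`, `rmse_pct_angle`, `n`.
#' @export
boundary_error <- function(cv_original, cv_extended) {
  key <- function(d) paste(d$row, d$col, d$direction)
  if (!identical(key(cv_original), key(cv_extended))) {
    stop("sampling locations/directions do not match")
  }
  ok <- !cv_original$blocked & !cv_extended$blocked
  mo <- cv_original$magnitude_m_per_s[ok]
  me <- cv_extended$magnitude_m_per_s[ok]
  ao <- cv_original$angle_deg[ok]
  ae <- cv_extended$angle_deg[ok]
  list(
    mean_error_magnitude = mean(me - mo),
    mean_error_angle = mean(ae - ao),
    rmse_pct_magnitude = 100 * sqrt(mean(((me - mo) / mo)^2)),
    rmse_pct_angle = 100 * sqrt(mean(((ae - ao) / 90)^2)),
    n = sum(ok)
  )
}

#' Passive space constants of the bidomain tissue
#'
#' Electrotonic length scales `lambda = sqrt((R / beta) * sigma_myo *
#' sigma_e / (sigma_myo + sigma_e))` for the longitudinal and transverse
#' directions, with conductivities scaled by the element volume fractions
#' (100% by default).
#'
#' @param params a [conductivity_params()].
#' @param V_myo,V_e volume-fraction context for the two domains.
#' @return List with `lambda_l_mm` and `lambda_t_mm`.
#' @export
space_constants <- function(params = conductivity_params(), V_myo = 1, V_e = 1) {
  sml <- V_myo * params$sigma_myo_long_100
  sel <- V_e * params$sigma_e_long_100
  smt <- sml / params$anis_myo
  set <- sel / params$anis_e
  if (sml + sel <= 0 || smt + set <= 0) stop("zero conductivity sum")
  lam <- function(sm, se) {
    sqrt((params$membrane_R / params$beta_sv) * sm * se / (sm + se)) * 1e3
  }
  list(lambda_l_mm = lam(sml, sel), lambda_t_mm = lam(smt, set))
}
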