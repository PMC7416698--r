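# OCT B-scan processing: from a depth x lateral reflectivity matrix to the
# per-eccentricity structural and reflectivity features used by the models.
#
# Conventions used throughout: depth in um with 0 at the RPE2/Bruch's
# membrane complex and increasing toward the vitreous; eccentricity in
# degrees with 0 at the foveola. Boundary order above BrM is
# RPE2/BrM < RPE1 < COST < EZ < ELM < OPL.

#' Segmentation tuning parameters
#'
#' @param smooth_sd Gaussian smoothing SD in axial samples applied to every
#'   LRP before peak finding (suppresses speckle-level wiggles).
#' @param prom_frac minimum peak prominence as a fraction of the scan's
#'   maximum smoothed reflectivity.
#' @param amp_sigma tolerance of the relative-amplitude score used when
#'   assigning candidate bands to boundary roles.
#' @param skip_penalty score penalty for declaring a boundary missing.
#' @param unassigned_penalty score penalty for leaving a candidate band
#'   unassigned (e.g. the inner surface).
#' @param max_jump maximum plausible boundary depth change (um) relative to
#'   the lateral running median before a point is flagged.
#' @param max_gap largest run of flagged A-scans (count) filled by linear
#'   interpolation; longer gaps stay flagged.
#' @param max_bands A-scans with more candidate bands than this are treated
#'   as speckle-only and flagged unsegmentable.
#' @param depth_priors list of per-role admissible depth windows (um above
#'   BrM).
#' @param expected_rel expected band amplitudes relative to RPE2/BrM.
#' @return named list of parameters.
#' @export
segmentation_config <- function(smooth_sd = 1, prom_frac = 0.15,
                                amp_sigma = 0.15, skip_penalty = 1.5,
                                unassigned_penalty = 0.5, max_jump = 8,
                                max_gap = 5, max_bands = 12,
                                depth_priors = list(
                                  rpe1 = c(6, 45), cost = c(12, 60),
                                  ez = c(16, 130), elm = c(25, 200),
                                  opl = c(40, 300)),
                                expected_rel = c(rpe1 = 0.7, cost = 0.6,
                                                 ez = 0.8, elm = 0.35,
                                                 opl = 0.45)) {
  as.list(environment())
}

.check_bscan <- function(scan) {
  stopifnot(inherits(scan, "bscan"))
  if (is.unsorted(scan$depth_um, strictly = TRUE) ||
      is.unsorted(scan$lateral_deg, strictly = TRUE))
    stopf("bscan axes must be strictly increasing")
}

axial_step_of <- function(scan) diff(scan$depth_um[1:2])

#' Reduce lateral sampling density by block-averaging neighbouring LRPs
#'
#' Neighbouring A-scans are averaged in non-overlapping, contiguous,
#' nearly-equal blocks chosen so that the output density matches
#' `target_per_15deg` A-scans per 15 degrees (e.g. 4091 -> 512 for a 15 deg
#' scan). The lateral axis of the result is the block centre; the
#' reflectivity of each block is its mean, which increases signal-to-noise
#' without moving band positions.
#'
#' @param scan a `bscan`.
#' @param target_per_15deg target lateral density (A-scans per 15 deg).
#' @return a `bscan` with fewer A-scans.
#' @export
downsample_lrps <- function(scan, target_per_15deg = 512) {
  .check_bscan(scan)
  extent <- diff(range(scan$lateral_deg))
  n <- length(scan$lateral_deg)
  n_out <- max(1L, round(target_per_15deg * extent / 15))
  if (n_out > n)
    stopf("target density (%d A-scans) exceeds input density (%d)", n_out, n)
  # contiguous blocks of size floor or ceiling, n_out of them
  block_id <- floor((seq_len(n) - 1) * n_out / n) + 1
  refl <- t(rowsum(t(scan$reflectivity), block_id) /
              as.vector(table(block_id)))
  lat <- as.vector(tapply(scan$lateral_deg, block_id, mean))

  truth <- attr(scan, "truth")
  truth_out <- if (!is.null(truth))
    apply(truth, 2, function(v) as.vector(tapply(v, block_id, mean)))
  structure(list(reflectivity = unname(refl), depth_um = scan$depth_um,
                 lateral_deg = lat, aligned = scan$aligned,
                 foveola = scan$foveola),
            class = "bscan", truth = truth_out,
            foveola_true = attr(scan, "foveola_true"))
}

#' Align a B-scan by straightening the RPE2/BrM band to depth 0
#'
#' The strongest hyperreflective band of each smoothed LRP is taken as
#' RPE2/BrM and the profile is shifted (with edge padding) so that its peak
#' sits at depth 0. A-scans whose maximum lies at the matrix border (a
#' truncated band) are flagged and excluded from feature extraction.
#' Idempotent up to +/- 1 axial step.
#'
#' @param scan a `bscan`.
#' @param config a [segmentation_config()].
#' @return an aligned `bscan` (attribute `flagged_ascans` marks truncated
#'   columns).
#' @export
align_to_brm <- function(scan, config = segmentation_config()) {
  .check_bscan(scan)
  refl <- scan$reflectivity
  if (max(refl) - min(refl) < 1e-10)
    stopf("no detectable band: scan is flat")
  sm <- gaussian_smooth(refl, config$smooth_sd)
  n_depth <- nrow(refl)
  idx0 <- which.min(abs(scan$depth_um))
  peak_idx <- apply(sm, 2, which.max)
  flagged <- peak_idx == 1L | peak_idx == n_depth

  out <- refl
  truth <- attr(scan, "truth")
  for (j in seq_len(ncol(refl))) {
    if (flagged[j]) next
    k <- peak_idx[j] - idx0
    if (k == 0) next
    if (k > 0) { # band too deep in the matrix: shift values down
      out[, j] <- c(refl[(k + 1):n_depth, j], rep(refl[n_depth, j], k))
    } else {
      out[, j] <- c(rep(refl[1, j], -k), refl[1:(n_depth + k), j])
    }
    if (!is.null(truth)) truth[j, ] <- truth[j, ] - k * axial_step_of(scan)
  }
  structure(list(reflectivity = out, depth_um = scan$depth_um,
                 lateral_deg = scan$lateral_deg, aligned = TRUE,
                 foveola = scan$foveola),
            class = "bscan", truth = truth,
            foveola_true = attr(scan, "foveola_true"),
            flagged_ascans = which(flagged))
}

#' Locate the foveola as the maximum depression of the inner retinal surface
#'
#' Mirrors manual foveola identification: if `override` is given it is
#' returned unchanged. Otherwise the inner-retinal surface is detected per
#' A-scan as the most vitread depth at which the smoothed reflectivity
#' exceeds a fraction of its range, the surface is smoothed laterally, and
#' the lateral position of its minimum height above BrM (the deepest pit
#' point) is returned; ties are broken toward the scan centre.
#'
#' @param scan an aligned `bscan`.
#' @param override manual foveola position in degrees, or `NULL`.
#' @param surface_frac reflectivity fraction defining the surface crossing.
#' @param lateral_smooth_sd lateral Gaussian smoothing of the surface, in
#'   A-scans.
#' @param config a [segmentation_config()].
#' @return foveola lateral position in degrees.
#' @export
locate_foveola <- function(scan, override = NULL, surface_frac = 0.15,
                           lateral_smooth_sd = 5,
                           config = segmentation_config()) {
  if (!is.null(override)) return(override)
  .check_bscan(scan)
  if (!isTRUE(scan$aligned)) stopf("scan must be aligned first")

  sm <- gaussian_smooth(scan$reflectivity, config$smooth_sd)
  n_depth <- nrow(sm)
  surface <- apply(sm, 2, function(v) {
    thr <- min(v) + surface_frac * (max(v) - min(v))
    idx <- which(v >= thr)
    scan$depth_um[max(idx)]
  })
  surface <- gaussian_smooth(surface, lateral_smooth_sd)

  n <- length(surface)
  lo <- which(surface <= min(surface) + 1e-6)
  center <- (n + 1) / 2
  best <- lo[which.min(abs(lo - center))]
  if (best <= 2 || best >= n - 1)
    stopf(paste("no interior surface depression found (monotone surface);",
                "supply override="))
  scan$lateral_deg[best]
}

# ---- boundary assignment ---------------------------------------------------

# Order-preserving assignment of candidate peaks (ascending depth) to the
# five boundary roles above BrM, maximising an amplitude+depth plausibility
# score; roles may be skipped (missing band) and peaks left unassigned.
assign_roles <- function(peak_depth, peak_rel_amp, config) {
  roles <- c("rpe1", "cost", "ez", "elm", "opl")
  m <- length(peak_depth)
  r <- length(roles)
  score <- matrix(-Inf, m, r)
  for (j in seq_len(m)) {
    for (k in seq_len(r)) {
      pr <- config$depth_priors[[roles[k]]]
      if (peak_depth[j] >= pr[1] && peak_depth[j] <= pr[2])
        score[j, k] <- -((peak_rel_amp[j] - config$expected_rel[[roles[k]]]) /
                           config$amp_sigma)^2
    }
  }
  # DP over (peaks so far, roles so far)
  M <- matrix(-Inf, m + 1, r + 1)
  back <- matrix(0L, m + 1, r + 1) # 1=skip peak, 2=skip role, 3=match
  M[1, 1] <- 0
  for (j in 0:m) for (k in 0:r) {
    if (j == 0 && k == 0) next
    best <- -Inf; b <- 0L
    if (j > 0 && M[j, k + 1] - config$unassigned_penalty > best) {
      best <- M[j, k + 1] - config$unassigned_penalty; b <- 1L
    }
    if (k > 0 && M[j + 1, k] - config$skip_penalty > best) {
      best <- M[j + 1, k] - config$skip_penalty; b <- 2L
    }
    if (j > 0 && k > 0 && is.finite(score[j, k]) &&
        M[j, k] + score[j, k] > best) {
      best <- M[j, k] + score[j, k]; b <- 3L
    }
    M[j + 1, k + 1] <- best; back[j + 1, k + 1] <- b
  }
  assignment <- setNames(rep(NA_real_, r), roles)
  j <- m; k <- r
  while (j > 0 || k > 0) {
    b <- back[j + 1, k + 1]
    if (b == 3L) { assignment[k] <- peak_depth[j]; j <- j - 1; k <- k - 1 }
    else if (b == 1L) j <- j - 1
    else if (b == 2L) k <- k - 1
    else break
  }
  assignment
}

# Quadratic sub-sample refinement of a peak position on a smoothed LRP.
refine_peak <- function(v, idx, depth) {
  if (idx <= 1 || idx >= length(v)) return(depth[idx])
  num <- v[idx - 1] - v[idx + 1]
  den <- v[idx - 1] - 2 * v[idx] + v[idx + 1]
  if (abs(den) < 1e-12) return(depth[idx])
  depth[idx] + 0.5 * num / den * diff(depth[1:2])
}

#' Segment six outer retinal boundaries from an aligned B-scan
#'
#' Per A-scan, candidate bands are prominence-filtered local maxima of the
#' smoothed LRP with sub-sample quadratic peak refinement. RPE2/BrM is the
#' band at depth 0 (the alignment reference); the remaining candidates are
#' assigned to RPE1, COST, EZ (IS/OS), ELM and OPL by an order-preserving
#' dynamic program over expected depth windows and relative amplitudes, so
#' a missing band (e.g. an IS/OS defect) is flagged rather than forcing a
#' wrong assignment. A lateral smoothness pass flags depths jumping more
#' than `max_jump` um from the running median and interpolates flagged runs
#' up to `max_gap` A-scans. Per-A-scan manual overrides mirror
#' computer-assisted correction.
#'
#' @param scan an aligned `bscan`.
#' @param config a [segmentation_config()].
#' @param overrides optional data frame with columns `ascan` (column index),
#'   `boundary` (one of opl, elm, ez, cost, rpe1, rpe2_brm) and `depth_um`;
#'   applied after automatic assignment.
#' @return object of class `layer_segmentation`: `boundaries` (A-scan x 6
#'   matrix of depths, um above BrM; NA = missing), `flags` (logical matrix,
#'   TRUE where a boundary was not confidently assigned), `lateral_deg`.
#' @export
segment_layers <- function(scan, config = segmentation_config(),
                           overrides = NULL) {
  .check_bscan(scan)
  if (!isTRUE(scan$aligned)) stopf("scan must be aligned first")
  refl <- scan$reflectivity
  sm <- gaussian_smooth(refl, config$smooth_sd)
  depth <- scan$depth_um
  step <- axial_step_of(scan)
  n_ascans <- ncol(refl)
  prom_min <- config$prom_frac * max(sm)
  roles <- c("opl", "elm", "ez", "cost", "rpe1", "rpe2_brm")

  boundaries <- matrix(NA_real_, n_ascans, 6,
                       dimnames = list(NULL, roles))
  unsegmentable <- logical(n_ascans)
  flagged_cols <- attr(scan, "flagged_ascans") %||% integer(0)

  for (j in seq_len(n_ascans)) {
    if (j %in% flagged_cols) { unsegmentable[j] <- TRUE; next }
    pk <- find_peaks(sm[, j], prom_min)
    if (nrow(pk) < 2 || nrow(pk) > config$max_bands) {
      unsegmentable[j] <- TRUE
      next
    }
    pk_depth <- vapply(pk$index, function(i) refine_peak(sm[, j], i, depth),
                       numeric(1))
    pk_amp <- sm[pk$index, j]
    # the alignment reference: band nearest depth 0
    brm_i <- which.min(abs(pk_depth))
    if (abs(pk_depth[brm_i]) > 3 * step) { unsegmentable[j] <- TRUE; next }
    boundaries[j, "rpe2_brm"] <- pk_depth[brm_i]
    rel <- pk_amp / pk_amp[brm_i]
    cand <- setdiff(order(pk_depth), brm_i)
    cand <- cand[pk_depth[cand] > 3 * step]
    if (length(cand)) {
      asg <- assign_roles(pk_depth[cand], rel[cand], config)
      boundaries[j, names(asg)] <- asg
    }
  }

  if (mean(unsegmentable) > 0.5)
    stopf("scan rejected as unsegmentable: fewer than 2 detectable bands in %d%% of A-scans",
          round(100 * mean(unsegmentable)))

  flags <- is.na(boundaries)
  # lateral smoothness: flag outliers against a running median, then fill
  # short gaps by interpolation
  for (b in roles) {
    v <- boundaries[, b]
    med <- stats::runmed(ifelse(is.na(v), stats::median(v, na.rm = TRUE), v),
                         k = min(5L, n_ascans - (1 - n_ascans %% 2)))
    bad <- !is.na(v) & abs(v - med) > config$max_jump
    v[bad] <- NA
    filled <- fill_short_gaps(v, config$max_gap)
    flags[, b] <- is.na(filled) # interpolated points count as assigned
    boundaries[, b] <- filled
  }
  boundaries[unsegmentable, ] <- NA
  flags[unsegmentable, ] <- TRUE

  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      boundaries[overrides$ascan[i], overrides$boundary[i]] <-
        overrides$depth_um[i]
      flags[overrides$ascan[i], overrides$boundary[i]] <- FALSE
    }
  }

  structure(list(boundaries = boundaries, flags = flags,
                 lateral_deg = scan$lateral_deg),
            class = "layer_segmentation")
}

# linear interpolation across interior NA runs no longer than max_gap
fill_short_gaps <- function(v, max_gap) {
  if (!anyNA(v) || all(is.na(v))) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(!is.na(v))
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > max_gap) next
    if (starts[i] == 1 || ends[i] == length(v)) next
    v[starts[i]:ends[i]] <- approx(ok, v[ok],
                                   xout = starts[i]:ends[i])$y
  }
  v
}

#' @export
print.layer_segmentation <- function(x, ...) {
  cat(sprintf("Layer segmentation: %d A-scans, %.0f%% boundaries assigned\n",
              nrow(x$boundaries), 100 * mean(!x$flags)))
  invisible(x)
}

#' Layer thicknesses from a six-boundary segmentation
#'
#' Definitions (depths measured above BrM): `ONL = OPL - ELM`,
#' `IS = ELM - EZ`, `COS = EZ - COST`, `RPE = RPE1 - RPE2/BrM`. A thickness
#' whose defining boundary is flagged is `NA` (flag propagation); a negative
#' thickness is set to `NA` and flagged, never clipped to 0.
#'
#' @param seg a `layer_segmentation`.
#' @return data frame with columns `lateral_deg`, `onl`, `is_len`,
#'   `cos_len`, `rpe` (um; NA = flagged).
#' @export
thicknesses_from_segmentation <- function(seg) {
  stopifnot(inherits(seg, "layer_segmentation"))
  b <- seg$boundaries
  f <- seg$flags
  val <- function(col) ifelse(f[, col], NA_real_, b[, col])
  out <- data.frame(
    lateral_deg = seg$lateral_deg,
    onl = val("opl") - val("elm"),
    is_len = val("elm") - val("ez"),
    cos_len = val("ez") - val("cost"),
    rpe = val("rpe1") - val("rpe2_brm")
  )
  for (cn in c("onl", "is_len", "cos_len", "rpe"))
    out[[cn]][!is.na(out[[cn]]) & out[[cn]] < 0] <- NA_real_
  out
}

#' Count gradient extrema of an LRP between ELM and RPE2/BrM
#'
#' The number of positive plus negative peaks of the first difference of the
#' smoothed LRP restricted to the open depth interval
#' (`brm_depth`, `elm_depth`), each required to exceed `min_prominence`.
#' This counts distinct reflective bands between the ELM and BrM (each
#' well-separated band contributes one gradient maximum and one minimum).
#'
#' @param lrp reflectivity vector (one A-scan).
#' @param depth_um depth axis of `lrp` (um above BrM).
#' @param elm_depth,brm_depth window bounds, `elm_depth > brm_depth`.
#' @param min_prominence minimum prominence on the gradient signal.
#' @param smooth_sd Gaussian smoothing SD (axial samples) before
#'   differencing.
#' @return integer extrema count.
#' @export
count_extrema <- function(lrp, depth_um, elm_depth, brm_depth = 0,
                          min_prominence, smooth_sd = 2) {
  if (elm_depth <= brm_depth) stopf("need elm_depth > brm_depth")
  sm <- gaussian_smooth(as.numeric(lrp), smooth_sd)
  sel <- depth_um > brm_depth & depth_um < elm_depth
  if (sum(sel) < 3) stopf("extrema window shorter than 3 samples")
  g <- diff(sm[sel])
  npos <- nrow(find_peaks(g, min_prominence))
  nneg <- nrow(find_peaks(-g, min_prominence))
  npos + nneg
}

#' Extract structural samples at the seven analysis eccentricities
#'
#' At each of the 7 grid eccentricities (foveola-centred, 0.25 deg
#' increments, -0.75 to +0.75), thicknesses are averaged over A-scans within
#' `+/- window` degrees of the target position, the extrema count is taken
#' on the window-averaged LRP, and the reflectivity vector is the
#' window-averaged LRP resampled at fixed depths above BrM.
#'
#' @param scan an aligned `bscan`.
#' @param seg the matching `layer_segmentation`.
#' @param foveola foveola position in degrees (see [locate_foveola()]).
#' @param scan_id identifier stored with the samples.
#' @param window lateral averaging half-width in degrees.
#' @param refl_depths reflectivity sampling depths (um above BrM); default
#'   0-240 um in 4 um steps (61 values), wide enough to contain the OPL band
#'   for the thickest training retinas.
#' @param prom_frac extrema prominence threshold as a fraction of the
#'   scan's maximum reflectivity.
#' @return data frame of 7 rows with columns `scan_id`, `eccentricity`,
#'   `onl`, `is_len`, `cos_len`, `rpe`, `n_extrema`, `refl_01`..`refl_61`.
#' @export
extract_samples <- function(scan, seg, foveola, scan_id = "scan",
                            window = 0.05, refl_depths = seq(0, 240, by = 4),
                            prom_frac = 0.05) {
  .check_bscan(scan)
  if (!isTRUE(scan$aligned)) stopf("scan must be aligned first")
  ecc_grid <- seq(-0.75, 0.75, by = 0.25)
  targets <- foveola + ecc_grid
  lat <- scan$lateral_deg
  if (any(targets < min(lat) | targets > max(lat)))
    stopf("grid eccentricity outside scan extent")
  th <- thicknesses_from_segmentation(seg)
  prom_min <- prom_frac * max(scan$reflectivity)

  rows <- lapply(seq_along(ecc_grid), function(k) {
    sel <- which(abs(lat - targets[k]) <= window + 1e-9)
    if (!length(sel)) sel <- which.min(abs(lat - targets[k]))
    lrp <- rowMeans(scan$reflectivity[, sel, drop = FALSE])
    elm_d <- mean(seg$boundaries[sel, "elm"], na.rm = TRUE)
    nx <- if (is.finite(elm_d))
      count_extrema(lrp, scan$depth_um, elm_d, 0, prom_min) else NA_integer_
    rv <- approx(scan$depth_um, lrp, xout = refl_depths, rule = 2)$y
    mcol <- function(v) {
      x <- mean(v[sel], na.rm = TRUE)
      if (is.nan(x)) NA_real_ else x
    }
    c(onl = mcol(th$onl), is_len = mcol(th$is_len),
      cos_len = mcol(th$cos_len), rpe = mcol(th$rpe), n_extrema = nx, rv)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("onl", "is_len", "cos_len", "rpe", "n_extrema",
                   sprintf("refl_%02d", seq_along(refl_depths)))
  data.frame(scan_id = scan_id, eccentricity = ecc_grid, m,
             row.names = NULL)
}
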