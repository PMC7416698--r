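# Synthetic cohorts and B-scans.
#
# The generator states the world the analysis assumes: an IRD training cohort
# whose foveal ONL spans 24-150 um with cone outer segment (COS) length
# linearly coupled to ONL (population r ~ 0.814), foveal sensitivity and
# acuity following the log quantum-catch curves plus measurement noise; and
# BCM cohorts with non-detectable sensitivity, reduced acuity, and short COS
# statistically independent of ONL (C203R retaining thicker ONL than the
# deletion genotype).

# mean and variance of a log-uniform draw on [a, b]
.loguniform_moments <- function(a, b) {
  L <- log(b / a)
  m <- (b - a) / L
  m2 <- (b^2 - a^2) / (2 * L)
  c(mean = m, var = m2 - m^2)
}

#' Default geometry and coupling parameters for the synthetic world
#'
#' All structural units are micrometres; eccentricity is in degrees. The COS
#' coupling (`cos_b0`, `cos_b1`) places normal foveal COS near 34 um at ONL
#' 130 um and ~13 um at the degenerate end of the training range, matching
#' the qualitative structure of clinical foveal OCT. `interdigitation_gap`
#' is the COST-to-apical-RPE separation.
#'
#' @param onl_range_ird,onl_range_normal log-uniform ONL sampling ranges (um).
#' @param cos_b0,cos_b1 intercept/slope of the COS-on-ONL coupling line.
#' @param resid_cos_frac fraction of the functional residual variance
#'   carried by the COS deviation from the coupling line (quantum catch
#'   depends on outer-segment length as well as cell count, so part of the
#'   scatter around the ONL curves is structured by COS). The residual
#'   remains N(0, noise SD) marginally and independent of ONL; this only
#'   correlates it with COS.
#' @param is_b0,is_b1,is_sd inner segment length model (linear in ONL).
#' @param rpe_mean,rpe_sd RPE thickness distribution.
#' @param onl_range_deletion,onl_range_c203r uniform BCM ONL ranges (um).
#' @param bcm_cos_range uniform BCM COS range, independent of ONL (um).
#' @param bcm_va_range uniform BCM decimal acuity range.
#' @param age_range_ird,age_range_normal,age_range_deletion,age_range_c203r
#'   uniform age ranges (years).
#' @param interdigitation_gap COST to RPE1 separation (um).
#' @param pit_width Gaussian half-width of the foveal pit (deg).
#' @param rim_inner inner-retinal thickness recovered at the pit rim (um).
#' @param onl_decline,subret_decline fractional fall-off of ONL and of
#'   IS/COS across +/- 0.75 deg.
#' @return named list of parameters.
#' @export
cohort_config <- function(onl_range_ird = c(24, 150),
                          onl_range_normal = c(110, 150),
                          cos_b0 = 5, cos_b1 = 0.22,
                          resid_cos_frac = 0.5,
                          is_b0 = 18, is_b1 = 0.08, is_sd = 1.5,
                          rpe_mean = 18, rpe_sd = 1.5,
                          onl_range_deletion = c(35, 75),
                          onl_range_c203r = c(65, 115),
                          bcm_cos_range = c(4.5, 10.5),
                          bcm_va_range = c(0.08, 0.25),
                          age_range_ird = c(18, 72),
                          age_range_normal = c(22, 32),
                          age_range_deletion = c(7, 20),
                          age_range_c203r = c(13, 52),
                          interdigitation_gap = 10,
                          pit_width = 0.4, rim_inner = 150,
                          onl_decline = 0.12, subret_decline = 0.08) {
  as.list(environment())
}

# shared per-subject structural draws given an ONL vector
.draw_structure <- function(onl, cfg) {
  n <- length(onl)
  list(
    is_fovea = pmax(6, cfg$is_b0 + cfg$is_b1 * onl + rnorm(n, 0, cfg$is_sd)),
    rpe_fovea = pmax(10, rnorm(n, cfg$rpe_mean, cfg$rpe_sd)),
    pit_width = cfg$pit_width * exp(rnorm(n, 0, 0.05)),
    rim_inner = cfg$rim_inner * exp(rnorm(n, 0, 0.05))
  )
}

.cohort_df <- function(subject_id, group, age, fs, va, onl, is_f, cos_f,
                       rpe_f, pit_width, rim_inner, cfg) {
  structure(
    data.frame(subject_id = subject_id, group = group, age = age,
               fs_db = fs, va_decimal = va,
               gt_onl_fovea = onl, gt_is_fovea = is_f, gt_cos_fovea = cos_f,
               gt_rpe_fovea = rpe_f, gt_pit_width = pit_width,
               gt_rim_inner = rim_inner,
               gt_onl_decline = cfg$onl_decline,
               gt_subret_decline = cfg$subret_decline,
               gt_interdigitation_gap = cfg$interdigitation_gap,
               stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame"))
}

#' Generate a synthetic IRD + normal training cohort
#'
#' Draws `n_ird` inherited-retinal-degeneration subjects with foveal ONL
#' log-uniform on the training range (default 24-150 um) and `n_normal`
#' normals near the upper end; COS is generated linearly in ONL with Gaussian
#' scatter tuned analytically so the population ONL-COS correlation equals
#' `onl_cos_corr`. Foveal sensitivity follows
#' `FS = -12.01 + 17.38 * log10(ONL) + N(0, noise_fs_sd)` floored at 0 dB;
#' decimal acuity follows the VA curve with noise applied on the logMAR
#' scale (acuity noise is multiplicative in MAR).
#'
#' @param n_ird,n_normal cohort sizes (defaults 26 + 3 = 29).
#' @param noise_fs_sd FS measurement noise SD, dB (>= 0).
#' @param noise_va_sd VA measurement noise SD, logMAR (>= 0).
#' @param onl_cos_corr target population Pearson correlation between COS and
#'   ONL, in [0, 1).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @param config a [cohort_config()] list.
#' @return A `cohort_table` data frame (one row per subject) with measured
#'   columns `fs_db` (NA = non-detectable), `va_decimal`, and ground-truth
#'   columns prefixed `gt_`.
#' @export
generate_training_cohort <- function(n_ird = 26, n_normal = 3,
                                     noise_fs_sd = 1.5, noise_va_sd = 0.08,
                                     onl_cos_corr = 0.814, seed = 1,
                                     config = cohort_config()) {
  if (n_ird + n_normal < 5) stopf("need at least 5 subjects")
  if (noise_fs_sd < 0 || noise_va_sd < 0) stopf("noise SDs must be >= 0")
  if (onl_cos_corr < 0 || onl_cos_corr >= 1)
    stopf("onl_cos_corr must be in [0, 1)")
  cfg <- config
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)

  onl_ird <- exp(runif(n_ird, log(cfg$onl_range_ird[1]),
                       log(cfg$onl_range_ird[2])))
  onl_norm <- if (n_normal > 0)
    exp(runif(n_normal, log(cfg$onl_range_normal[1]),
              log(cfg$onl_range_normal[2]))) else numeric(0)
  onl <- c(onl_ird, onl_norm)
  n <- length(onl)

  # analytic mixture variance of the ONL draw, used to tune the COS scatter
  mi <- .loguniform_moments(cfg$onl_range_ird[1], cfg$onl_range_ird[2])
  w <- n_ird / n
  if (n_normal > 0) {
    mn <- .loguniform_moments(cfg$onl_range_normal[1], cfg$onl_range_normal[2])
    mu_mix <- w * mi["mean"] + (1 - w) * mn["mean"]
    var_mix <- w * (mi["var"] + mi["mean"]^2) +
      (1 - w) * (mn["var"] + mn["mean"]^2) - mu_mix^2
  } else {
    mu_mix <- mi["mean"]
    var_mix <- mi["var"]
  }
  sd_onl <- sqrt(as.numeric(var_mix))

  cos_hat <- cfg$cos_b0 + cfg$cos_b1 * onl
  if (onl_cos_corr > 0) {
    sd_e <- cfg$cos_b1 * sd_onl * sqrt(1 / onl_cos_corr^2 - 1)
    cos_f <- cos_hat + rnorm(n, 0, sd_e)
  } else {
    sd_e <- cfg$cos_b1 * sd_onl
    cos_f <- rnorm(n, cfg$cos_b0 + cfg$cos_b1 * as.numeric(mu_mix), sd_e)
  }
  # physical floor: IRD subjects with measurable cone function retain some
  # outer segment; also keeps rendered EZ/COST bands separable
  cos_f <- pmax(6, cos_f)

  st <- .draw_structure(onl, cfg)

  # Functional residuals: marginally N(0, noise SD) and independent of ONL,
  # but partly structured by the COS deviation from the coupling line --
  # quantum catch tracks outer-segment length, not only cell count. Shorter
  # COS than ONL predicts lowers FS and acuity (raises logMAR).
  rho <- cfg$resid_cos_frac
  cos_dev <- (cos_f - cos_hat) / sd_e
  fs <- pmax(0, fs_from_onl(onl) +
               noise_fs_sd * (sqrt(rho) * cos_dev +
                                sqrt(1 - rho) * rnorm(n)))
  va_true <- pmax(1e-3, va_from_onl(onl))
  logmar <- -log10(va_true) +
    noise_va_sd * (-sqrt(rho) * cos_dev + sqrt(1 - rho) * rnorm(n))
  va <- 10^(-logmar)

  age <- c(round(runif(n_ird, cfg$age_range_ird[1], cfg$age_range_ird[2])),
           if (n_normal > 0)
             round(runif(n_normal, cfg$age_range_normal[1],
                         cfg$age_range_normal[2])))
  ids <- c(sprintf("S%02d", seq_len(n_ird)),
           if (n_normal > 0) sprintf("N%d", seq_len(n_normal)))
  groups <- c(rep("IRD", n_ird), rep("normal", n_normal))

  .cohort_df(ids, groups, age, fs, va, onl, st$is_fovea, cos_f, st$rpe_fovea,
             st$pit_width, st$rim_inner, cfg)
}

#' Generate a synthetic BCM cohort
#'
#' All subjects have non-detectable foveal sensitivity (`fs_db = NA`) and
#' reduced decimal acuity. COS is drawn short and statistically independent
#' of ONL, the generator-level restatement of the observation that in BCM
#' the outer segments are uniformly shortened regardless of how much ONL
#' survives. The C203R genotype draws thicker ONL than the deletion genotype
#' at matched ages.
#'
#' @param genotype `"deletion"` or `"C203R"`.
#' @param n cohort size, >= 1 (the study cohorts were 8 + 8).
#' @param seed integer RNG seed.
#' @param config a [cohort_config()] list (BCM ranges are config-exposed:
#'   no reference distributions exist for BCM VA or age).
#' @return A `cohort_table` data frame; `group` is `"BCM_deletion"` or
#'   `"BCM_C203R"`.
#' @export
generate_bcm_cohort <- function(genotype = c("deletion", "C203R"), n = 8,
                                seed = 1, config = cohort_config()) {
  genotype <- match.arg(genotype)
  if (n < 1) stopf("cohort size must be >= 1")
  cfg <- config
  restore <- .Random.seed_guard(derive_seed(seed, genotype))
  on.exit(restore(), add = TRUE)

  rng <- if (genotype == "deletion") cfg$onl_range_deletion else
    cfg$onl_range_c203r
  agr <- if (genotype == "deletion") cfg$age_range_deletion else
    cfg$age_range_c203r
  onl <- runif(n, rng[1], rng[2])
  cos_f <- runif(n, cfg$bcm_cos_range[1], cfg$bcm_cos_range[2])
  va <- runif(n, cfg$bcm_va_range[1], cfg$bcm_va_range[2])
  age <- round(runif(n, agr[1], agr[2]))
  st <- .draw_structure(onl, cfg)

  ids <- sprintf("%s%02d", if (genotype == "deletion") "BD" else "BC",
                 seq_len(n))
  group <- if (genotype == "deletion") "BCM_deletion" else "BCM_C203R"
  .cohort_df(ids, rep(group, n), age, rep(NA_real_, n), va, onl, st$is_fovea,
             cos_f, st$rpe_fovea, st$pit_width, st$rim_inner, cfg)
}

#' Ground-truth retinal geometry for one synthetic subject
#'
#' Expands a cohort row into continuous thickness profiles and a foveal pit
#' profile. Thickness profiles peak at the foveola and decline quadratically
#' with eccentricity (ONL by `gt_onl_decline`, IS and COS by
#' `gt_subret_decline`, across +/- 0.75 deg); RPE is flat. The pit profile
#' gives the depth of the inner-retinal surface above Bruch's membrane: the
#' outer-retinal stack plus a thin residual inner retina at the foveola,
#' recovering `gt_rim_inner` um of inner retina at the rim with a Gaussian
#' shoulder of half-width `gt_pit_width` deg.
#'
#' @param row one row of a `cohort_table`.
#' @return object of class `ground_truth_retina` with scalar fields and
#'   function fields `thickness_profiles(ecc)` (matrix with columns
#'   onl, is, cos, rpe) and `pit_profile(ecc)` (um above BrM).
#' @export
ground_truth_retina <- function(row) {
  stopifnot(nrow(row) == 1)
  onl0 <- row$gt_onl_fovea; is0 <- row$gt_is_fovea
  cos0 <- row$gt_cos_fovea; rpe0 <- row$gt_rpe_fovea
  d_onl <- row$gt_onl_decline; d_sub <- row$gt_subret_decline
  gap <- row$gt_interdigitation_gap
  pw <- row$gt_pit_width; rim <- row$gt_rim_inner
  if (any(c(onl0, is0, cos0, rpe0) < 0)) stopf("negative ground truth")

  # quadratic decline across +/-0.75 deg, saturating beyond it so wide
  # scans stay physically valid (bands never collapse at the periphery)
  thickness_profiles <- function(ecc) {
    s <- pmin(1, (abs(ecc) / 0.75)^2)
    cbind(onl = onl0 * (1 - d_onl * s), is = is0 * (1 - d_sub * s),
          cos = cos0 * (1 - d_sub * s), rpe = rep(rpe0, length(ecc)))
  }
  # inner-retinal surface height above BrM: outer stack plus a 30 um
  # residual inner retina at the foveola, recovering `rim` um at the rim
  pit_profile <- function(ecc) {
    th <- thickness_profiles(ecc)
    opl <- th[, "rpe"] + gap + th[, "cos"] + th[, "is"] + th[, "onl"]
    opl + 30 + rim * (1 - exp(-(ecc / pw)^2))
  }
  structure(list(
    subject_id = row$subject_id, group = row$group,
    onl_fovea = onl0, is_fovea = is0, cos_fovea = cos0, rpe_fovea = rpe0,
    interdigitation_gap = gap,
    thickness_profiles = thickness_profiles, pit_profile = pit_profile
  ), class = "ground_truth_retina")
}

#' Relative reflectance amplitudes of the rendered OCT bands
#'
#' Preserves the qualitative amplitude ordering seen in clinical OCT so that
#' the segmentation's order-and-amplitude assignment logic is exercised:
#' RPE2/BrM is the globally strongest band. The `ilm` band marks the
#' inner-retinal surface used for foveola detection.
#'
#' @param opl,elm,ez,cost,rpe1,rpe2_brm,ilm relative amplitudes.
#' @return named numeric vector.
#' @export
band_amplitudes <- function(opl = 0.45, elm = 0.35, ez = 0.8, cost = 0.6,
                            rpe1 = 0.7, rpe2_brm = 1.0, ilm = 0.25) {
  c(opl = opl, elm = elm, ez = ez, cost = cost, rpe1 = rpe1,
    rpe2_brm = rpe2_brm, ilm = ilm)
}

# Boundary depths (um above BrM) for one retina at eccentricities `ecc`
# relative to the pit center. Columns ordered vitread to sclerad.
boundary_depths <- function(retina, ecc) {
  th <- retina$thickness_profiles(ecc)
  rpe1 <- th[, "rpe"]
  cost <- rpe1 + retina$interdigitation_gap
  ez <- cost + th[, "cos"]
  elm <- ez + th[, "is"]
  opl <- elm + th[, "onl"]
  cbind(ilm = retina$pit_profile(ecc), opl = opl, elm = elm, ez = ez,
        cost = cost, rpe1 = rpe1, rpe2_brm = rep(0, length(ecc)))
}

# One longitudinal reflectivity profile from boundary depths.
lrp_from_boundaries <- function(depths_um, bounds, amplitudes, band_sd = 2.5,
                                baseline = 0.05) {
  lrp <- rep(baseline, length(depths_um))
  for (nm in names(bounds)) {
    a <- amplitudes[[nm]]
    if (is.null(a) || is.na(a) || a <= 0) next
    lrp <- lrp + a * exp(-((depths_um - bounds[[nm]])^2) / (2 * band_sd^2))
  }
  lrp
}

#' Render a synthetic OCT B-scan from ground-truth geometry
#'
#' Each A-scan (longitudinal reflectivity profile, LRP) is a low baseline
#' plus Gaussian reflectance bands centred at the depths of the six outer
#' retinal boundaries (OPL, ELM, EZ, COST, RPE1, RPE2/BrM) plus an inner
#' surface (ILM) band, with additive Gaussian speckle. RPE2/BrM is the
#' globally strongest band and the ONL is hyporeflective. Ground-truth
#' boundary depths are stored alongside for oracle testing.
#'
#' @param retina a [ground_truth_retina()].
#' @param lateral_extent scan width in degrees (>= 1.5).
#' @param n_ascans number of A-scans (>= 64).
#' @param axial_step depth sampling in um (<= 4).
#' @param noise_sd additive Gaussian speckle SD (reflectance units).
#' @param seed RNG seed for the speckle.
#' @param pit_center lateral position of the foveola in the scan frame (deg).
#' @param amplitudes a [band_amplitudes()] vector.
#' @param band_sd axial Gaussian SD of each band (um); the default gives
#'   a ~6 um FWHM, typical of spectral-domain OCT axial resolution.
#' @param depth_max,depth_min depth window relative to BrM (um); the window
#'   extends a little below BrM so the alignment band is an interior peak,
#'   as in real scans where choroid lies beneath.
#' @param brm_tilt linear BrM depth drift across the scan (um/deg); non-zero
#'   tilt produces an unaligned scan for testing [align_to_brm()].
#' @return object of class `bscan`: `reflectivity` (depth x lateral matrix),
#'   `depth_um` (0 at BrM, increasing toward the vitreous), `lateral_deg`,
#'   `aligned`, `foveola` (NA until located), and attributes `truth`
#'   (boundary depth matrix) and `foveola_true`.
#' @export
render_bscan <- function(retina, lateral_extent = 3, n_ascans = 256,
                         axial_step = 2, noise_sd = 0.02, seed = 1,
                         pit_center = 0, amplitudes = band_amplitudes(),
                         band_sd = 2.5, depth_max = 480, depth_min = -40,
                         brm_tilt = 0) {
  stopifnot(inherits(retina, "ground_truth_retina"))
  if (n_ascans < 64) stopf("need at least 64 A-scans")
  if (axial_step > 4) stopf("axial_step must be <= 4 um")
  if (lateral_extent < 1.5) stopf("lateral_extent must be >= 1.5 deg")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")

  depth <- seq(depth_min, depth_max, by = axial_step)
  if (!any(depth == 0)) stopf("depth grid must contain 0 (BrM)")
  lateral <- seq(-lateral_extent / 2, lateral_extent / 2,
                 length.out = n_ascans)
  ecc <- lateral - pit_center
  bounds <- boundary_depths(retina, ecc)
  # non-negative tilt keeps the BrM band inside the depth window
  tilt <- brm_tilt * (lateral - min(lateral))
  bounds_t <- bounds + tilt # same shift for all boundaries of an A-scan

  # degenerate-geometry check on the six segmented boundaries
  seg_cols <- c("opl", "elm", "ez", "cost", "rpe1", "rpe2_brm")
  gaps <- abs(bounds[, seg_cols][, -1, drop = FALSE] -
                bounds[, seg_cols][, -6, drop = FALSE])
  if (any(gaps < 2 * axial_step))
    stopf("degenerate geometry: boundaries closer than 2*axial_step at %.2f deg",
          lateral[which(rowSums(gaps < 2 * axial_step) > 0)[1]])

  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  refl <- matrix(0.05, nrow = length(depth), ncol = n_ascans)
  for (nm in colnames(bounds_t)) {
    a <- amplitudes[[nm]]
    if (is.null(a) || is.na(a) || a <= 0) next
    refl <- refl + a * exp(-(outer(depth, bounds_t[, nm], "-")^2) /
                             (2 * band_sd^2))
  }
  if (noise_sd > 0)
    refl <- refl + matrix(rnorm(length(refl), 0, noise_sd), nrow(refl))

  structure(list(
    reflectivity = refl, depth_um = depth, lateral_deg = lateral,
    aligned = (brm_tilt == 0), foveola = NA_real_
  ), class = "bscan", truth = bounds_t, foveola_true = pit_center)
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("B-scan: %d depths x %d A-scans, %.1f deg, %saligned\n",
              length(x$depth_um), length(x$lateral_deg),
              diff(range(x$lateral_deg)), if (x$aligned) "" else "not "))
  invisible(x)
}

#' Build subject records directly from generator ground truth
#'
#' Fast path used for model-level simulation studies: per subject, builds
#' `n_scans` scans x 7 eccentricity structural samples from the ground-truth
#' thickness profiles plus per-scan Gaussian measurement noise, with the
#' reflectivity vector rendered analytically from the (noisy) boundary
#' depths. This bypasses image rendering and re-segmentation; the image path
#' is validated separately against the renderer oracle.
#'
#' @param cohort a `cohort_table`.
#' @param n_scans scans per subject (default 3).
#' @param thickness_noise_sd per-scan, per-eccentricity thickness measurement
#'   noise SD in um (default 2, typical segmentation repeatability).
#' @param seed RNG seed.
#' @param refl_depths depths (um above BrM) at which the reflectivity vector
#'   is sampled (default 0-240 um in 4 um steps, 61 values; the window must
#'   cover the OPL band across the full training ONL range).
#' @param amplitudes a [band_amplitudes()] vector.
#' @return list of `subject_record` objects (see [subject_record()]).
#' @export
samples_from_cohort <- function(cohort, n_scans = 3, thickness_noise_sd = 2,
                                seed = 1,
                                refl_depths = seq(0, 240, by = 4),
                                amplitudes = band_amplitudes()) {
  stopifnot(inherits(cohort, "cohort_table"))
  ecc_grid <- seq(-0.75, 0.75, by = 0.25)
  restore <- .Random.seed_guard(derive_seed(seed, "samples"))
  on.exit(restore(), add = TRUE)

  lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    retina <- ground_truth_retina(row)
    samples <- do.call(rbind, lapply(seq_len(n_scans), function(s) {
      th <- retina$thickness_profiles(ecc_grid)
      th <- pmax(th + matrix(rnorm(length(th), 0, thickness_noise_sd),
                             nrow(th)), 0)
      rpe1 <- th[, "rpe"]
      cost <- rpe1 + retina$interdigitation_gap
      ez <- cost + th[, "cos"]
      elm <- ez + th[, "is"]
      fine <- seq(0, max(refl_depths), by = 1)
      out <- lapply(seq_along(ecc_grid), function(k) {
        bounds <- list(opl = elm[k] + th[k, "onl"], elm = elm[k], ez = ez[k],
                       cost = cost[k], rpe1 = rpe1[k], rpe2_brm = 0)
        lrp_fine <- lrp_from_boundaries(fine, bounds, amplitudes)
        nx <- count_extrema(lrp_fine, fine, elm_depth = elm[k],
                            brm_depth = 0,
                            min_prominence = 0.05 * max(lrp_fine))
        rv <- approx(fine, lrp_fine, xout = refl_depths)$y
        c(onl = th[k, "onl"], is_len = th[k, "is"], cos_len = th[k, "cos"],
          rpe = th[k, "rpe"], n_extrema = nx, rv)
      })
      m <- do.call(rbind, out)
      colnames(m) <- c("onl", "is_len", "cos_len", "rpe", "n_extrema",
                       sprintf("refl_%02d", seq_along(refl_depths)))
      data.frame(scan_id = sprintf("%s_scan%d", row$subject_id, s),
                 eccentricity = ecc_grid, m, row.names = NULL)
    }))
    subject_record(row$subject_id, row$group, row$fs_db, row$va_decimal,
                   samples)
  })
}
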