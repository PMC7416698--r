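#' Convert decimal visual acuity to logMAR
#'
#' `logMAR = -log10(decimal acuity)`; 20/20 (decimal 1.0) is logMAR 0 and
#' each 0.1 logMAR is one ETDRS chart line.
#'
#' @param va decimal visual acuity, > 0 (vectorised).
#' @return logMAR value(s).
#' @examples
#' decimal_to_logmar(0.2)  # 0.69897
#' @export
decimal_to_logmar <- function(va) {
  if (any(!is.finite(va)) || any(va <= 0))
    stopf("decimal acuity must be positive")
  -log10(va)
}

# Round a logMAR value to the 0.1 ETDRS chart-line grid. Half-grid ties are
# rounded toward better acuity (lower logMAR).
round_to_chart_line <- function(logmar) {
  floor(logmar * 10 + 0.5 - 1e-9) / 10
}

#' ETDRS lines gained between a measured and a predicted acuity
#'
#' Both acuities are converted to logMAR and rounded to the nearest 0.1 (the
#' ETDRS chart-line grid; half-grid ties round toward better acuity); the
#' result is `10 * (rounded measured - rounded predicted)` lines, positive
#' when the predicted acuity is better than the measured one.
#'
#' @param va_measured,va_predicted decimal acuities, > 0.
#' @return integer number of chart lines gained.
#' @examples
#' etdrs_lines_gained(0.2, va_from_onl(90))  # 6
#' etdrs_lines_gained(0.2, va_from_onl(59))  # 4
#' @export
etdrs_lines_gained <- function(va_measured, va_predicted) {
  m <- round_to_chart_line(decimal_to_logmar(va_measured))
  p <- round_to_chart_line(decimal_to_logmar(va_predicted))
  as.integer(round(10 * (m - p)))
}

# Standard ETDRS denominators for the 20/x notation, logMAR -0.3 .. 1.0.
.chart_denominators <- c(10, 12.5, 16, 20, 25, 32, 40, 50, 63, 80,
                         100, 125, 160, 200)

#' Nearest ETDRS chart line as a Snellen string
#'
#' Rounds the acuity's logMAR to the nearest 0.1 chart line and reports the
#' standard Snellen 20/x denominator for that line. Acuities beyond the
#' 20/10 - 20/200 chart range are flagged rather than extrapolated.
#'
#' @param va decimal visual acuity, > 0.
#' @return Snellen string such as `"20/25"`, or a flagged string for
#'   off-chart acuities.
#' @examples
#' nearest_chart_line(va_from_onl(90))  # "20/25"
#' nearest_chart_line(va_from_onl(59))  # "20/40"
#' @export
nearest_chart_line <- function(va) {
  r <- round_to_chart_line(decimal_to_logmar(va))
  k <- as.integer(round((r + 0.3) * 10))
  if (k < 0 || k >= length(.chart_denominators))
    return(sprintf("off-chart (logMAR %.1f)", r))
  sprintf("20/%g", .chart_denominators[k + 1])
}

#' Treatment potential: predicted minus measured function
#'
#' The estimated best-case gain from a therapy that restores function to the
#' level commensurate with retained structure. For foveal sensitivity,
#' a non-detectable measurement (`NA` or the string `"ND"`) is floored at
#' `nd_floor` dB before differencing, so the potential is the full predicted
#' sensitivity; the delta is also reported in log units (10 dB = 1 log unit).
#' For visual acuity the delta is computed on the logMAR scale
#' (`logMAR_measured - logMAR_predicted`, positive = improvement) and also
#' reported as a decimal difference, together with ETDRS lines gained and the
#' predicted Snellen line. Non-detectable VA is rejected: no flooring
#' convention is defined for acuity.
#'
#' @param measured measured value (dB for FS, decimal for VA); for FS may be
#'   `NA` or `"ND"` meaning non-detectable.
#' @param predicted a `prediction` object (see [predict_cf()],
#'   [predict_subject()]).
#' @param target `"FS"` or `"VA"`.
#' @param subject_id optional identifier carried through to reports.
#' @param method optional label (`"I"`, `"II"`, `"CF"`).
#' @param nd_floor dB value substituted for non-detectable FS (default 0;
#'   device-dependent, hence configurable).
#' @return An object of class `treatment_potential`.
#' @export
treatment_potential <- function(measured, predicted, target = c("FS", "VA"),
                                subject_id = NA_character_,
                                method = NA_character_, nd_floor = 0) {
  target <- match.arg(target)
  stopifnot(inherits(predicted, "prediction"))
  is_nd <- is.na(measured) || (is.character(measured) && measured == "ND")

  if (target == "FS") {
    measured_num <- if (is_nd) nd_floor else as.numeric(measured)
    if (measured_num < 0) stopf("measured FS must be >= 0 dB")
    delta <- predicted$value - measured_num
    out <- list(delta = delta, delta_log_units = delta / 10,
                lines_gained = NA_integer_, snellen_predicted = NA_character_)
  } else {
    if (is_nd) stopf("non-detectable VA has no defined floor; supply a value")
    measured_num <- as.numeric(measured)
    if (measured_num <= 0) stopf("measured VA must be positive")
    if (predicted$value > 0) {
      delta <- decimal_to_logmar(measured_num) -
        decimal_to_logmar(predicted$value)
      lines <- etdrs_lines_gained(measured_num, predicted$value)
      snellen <- nearest_chart_line(predicted$value)
    } else {
      warning("predicted VA non-positive; logMAR delta undefined")
      delta <- NA_real_
      lines <- NA_integer_
      snellen <- NA_character_
    }
    out <- list(delta = delta,
                delta_decimal = predicted$value - measured_num,
                lines_gained = lines, snellen_predicted = snellen)
  }

  structure(c(list(subject_id = subject_id, target = target, method = method,
                   measured = if (is_nd) "ND" else measured_num,
                   measured_floored = measured_num,
                   predicted = predicted,
                   half_width = predicted$half_width), out),
            class = "treatment_potential")
}

#' @export
print.treatment_potential <- function(x, ...) {
  cat(sprintf("Treatment potential [%s, method %s] subject %s\n", x$target,
              x$method, x$subject_id))
  cat(sprintf("  measured %s -> predicted %.3g (+/- %.3g), delta %.3g\n",
              paste(x$measured), x$predicted$value, x$half_width, x$delta))
  invisible(x)
}

#' Kruskal-Wallis rank test (implemented from the rank formula)
#'
#' One-way ANOVA on ranks: with pooled ranks \eqn{R_j} summed per group,
#' \deqn{H = \frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3(N+1),}
#' divided by the tie correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}. The
#' p-value uses the chi-square approximation with `k - 1` degrees of freedom;
#' optionally a Monte Carlo permutation p-value is computed by reshuffling
#' group labels.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; at least 2 groups
#'   each with at least 2 observations.
#' @param n_perm number of label permutations for the permutation p-value
#'   (0 = skip).
#' @param seed RNG seed for the permutation draw.
#' @return list with `H`, `df`, `p_chisq`, and `p_perm` (NA if `n_perm = 0`).
#' @export
kruskal_wallis_test <- function(values, groups, n_perm = 0, seed = 1) {
  values <- as.numeric(values)
  groups <- as.factor(groups)
  if (length(values) != length(groups)) stopf("length mismatch")
  if (nlevels(droplevels(groups)) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("each group needs at least 2 observations")

  H_stat <- function(v, g) {
    N <- length(v)
    r <- rank(v)
    Rj <- tapply(r, g, sum)
    nj <- tapply(r, g, length)
    H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
    ties <- table(v)
    C <- 1 - sum(ties^3 - ties) / (N^3 - N)
    if (C <= 0) 0 else H / C
  }

  H <- H_stat(values, groups)
  df <- nlevels(droplevels(groups)) - 1
  p_chisq <- if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      H_stat(values, sample(groups)) >= H - 1e-12
    }, logical(1)))
    p_perm <- (hits + 1) / (n_perm + 1)
  }
  list(H = H, df = df, p_chisq = p_chisq, p_perm = p_perm)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
.Random.seed_guard <- function(seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
}

#' Compare treatment potential across prediction methods by genotype group
#'
#' Summarises per-subject treatment potentials (mean, SD, n per
#' genotype-group x method cell) and tests, within each genotype group and
#' target, whether the three prediction methods (Model I, Model II, curve
#' fit) differ, using [kruskal_wallis_test()]. Pairwise mean differences are
#' reported descriptively (no formal post-hoc procedure).
#'
#' @param potentials data frame with columns `subject_id`, `group`, `target`,
#'   `method`, `delta` (one row per subject x target x method).
#' @param n_perm permutations for the permutation p-value (0 = skip).
#' @param seed RNG seed for permutations.
#' @return list with elements `summary` (data frame) and `tests` (data
#'   frame with H, df, p_chisq, p_perm per group x target) and `pairwise`
#'   (descriptive mean differences).
#' @export
compare_groups <- function(potentials, n_perm = 0, seed = 1) {
  need <- c("subject_id", "group", "target", "method", "delta")
  if (!all(need %in% names(potentials)))
    stopf("potentials must have columns %s", paste(need, collapse = ", "))
  if (!nrow(potentials)) stopf("empty group: no potentials supplied")

  agg <- aggregate(delta ~ group + target + method, data = potentials,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  summary_df <- data.frame(agg[c("group", "target", "method")],
                           mean = agg$delta[, "mean"], sd = agg$delta[, "sd"],
                           n = agg$delta[, "n"])

  cells <- unique(potentials[c("group", "target")])
  tests <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- potentials[potentials$group == cells$group[i] &
                        potentials$target == cells$target[i], ]
    if (length(unique(sub$method)) < 2 || any(table(sub$method) < 2))
      return(NULL)
    kw <- kruskal_wallis_test(sub$delta, sub$method, n_perm = n_perm,
                              seed = derive_seed(seed, i))
    data.frame(group = cells$group[i], target = cells$target[i], H = kw$H,
               df = kw$df, p_chisq = kw$p_chisq, p_perm = kw$p_perm)
  }))

  pairwise <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- potentials[potentials$group == cells$group[i] &
                        potentials$target == cells$target[i], ]
    ms <- tapply(sub$delta, sub$method, mean)
    if (length(ms) < 2) return(NULL)
    cmb <- utils::combn(names(ms), 2)
    data.frame(group = cells$group[i], target = cells$target[i],
               method_a = cmb[1, ], method_b = cmb[2, ],
               mean_diff = ms[cmb[1, ]] - ms[cmb[2, ]], row.names = NULL)
  }))

  list(summary = summary_df, tests = tests, pairwise = pairwise)
}
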