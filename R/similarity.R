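#' Euclidean distance between a canthus landmark and the pupil center
#'
#' @param landmark,center 2-D points `c(x, y)` in a common coordinate frame.
#' @return Distance in pixels.
#' @export
canthus_distance <- function(landmark, center) {
  if (!all(is.finite(landmark)) || !all(is.finite(center))) {
    strab_error("canthus/center coordinates must be finite", "measurement_error")
  }
  sqrt(sum((unname(landmark)[1:2] - unname(center)[1:2])^2))
}

#' Per-eye distance measurement
#'
#' Collects the pupil center and its distances to the lateral (temple-side)
#' and medial (nose-side) canthus; the eye's deviation ratio is
#' `d_lateral / d_medial`, the same anatomical orientation for both eyes so
#' that a symmetric gaze gives matching ratios.
#'
#' @param side `"right"` or `"left"`.
#' @param pupil_center `c(x, y)` in source-image coordinates.
#' @param lateral_canthus,medial_canthus Canthus points, source-image
#'   coordinates.
#' @return An object of class `eye_measurement`.
#' @export
eye_measurement <- function(side, pupil_center, lateral_canthus, medial_canthus) {
  d_lat <- canthus_distance(lateral_canthus, pupil_center)
  d_med <- canthus_distance(medial_canthus, pupil_center)
  if (d_lat <= 0 || d_med <= 0) {
    strab_error(sprintf("%s eye: pupil center coincides with a canthus", side),
                "measurement_error")
  }
  structure(
    list(side = side, pupil_center = pupil_center,
         d_lateral = d_lat, d_medial = d_med, ratio = d_lat / d_med),
    class = "eye_measurement"
  )
}

#' Positional similarity of the two eyes
#'
#' `S = max(r_R, r_L) / min(r_R, r_L)` where `r_R`, `r_L` are the per-eye
#' canthus-distance ratios. S is always >= 1; S = 1 means the two irises sit
#' in mirror-symmetric positions within their palpebral fissures (normal
#' alignment), larger S indicates deviation of one eye.
#'
#' @param right,left [eye_measurement()] objects.
#' @param threshold Classification cutoff: `label = "suspect-strabismus"` iff
#'   `S > threshold` (default 1.2).
#' @return An object of class `screening_result` with fields `right`, `left`,
#'   `S`, `label`, `threshold_used`.
#' @export
positional_similarity <- function(right, left, threshold = 1.2) {
  ratios <- c(right$ratio, left$ratio)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    strab_error("per-eye ratios must be finite and positive", "measurement_error")
  }
  S <- max(ratios) / min(ratios)
  structure(
    list(right = right, left = left, S = S,
         label = if (S > threshold) "suspect-strabismus" else "normal",
         threshold_used = threshold),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Strabismus screening: S = %.4f (threshold %.3f) -> %s\n",
              x$S, x$threshold_used, x$label))
  for (side in c("right", "left")) {
    m <- x[[side]]
    cat(sprintf("  %-5s eye: center (%.2f, %.2f), d_lateral %.2f, d_medial %.2f, ratio %.4f\n",
                side, m$pupil_center[1], m$pupil_center[2],
                m$d_lateral, m$d_medial, m$ratio))
  }
  invisible(x)
}

#' One-sided Mann-Whitney U test between normal and strabismus cohorts
#'
#' Tests `H0: mu_N >= mu_S` against `HA: mu_N < mu_S`, where `mu_N` and `mu_S`
#' are the average similarity values of the normal and strabismus groups. The
#' U statistic is computed for the strabismus group (large U = strabismus
#' values rank higher); the default p-value uses the normal approximation with
#' continuity correction and tie-corrected variance. For small samples without
#' ties (`n1 * n2 <= 400`) the exact null distribution is available via
#' `method = "exact"`.
#'
#' @param normal_S,strab_S Numeric vectors of similarity values.
#' @param alpha Significance level (default 0.001).
#' @param method `"normal"` (default) or `"exact"`.
#' @return An object of class `cohort_stats`: group means, standard errors and
#'   sample standard deviations, `U`, `p_one_sided`, `alpha`, `reject_null`,
#'   `method`.
#' @export
mann_whitney_one_sided <- function(normal_S, strab_S, alpha = 0.001,
                                   method = c("normal", "exact")) {
  method <- match.arg(method)
  n_n <- length(normal_S); n_s <- length(strab_S)
  if (n_n == 0L || n_s == 0L) {
    strab_error("both cohorts must be non-empty", "cardinality_error")
  }
  combined <- c(strab_S, normal_S)
  rk <- rank(combined)
  U <- sum(rk[seq_len(n_s)]) - n_s * (n_s + 1) / 2
  N <- n_n + n_s
  tie_tab <- table(combined)
  has_ties <- any(tie_tab > 1)
  if (method == "exact") {
    if (has_ties) {
      warning("ties present; falling back to the normal approximation")
      method <- "normal"
    } else if (n_n * n_s > 400L) {
      strab_error("exact method limited to n1 * n2 <= 400", "configuration_error")
    }
  }
  if (method == "exact") {
    # P(U >= u) under the exact null distribution of the rank-sum statistic
    p <- stats::pwilcox(U - 1, n_s, n_n, lower.tail = FALSE)
  } else {
    mu <- n_n * n_s / 2
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n_n * n_s / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 0.5  # all observations identical: no evidence either way
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  structure(
    list(
      group_means = c(normal = mean(normal_S), strabismus = mean(strab_S)),
      group_se = c(normal = stats::sd(normal_S) / sqrt(n_n),
                   strabismus = stats::sd(strab_S) / sqrt(n_s)),
      group_sds = c(normal = stats::sd(normal_S), strabismus = stats::sd(strab_S)),
      n = c(normal = n_n, strabismus = n_s),
      U = U, p_one_sided = p, alpha = alpha,
      reject_null = p < alpha, method = method
    ),
    class = "cohort_stats"
  )
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("Cohort comparison (one-sided Mann-Whitney, %s method)\n", x$method))
  cat(sprintf("  normal:     mean S = %.3f +/- %.3f (sd %.3f, n = %d)\n",
              x$group_means["normal"], x$group_se["normal"],
              x$group_sds["normal"], x$n["normal"]))
  cat(sprintf("  strabismus: mean S = %.3f +/- %.3f (sd %.3f, n = %d)\n",
              x$group_means["strabismus"], x$group_se["strabismus"],
              x$group_sds["strabismus"], x$n["strabismus"]))
  cat(sprintf("  U = %g, one-sided p = %.4g, alpha = %g -> %s\n",
              x$U, x$p_one_sided, x$alpha,
              if (x$reject_null) "reject H0 (normal mean < strabismus mean)"
              else "fail to reject H0"))
  invisible(x)
}
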