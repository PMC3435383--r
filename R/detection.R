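# Detection limits: probability of seeing an OTU at all at a given depth,
# and the critical proportion for 95% confidence of detection.

#' Probability of detecting an OTU
#'
#' Probability that an OTU of proportion `p` yields a nonzero count when a
#' replicate aliquot of the same fluid is re-extracted and sequenced to
#' depth `size`, under the beta-binomial model with over-dispersion
#' `theta`. `theta = 0` gives the binomial closed form `1 - (1-p)^N`.
#'
#' @param p OTU proportion(s) in (0, 1).
#' @param size Sequencing depth N (positive integer).
#' @param theta Over-dispersion in \[0, 1). The study-wide median of
#'   replicate extractions is about 0.003; 0.03 is the observed worst case.
#' @return Detection probability, vectorized over `p`.
#' @seealso [critical_proportion()] for the inverse problem.
#' @examples
#' detection_probability(0.003, size = 5000, theta = 0.003)  # ~0.93
#' detection_probability(0.01, size = 500, theta = 0)        # binomial limit
#' @export
detection_probability <- function(p, size, theta) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)")
  }
  if (length(theta) != 1L || theta < 0 || theta >= 1) {
    stop("'theta' must be a single value in [0, 1)")
  }
  if (theta == 0) {
    # binomial limit: no over-dispersion between replicates
    return(1 - (1 - p)^size)
  }
  ab <- (1 - theta) / theta
  # P(X = 0) = B(a, b + N) / B(a, b) with a = p(a+b)
  vapply(p, function(pi) {
    1 - bb_prob_zero(size, bb_params(pi * ab, (1 - pi) * ab))
  }, 0)
}

#' Critical proportion for reliable detection
#'
#' The smallest OTU proportion whose probability of a nonzero count at
#' sequencing depth `size` reaches `confidence` (default 95%), under the
#' beta-binomial model with over-dispersion `theta`. Solved by bisection on
#' p (the detection probability is strictly increasing in p), to a
#' tolerance of 1e-9 on the proportion.
#'
#' @inheritParams detection_probability
#' @param size Sequencing depth(s); vectorized.
#' @param confidence Target detection probability in (0, 1); default 0.95.
#' @return Critical proportion(s) in (0, 1), one per depth.
#' @examples
#' critical_proportion(5000, theta = 0.003)  # ~0.0032 (prints as 0.3%)
#' critical_proportion(500, theta = 0.003)   # ~0.0098 (prints as 1.0%)
#' @export
critical_proportion <- function(size, theta, confidence = 0.95) {
  if (length(confidence) != 1L || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be a single probability in (0, 1)")
  }
  if (any(size < 1) || any(size != floor(size))) {
    stop("'size' must be a positive integer depth")
  }
  vapply(size, function(n) {
    lo <- 1e-12
    hi <- 1 - 1e-12
    f_hi <- detection_probability(hi, n, theta) - confidence
    if (f_hi < 0) {
      stop(sprintf(
        "no proportion reaches %.3g detection probability at depth %d with theta = %g",
        confidence, n, theta))
    }
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (detection_probability(mid, n, theta) < confidence) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, 0)
}

#' Detection-limit curve over sequencing depths
#'
#' Tabulates the critical proportion and critical count
#' (`depth * proportion`) over a grid of sequencing depths for a given
#' over-dispersion. The default grid, 100 to 10,000 in steps of 100, spans
#' the per-sample depths typical of replicate 16S surveys.
#'
#' @inheritParams critical_proportion
#' @param theta Over-dispersion; default 0.003, the median over replicate
#'   extractions. Use `theta = 0.03` for the observed worst case.
#' @param depths Integer vector of sequencing depths.
#' @return A data frame of class `"detection_curve"` with columns `depth`,
#'   `critical_proportion`, `critical_count`, and attributes `theta` and
#'   `confidence`.
#' @export
detection_curve <- function(theta = 0.003,
                            depths = seq(100L, 10000L, by = 100L),
                            confidence = 0.95) {
  cp <- critical_proportion(depths, theta, confidence)
  out <- data.frame(depth = as.integer(depths),
                    critical_proportion = cp,
                    critical_count = depths * cp)
  class(out) <- c("detection_curve", "data.frame")
  attr(out, "theta") <- theta
  attr(out, "confidence") <- confidence
  out
}

#' Polynomial fit of the critical count against depth
#'
#' Least-squares polynomial fit of the critical OTU count (depth times
#' critical proportion) as a function of sequencing depth. A quadratic
#' describes the curve at `theta = 0.003` with R-squared above 0.999; the
#' fit object also reports how much the next-higher degree would improve
#' R-squared, which is negligible for the default settings.
#'
#' @inheritParams detection_curve
#' @param degree Polynomial degree (>= 1, default 2).
#' @return An object of class `"critical_count_fit"`: a list with
#'   `degree`, `coefficients` (intercept first), `r_squared`,
#'   `r_squared_next_degree`, `delta_r_squared`, and the underlying
#'   `curve`.
#' @examples
#' fit <- fit_critical_count_curve(theta = 0.003)
#' fit$r_squared
#' @export
fit_critical_count_curve <- function(theta = 0.003,
                                     depths = seq(100L, 10000L, by = 100L),
                                     degree = 2L,
                                     confidence = 0.95) {
  if (degree < 1L) {
    stop("'degree' must be >= 1")
  }
  depths <- unique(as.integer(depths))
  if (length(depths) < degree + 2L) {
    stop("need at least degree + 2 distinct depths to assess the fit")
  }
  curve <- detection_curve(theta, depths, confidence)
  r2 <- function(d) {
    m <- lm(critical_count ~ poly(depth, d, raw = TRUE), data = curve)
    list(model = m,
         r2 = 1 - sum(residuals(m)^2) /
           sum((curve$critical_count - mean(curve$critical_count))^2))
  }
  fit <- r2(degree)
  fit_next <- r2(degree + 1L)
  structure(
    list(degree = as.integer(degree),
         coefficients = unname(coef(fit$model)),
         r_squared = fit$r2,
         r_squared_next_degree = fit_next$r2,
         delta_r_squared = fit_next$r2 - fit$r2,
         curve = curve),
    class = "critical_count_fit"
  )
}

#' @export
print.critical_count_fit <- function(x, ...) {
  cat(sprintf("Degree-%d fit of critical count vs sequencing depth\n", x$degree))
  cat("  coefficients:", paste(sprintf("%.4g", x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.6f (degree %d would add %.2g)\n",
              x$r_squared, x$degree + 1L, x$delta_r_squared))
  invisible(x)
}
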