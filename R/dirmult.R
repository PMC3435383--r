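# Dirichlet-multinomial joint model: likelihood, method-of-moments
# over-dispersion estimator, maximum-likelihood fit.

# --- numerically stable ascending log-gamma / digamma differences ---------
# lgamma(a + k) - lgamma(a) evaluated directly loses all precision when a is
# huge (catastrophic cancellation of two ~a*log(a) terms), which is exactly
# the regime reached near the multinomial (theta -> 0) limit. For large a the
# difference is computed as sum(log(a + j)), j = 0..k-1, which is exact at
# the depths handled here (k <= ~1e5).

.big_arg <- 1e7

.lgamma_inc <- function(a, k) {
  n <- max(length(a), length(k))
  a <- rep_len(as.numeric(a), n)
  k <- rep_len(as.numeric(k), n)
  out <- lgamma(a + k) - lgamma(a)
  big <- which(a > .big_arg & k > 0)
  for (j in big) {
    out[j] <- sum(log(a[j] + seq_len(k[j]) - 1))
  }
  out
}

.digamma_inc <- function(a, k) {
  n <- max(length(a), length(k))
  a <- rep_len(as.numeric(a), n)
  k <- rep_len(as.numeric(k), n)
  out <- digamma(a + k) - digamma(a)
  big <- which(a > .big_arg & k > 0)
  for (j in big) {
    out[j] <- sum(1 / (a[j] + seq_len(k[j]) - 1))
  }
  out
}

# --- count matrix validation ----------------------------------------------

.check_counts <- function(counts, min_samples = 1L) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (samples in rows, OTUs in columns)")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("'counts' must contain non-negative integers")
  }
  if (nrow(counts) < min_samples) {
    stop(sprintf("at least %d sample rows are required", min_samples))
  }
  if (any(rowSums(counts) < 1)) {
    stop("every sample row must have depth (row sum) >= 1")
  }
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    stop("duplicated OTU ids in 'counts' column names")
  }
  invisible(TRUE)
}

# core log-likelihood without the multinomial coefficient (constant in the
# parameters); `a` is the concentration vector
.dm_ll_core <- function(a, counts, depths) {
  A <- sum(a)
  s <- nrow(counts)
  -sum(.lgamma_inc(A, depths)) +
    sum(.lgamma_inc(rep(a, each = s), as.vector(counts)))
}

.dm_ll_core_grad <- function(a, counts, depths) {
  A <- sum(a)
  s <- nrow(counts)
  per <- matrix(.digamma_inc(rep(a, each = s), as.vector(counts)), nrow = s)
  -sum(.digamma_inc(A, depths)) + colSums(per)
}

#' Dirichlet-multinomial log-likelihood
#'
#' Joint log-probability of a matrix of replicate OTU count vectors
#' (samples in rows) under a Dirichlet-multinomial model, i.e. the sum of
#' independent per-sample log pmfs including the multinomial coefficient.
#'
#' @param counts Integer matrix, samples in rows, OTUs in columns. If both
#'   the matrix columns and the parameters carry OTU names they are aligned
#'   by name.
#' @param params A [dm_params] object with one concentration per OTU column.
#' @return A single finite log-likelihood value.
#' @examples
#' x <- rbind(c(2, 1))
#' dm_log_likelihood(x, dm_params(c(1, 1)))  # log(1/3)
#' @export
dm_log_likelihood <- function(counts, params) {
  if (!inherits(params, "dm_params")) {
    stop("'params' must be a dm_params object")
  }
  .check_counts(counts)
  a <- params$concentration
  if (ncol(counts) != length(a)) {
    stop(sprintf("dimension mismatch: %d OTU columns vs %d concentrations",
                 ncol(counts), length(a)))
  }
  if (!is.null(colnames(counts)) && !is.null(names(a))) {
    if (!setequal(colnames(counts), names(a))) {
      stop("OTU ids of 'counts' and 'params' differ")
    }
    counts <- counts[, names(a), drop = FALSE]
  }
  depths <- rowSums(counts)
  coeff <- sum(lgamma(depths + 1)) - sum(lgamma(counts + 1))
  coeff + .dm_ll_core(a, counts, depths)
}

#' Method-of-moments over-dispersion estimate
#'
#' Pooled moment estimator of the Dirichlet-multinomial over-dispersion
#' `theta` from a set of replicate samples (e.g. the three DNA extractions
#' of one fluid). Each read is treated as one categorical observation;
#' per-OTU between-replicate and within-replicate mean squares are combined
#' across OTUs as
#' `theta = sum(MSP - MSG) / sum(MSP + (n_c - 1) * MSG)`,
#' with `n_c` the usual effective sample size for unequal depths. `theta`
#' is zero when replicate variation is explained by multinomial resampling
#' of fixed proportions and grows as replicates diverge; negative moment
#' estimates (sampling noise) are truncated to 0.
#'
#' The standard error is a delete-one jackknife over OTU columns.
#'
#' @param counts Integer matrix of replicates (rows) by OTUs (columns); at
#'   least 2 rows. Columns with zero total count are ignored.
#' @param se Compute the jackknife standard error? (default `TRUE`)
#' @return An object of class `"theta_estimate"`: a list with elements
#'   `theta`, `standard_error`, `n_samples`, `depths`, `n_otus`.
#' @examples
#' set.seed(1)
#' dm <- dm_params(c(60, 25, 10, 5))
#' x <- sample_dm(dm, depths = rep(2000, 3))
#' estimate_theta_mom(x)
#' @export
estimate_theta_mom <- function(counts, se = TRUE) {
  .check_counts(counts, min_samples = 2L)
  if (nrow(counts) < 2L) {
    stop("theta is unidentifiable from a single sample; need >= 2 replicates")
  }
  x <- counts[, colSums(counts) > 0, drop = FALSE]
  r <- nrow(x)
  n <- rowSums(x)
  sn <- sum(n)
  p <- x / n
  pbar <- colSums(x) / sn
  msp <- colSums(n * (p - rep(pbar, each = r))^2) / (r - 1)
  msg <- colSums(n * p * (1 - p)) / (sn - r)
  nc <- (sn - sum(n^2) / sn) / (r - 1)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  clamp <- function(v) min(max(v, 0), 1 - 1e-12)
  theta <- clamp(sum(num) / sum(den))
  std_err <- NA_real_
  if (se && ncol(x) > 2L) {
    loo <- vapply(seq_len(ncol(x)), function(i) {
      d <- sum(den) - den[i]
      if (d <= 0) return(NA_real_)
      clamp((sum(num) - num[i]) / d)
    }, 0)
    loo <- loo[!is.na(loo)]
    k <- length(loo)
    if (k > 1L) {
      std_err <- sqrt((k - 1) / k * sum((loo - mean(loo))^2))
    }
  }
  structure(
    list(theta = theta, standard_error = std_err, n_samples = r,
         depths = n, n_otus = ncol(x)),
    class = "theta_estimate"
  )
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("Over-dispersion estimate (method of moments): theta = %.4g\n",
              x$theta))
  if (!is.na(x$standard_error)) {
    cat(sprintf("  jackknife SE = %.3g (over %d OTUs)\n",
                x$standard_error, x$n_otus))
  }
  cat(sprintf("  %d replicates, depths %s\n", x$n_samples,
              paste(x$depths, collapse = ", ")))
  invisible(x)
}

#' Maximum-likelihood Dirichlet-multinomial fit
#'
#' Fits the full concentration vector by numerical optimization of the
#' joint likelihood over all sample rows. The optimizer works on
#' log-concentrations (a smooth unconstrained parameterization, box-bounded
#' far from the data scale purely as a numerical safeguard), starting from
#' the pooled observed proportions scaled by the method-of-moments total
#' `A = (1 - theta)/theta` (floored at 10, capped at 1e9 when the moment
#' estimate truncates to 0). Convergence is declared at a relative
#' log-likelihood change of `reltol`.
#'
#' OTU columns with zero total count contribute nothing to the likelihood
#' and are dropped before fitting; the returned concentrations cover the
#' retained columns (named when the input has column names).
#'
#' @param counts Integer matrix of samples (rows) by OTUs (columns); at
#'   least 2 rows and 2 OTU columns with nonzero totals.
#' @param init Optional starting concentrations: a numeric vector over all
#'   OTU columns of `counts` (entries for dropped all-zero columns are
#'   ignored). Defaults to the method-of-moments initialization.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum optimizer iterations; exceeding it raises an error
#'   of class `"balenrich_mle_error"` carrying the best-so-far parameters in
#'   its `params` field.
#' @return A [dm_params] object with attributes `logLik` (full
#'   log-likelihood of the fit), `theta_mom` (the moment initialization)
#'   and `convergence` (the `optim` code).
#' @examples
#' set.seed(1)
#' truth <- dm_params(c(300, 150, 50, 30))
#' x <- sample_dm(truth, depths = rep(5000, 6))
#' fit <- fit_dm_mle(x)
#' dm_theta(fit)
#' @export
fit_dm_mle <- function(counts, init = NULL, reltol = 1e-8, maxit = 500L) {
  .check_counts(counts, min_samples = 2L)
  keep <- colSums(counts) > 0
  if (sum(keep) < 2L) {
    stop("need at least 2 OTUs with nonzero total count")
  }
  x <- counts[, keep, drop = FALSE]
  depths <- rowSums(x)

  theta0 <- estimate_theta_mom(x, se = FALSE)$theta
  if (is.null(init)) {
    a_total <- if (theta0 > 0) (1 - theta0) / theta0 else Inf
    a_total <- min(max(a_total, 10), 1e9)
    p0 <- colSums(x) / sum(x)
    w0 <- log(p0 * a_total)
  } else {
    if (length(init) != ncol(counts) || any(init <= 0)) {
      stop("'init' must give a positive concentration per OTU column")
    }
    w0 <- log(init[keep])
  }

  lo <- log(1e-10)
  hi <- log(1e10)
  w0 <- pmin(pmax(w0, lo), hi)

  fn <- function(w) -.dm_ll_core(exp(w), x, depths)
  gr <- function(w) -.dm_ll_core_grad(exp(w), x, depths) * exp(w)

  opt <- optim(w0, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = maxit,
                              factr = reltol / .Machine$double.eps))
  a_hat <- exp(opt$par)
  if (opt$value > fn(w0) + 1e-8) {
    # line-search safeguard: never return worse than the initialization
    a_hat <- exp(w0)
    opt$value <- fn(w0)
  }
  params <- dm_params(a_hat, otu_ids = colnames(x))
  attr(params, "logLik") <- dm_log_likelihood(x, params)
  attr(params, "theta_mom") <- theta0
  attr(params, "convergence") <- opt$convergence
  if (opt$convergence == 1L) {
    cond <- structure(
      class = c("balenrich_mle_error", "error", "condition"),
      list(message = sprintf(
             "Dirichlet-multinomial MLE did not converge in %d iterations (best log-likelihood %.6g)",
             maxit, -opt$value),
           call = sys.call(-1), params = params)
    )
    stop(cond)
  }
  params
}
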