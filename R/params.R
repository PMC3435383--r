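#' Beta-binomial shape parameters
#'
#' Container for the two shape parameters of a beta-binomial distribution.
#' The shapes control the expected OTU proportion, `a/(a+b)`, and the
#' over-dispersion `theta = 1/(a+b+1)`: `theta = 0` is the binomial limit
#' (no extra variability between replicate extractions), larger `theta`
#' means more dissimilar replicates.
#'
#' @param a,b Positive shape parameters.
#' @return An object of class `"bb_params"` with elements `a` and `b`.
#' @seealso [bb_from_mean_theta()] to construct from (proportion, theta);
#'   [bb_log_pmf()], [bb_prob_zero()], [bb_upper_tail()].
#' @examples
#' p <- bb_params(1.5, 498.5)
#' bb_mean(p)
#' bb_theta(p)
#' @export
bb_params <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("beta-binomial shape parameters 'a' and 'b' must be finite and > 0")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "bb_params")
}

#' @param p Expected proportion, in (0, 1).
#' @param theta Over-dispersion, in \[0, 1). `theta = 0` gives the binomial
#'   limit, represented internally by a very large total concentration.
#' @rdname bb_params
#' @export
bb_from_mean_theta <- function(p, theta) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("'p' must be a single proportion in (0, 1)")
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1) {
    stop("'theta' must be a single value in [0, 1)")
  }
  ab <- if (theta == 0) .bb_binomial_limit_total else (1 - theta) / theta
  bb_params(p * ab, (1 - p) * ab)
}

# Total concentration standing in for theta = 0. Large enough that the
# beta-binomial is numerically binomial at the depths handled here (<= 1e5).
.bb_binomial_limit_total <- 1e12

#' @rdname bb_params
#' @param params A `"bb_params"` object.
#' @export
bb_mean <- function(params) params$a / (params$a + params$b)

#' @rdname bb_params
#' @export
bb_theta <- function(params) 1 / (params$a + params$b + 1)

#' @export
print.bb_params <- function(x, ...) {
  cat(sprintf("Beta-binomial parameters: a = %.6g, b = %.6g\n", x$a, x$b))
  cat(sprintf("  mean proportion p = %.6g, over-dispersion theta = %.6g\n",
              bb_mean(x), bb_theta(x)))
  invisible(x)
}

#' Dirichlet-multinomial parameters
#'
#' Concentration vector of a Dirichlet-multinomial distribution over K OTUs.
#' The total concentration `A = sum(concentration)` encodes the common
#' over-dispersion `theta = 1/(A+1)`; the normalized concentrations are the
#' expected OTU proportions. The marginal distribution of OTU `i` is
#' beta-binomial with shapes `(concentration[i], A - concentration[i])`.
#'
#' @param concentration Vector of K strictly positive reals, optionally
#'   named by OTU id.
#' @param otu_ids Optional character vector of OTU identifiers (defaults to
#'   the names of `concentration`).
#' @return An object of class `"dm_params"`.
#' @seealso [dm_marginal()], [dm_log_likelihood()], [fit_dm_mle()],
#'   [sample_dm()].
#' @examples
#' dm <- dm_params(c(a = 30, b = 15, c = 5))
#' dm_proportions(dm)
#' dm_theta(dm)
#' @export
dm_params <- function(concentration, otu_ids = names(concentration)) {
  if (!is.numeric(concentration) || length(concentration) < 2L) {
    stop("'concentration' must be a numeric vector of length >= 2")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("all concentrations must be finite and strictly positive")
  }
  conc <- as.numeric(concentration)
  if (!is.null(otu_ids)) {
    if (length(otu_ids) != length(conc)) {
      stop("'otu_ids' must match the length of 'concentration'")
    }
    names(conc) <- otu_ids
  }
  structure(list(concentration = conc), class = "dm_params")
}

#' @rdname dm_params
#' @param params A `"dm_params"` object.
#' @export
dm_total <- function(params) sum(params$concentration)

#' @rdname dm_params
#' @export
dm_proportions <- function(params) params$concentration / dm_total(params)

#' @rdname dm_params
#' @export
dm_theta <- function(params) 1 / (dm_total(params) + 1)

#' Marginal beta-binomial distribution of one OTU
#'
#' Under the Dirichlet-multinomial joint model the count of OTU `i` in a
#' sample of given depth is beta-binomial with shapes
#' `(concentration[i], A - concentration[i])`. This marginal is the null
#' distribution used by the outlier tests.
#'
#' @param params A `"dm_params"` object.
#' @param i OTU index or name.
#' @return A `"bb_params"` object.
#' @export
dm_marginal <- function(params, i) {
  a <- params$concentration[[i]]
  bb_params(a, dm_total(params) - a)
}

#' @export
print.dm_params <- function(x, ...) {
  k <- length(x$concentration)
  cat(sprintf("Dirichlet-multinomial parameters over %d OTUs\n", k))
  cat(sprintf("  total concentration A = %.6g, theta = %.6g\n",
              dm_total(x), dm_theta(x)))
  props <- sort(dm_proportions(x), decreasing = TRUE)
  show <- head(props, 5L)
  if (is.null(names(show))) names(show) <- seq_along(show)
  cat("  top proportions:",
      paste(sprintf("%s=%.3g", names(show), show), collapse = ", "), "\n")
  invisible(x)
}
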