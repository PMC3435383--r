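# Single-sided outlier test: one BAL sample against one OW sample.

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment of p-values to control the false discovery rate, the
#' correction used throughout the outlier analyses (FDR 5% by default at
#' the calling level).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, each at least its input p-value, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) {
    return(numeric(0))
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

.three_tier_call <- function(significant_raw, significant_fdr) {
  factor(ifelse(significant_fdr, "significant (FDR)",
                ifelse(significant_raw, "significant (unadjusted)",
                       "not significant")),
         levels = c("not significant", "significant (unadjusted)",
                    "significant (FDR)"))
}

.match_taxonomy <- function(otu_ids, taxonomy) {
  if (is.null(taxonomy)) {
    return(rep(NA_character_, length(otu_ids)))
  }
  if (!is.null(names(taxonomy))) {
    return(as.character(unname(taxonomy[otu_ids])))
  }
  if (length(taxonomy) != length(otu_ids)) {
    stop("unnamed 'taxonomy' must be parallel to the OTU index")
  }
  as.character(taxonomy)
}

#' Pairwise single-sided outlier test for lung enrichment
#'
#' Tests every OTU for enrichment in one BAL sample relative to one OW
#' sample. A Dirichlet-multinomial model is fitted by maximum likelihood to
#' the two count vectors treated as two observations; for each OTU the
#' fitted concentrations give a marginal beta-binomial null
#' `BB(a_i, A - a_i)` at the BAL depth, representing the count distribution
#' if the OTU is not enriched in BAL. The p-value is the inclusive upper
#' tail `P(X >= x_obs)` -- one-sided, so only enrichment toward lung is
#' flagged -- followed by Benjamini-Hochberg adjustment across OTUs.
#'
#' The tested OTU is not removed from the null fit: a genuinely enriched
#' OTU inflates the estimated over-dispersion and thereby raises the bar
#' for its own detection, making the test conservative.
#'
#' @param bal,ow Integer count vectors over a shared OTU index (aligned by
#'   names when both are named).
#' @param alpha Significance level for the call flags (default 0.05, i.e.
#'   FDR 5%).
#' @param otu_ids Optional OTU identifiers (defaults to names of `bal`).
#' @param taxonomy Optional taxonomy strings, named by OTU id or parallel
#'   to `otu_ids`.
#' @return A data frame of class `"outlier_result"`, one row per OTU with
#'   nonzero total count: `otu_id`, `taxonomy`, `bal_count`, `ow_count`,
#'   `bal_proportion`, `ow_proportion`, `fold_change` (BAL/OW proportions;
#'   `Inf` when the OTU is absent from OW), `p_value`, `q_value`,
#'   `significant_raw`, `significant_fdr`, `call`. Attributes record
#'   `alpha`, the two depths, and the fitted `theta`.
#' @examples
#' set.seed(1)
#' design <- synthetic_design(n_otus = 40, enriched_otus = 10,
#'                            fold_changes = 20, seed = 1)
#' d <- generate_paired_dataset(design)
#' res <- pairwise_outlier_test(d$bal[1, ], d$ow[1, ])
#' head(res[order(res$p_value), ])
#' @export
pairwise_outlier_test <- function(bal, ow, alpha = 0.05, otu_ids = NULL,
                                  taxonomy = NULL) {
  if (!is.numeric(bal) || !is.numeric(ow)) {
    stop("'bal' and 'ow' must be numeric count vectors")
  }
  if (!is.null(names(bal)) && !is.null(names(ow))) {
    if (!setequal(names(bal), names(ow))) {
      stop("'bal' and 'ow' must share the same OTU index")
    }
    ow <- ow[names(bal)]
  } else if (length(bal) != length(ow)) {
    stop("'bal' and 'ow' must share the same OTU index")
  }
  if (is.null(otu_ids)) {
    otu_ids <- if (!is.null(names(bal))) names(bal) else
      sprintf("OTU_%d", seq_along(bal))
  }
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single level in (0, 1)")
  }

  counts <- rbind(BAL = as.numeric(bal), OW = as.numeric(ow))
  colnames(counts) <- otu_ids
  .check_counts(counts, min_samples = 2L)
  keep <- colSums(counts) > 0
  if (sum(keep) < 2L) {
    stop("need at least 2 OTUs with nonzero total count")
  }

  fit <- fit_dm_mle(counts)
  conc <- fit$concentration
  total <- dm_total(fit)
  depth_bal <- sum(bal)
  depth_ow <- sum(ow)

  kept_ids <- colnames(counts)[keep]
  tax <- .match_taxonomy(otu_ids, taxonomy)[keep]
  x_bal <- counts["BAL", keep]
  x_ow <- counts["OW", keep]
  p <- vapply(seq_along(kept_ids), function(i) {
    bb_upper_tail(x_bal[i], depth_bal, bb_params(conc[i], total - conc[i]))
  }, 0)
  q <- bh_adjust(p)

  bal_prop <- x_bal / depth_bal
  ow_prop <- x_ow / depth_ow
  fold <- ifelse(ow_prop > 0, bal_prop / ow_prop, Inf)

  out <- data.frame(
    otu_id = kept_ids,
    taxonomy = tax,
    bal_count = as.integer(x_bal),
    ow_count = as.integer(x_ow),
    bal_proportion = bal_prop,
    ow_proportion = ow_prop,
    fold_change = fold,
    p_value = p,
    q_value = q,
    significant_raw = p <= alpha,
    significant_fdr = q <= alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$call <- .three_tier_call(out$significant_raw, out$significant_fdr)
  class(out) <- c("outlier_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "depth_bal") <- depth_bal
  attr(out, "depth_ow") <- depth_ow
  attr(out, "theta") <- dm_theta(fit)
  out
}

#' Replicate concordance table
#'
#' Compares OTU proportions between two replicate extractions of the same
#' fluid, flagging OTUs observed in exactly one replicate (the points
#' abutting the axes of a bivariate log-log replicate plot). In
#' well-behaved replicate data every single-replicate OTU is rare --
#' below the critical proportion for the sample's depth.
#'
#' @param rep_a,rep_b Integer count vectors over a shared OTU index.
#' @param otu_ids Optional OTU identifiers.
#' @return A data frame of class `"concordance"` with columns `otu_id`,
#'   `count_a`, `count_b`, `proportion_a`, `proportion_b`, `unique_to`
#'   (`"a"`, `"b"` or `NA`); attributes `n_unique_a`, `n_unique_b` and
#'   `max_unique_proportion` summarize the single-replicate OTUs.
#' @export
replicate_concordance <- function(rep_a, rep_b, otu_ids = NULL) {
  if (!is.null(names(rep_a)) && !is.null(names(rep_b))) {
    if (!setequal(names(rep_a), names(rep_b))) {
      stop("'rep_a' and 'rep_b' must share the same OTU index")
    }
    rep_b <- rep_b[names(rep_a)]
  } else if (length(rep_a) != length(rep_b)) {
    stop("'rep_a' and 'rep_b' must share the same OTU index")
  }
  if (is.null(otu_ids)) {
    otu_ids <- if (!is.null(names(rep_a))) names(rep_a) else
      sprintf("OTU_%d", seq_along(rep_a))
  }
  pa <- rep_a / sum(rep_a)
  pb <- rep_b / sum(rep_b)
  unique_to <- ifelse(rep_a > 0 & rep_b == 0, "a",
                      ifelse(rep_b > 0 & rep_a == 0, "b", NA_character_))
  out <- data.frame(
    otu_id = otu_ids,
    count_a = as.integer(rep_a),
    count_b = as.integer(rep_b),
    proportion_a = as.numeric(pa),
    proportion_b = as.numeric(pb),
    unique_to = unique_to,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("concordance", "data.frame")
  uniq <- !is.na(unique_to)
  attr(out, "n_unique_a") <- sum(unique_to == "a", na.rm = TRUE)
  attr(out, "n_unique_b") <- sum(unique_to == "b", na.rm = TRUE)
  attr(out, "max_unique_proportion") <-
    if (any(uniq)) max(pmax(pa, pb)[uniq]) else 0
  out
}
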