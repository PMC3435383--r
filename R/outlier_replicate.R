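# Pooled-replicate outlier analysis: DM fit across all BAL and OW
# replicates of a subject, mean-BAL-proportion statistic, Monte-Carlo null.

.align_replicate_matrices <- function(bal, ow) {
  if (!is.matrix(bal)) bal <- matrix(bal, nrow = 1, dimnames = list(NULL, names(bal)))
  if (!is.matrix(ow)) ow <- matrix(ow, nrow = 1, dimnames = list(NULL, names(ow)))
  if (!is.null(colnames(bal)) && !is.null(colnames(ow))) {
    if (!setequal(colnames(bal), colnames(ow))) {
      stop("'bal' and 'ow' must share the same OTU index")
    }
    ow <- ow[, colnames(bal), drop = FALSE]
  } else if (ncol(bal) != ncol(ow)) {
    stop("'bal' and 'ow' must share the same OTU index")
  }
  list(bal = bal, ow = ow)
}

#' Pooled-replicate outlier test for lung enrichment
#'
#' Tests each OTU for enrichment in BAL using all replicates of both
#' fluids. The Dirichlet-multinomial parameters are estimated by maximum
#' likelihood treating every BAL and OW replicate as a separate
#' observation. The test statistic for an OTU is the unweighted arithmetic
#' mean of its per-BAL-replicate proportions. Its null distribution is
#' simulated: each trial draws one count per BAL replicate (at that
#' replicate's observed depth) from the marginal beta-binomial
#' `BB(a_i, A - a_i)`, converts to proportions, and averages; the one-sided
#' Monte-Carlo p-value uses the add-one correction
#' `(1 + #\{trial >= observed\}) / (1 + n_trials)` with ties counted as
#' exceedances, so p-values are floored at `1/(n_trials + 1)`
#' (`1/10001 < 0.0001` at the default 10,000 trials). Benjamini-Hochberg
#' adjustment is applied across OTUs.
#'
#' Each OTU uses its own random substream derived deterministically from
#' the master seed, so results are reproducible and independent of OTU
#' iteration order.
#'
#' @param bal,ow Integer matrices of replicates (rows) by OTUs (columns)
#'   over a shared OTU index; vectors are treated as single replicates.
#' @param n_trials Number of Monte-Carlo null trials (default 10,000;
#'   at least 1,000 for a reported analysis).
#' @param alpha Significance level for call flags (default 0.05).
#' @param seed Master seed for the Monte-Carlo stream (required).
#' @return A data frame of class `"outlier_result"` (see
#'   [pairwise_outlier_test()]) whose proportions are means over
#'   replicates, with attributes `n_trials`, `seed`, `p_floor`, `alpha`
#'   and the fitted `theta`.
#' @examples
#' set.seed(1)
#' design <- synthetic_design(n_otus = 30, enriched_otus = 5,
#'                            fold_changes = 10, seed = 7)
#' d <- generate_paired_dataset(design)
#' res <- replicate_outlier_test(d$bal, d$ow, n_trials = 2000, seed = 11)
#' res[res$significant_fdr, c("otu_id", "fold_change", "p_value", "q_value")]
#' @export
replicate_outlier_test <- function(bal, ow, n_trials = 10000L, alpha = 0.05,
                                   seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("a single integer 'seed' is required for a reproducible Monte-Carlo null")
  }
  if (n_trials < 1L) {
    stop("'n_trials' must be >= 1")
  }
  if (n_trials < 1000L) {
    warning("fewer than 1000 Monte-Carlo trials gives a coarse p-value floor")
  }
  m <- .align_replicate_matrices(bal, ow)
  counts <- rbind(m$bal, m$ow)
  rownames(counts) <- c(sprintf("BAL_%d", seq_len(nrow(m$bal))),
                        sprintf("OW_%d", seq_len(nrow(m$ow))))
  .check_counts(counts, min_samples = 2L)
  keep <- colSums(counts) > 0
  if (sum(keep) < 2L) {
    stop("need at least 2 OTUs with nonzero total count")
  }

  fit <- fit_dm_mle(counts)
  conc <- fit$concentration
  total <- dm_total(fit)

  depths_bal <- rowSums(m$bal)
  depths_ow <- rowSums(m$ow)
  r_bal <- nrow(m$bal)
  kept_ids <- if (!is.null(colnames(counts))) colnames(counts)[keep] else
    sprintf("OTU_%d", which(keep))

  prop_bal <- sweep(m$bal[, keep, drop = FALSE], 1, depths_bal, "/")
  prop_ow <- sweep(m$ow[, keep, drop = FALSE], 1, depths_ow, "/")
  obs <- colMeans(prop_bal)
  ow_mean <- colMeans(prop_ow)

  # per-OTU substreams, deterministic in OTU position
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(kept_ids))

  p <- vapply(seq_along(kept_ids), function(i) {
    set.seed(sub_seeds[i])
    a <- conc[i]
    b <- total - a
    trial_means <- rowMeans(vapply(seq_len(r_bal), function(r) {
      rbinom(n_trials, depths_bal[r], rbeta(n_trials, a, b)) / depths_bal[r]
    }, numeric(n_trials)))
    (1 + sum(trial_means >= obs[i])) / (1 + n_trials)
  }, 0)
  q <- bh_adjust(p)

  fold <- ifelse(ow_mean > 0, obs / ow_mean, Inf)
  x_bal_tot <- colSums(m$bal[, keep, drop = FALSE])
  x_ow_tot <- colSums(m$ow[, keep, drop = FALSE])

  out <- data.frame(
    otu_id = kept_ids,
    taxonomy = NA_character_,
    bal_count = as.integer(x_bal_tot),
    ow_count = as.integer(x_ow_tot),
    bal_proportion = unname(obs),
    ow_proportion = unname(ow_mean),
    fold_change = unname(fold),
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
  attr(out, "n_trials") <- as.integer(n_trials)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "p_floor") <- 1 / (n_trials + 1)
  attr(out, "theta") <- dm_theta(fit)
  attr(out, "depths_bal") <- depths_bal
  attr(out, "depths_ow") <- depths_ow
  out
}

#' Compare pairwise calls with the pooled-replicate analysis
#'
#' Runs every BAL-replicate x OW-replicate pairwise outlier test alongside
#' the pooled-replicate test and tallies, per OTU, how often the pairwise
#' analyses call it (with and without FDR adjustment), mirroring a
#' per-subject replicate summary. OTUs called in at least one unadjusted
#' pairwise comparison but not significant in the replicate analysis are
#' listed separately: these are the calls that replication fails to
#' substantiate.
#'
#' @inheritParams replicate_outlier_test
#' @return A data frame of class `"outlier_comparison"`: the
#'   pooled-replicate results plus `n_pairwise_fdr` and `n_pairwise_raw`
#'   tallies (maximum = number of pairwise comparisons), ordered by
#'   q-value. Attributes: `n_pairs`, `additional_otus` (called pairwise
#'   unadjusted but absent from the replicate-significant set) and
#'   `n_additional`.
#' @export
compare_pairwise_vs_replicate <- function(bal, ow, n_trials = 10000L,
                                          alpha = 0.05, seed) {
  m <- .align_replicate_matrices(bal, ow)
  rep_res <- replicate_outlier_test(m$bal, m$ow, n_trials = n_trials,
                                    alpha = alpha, seed = seed)
  n_fdr <- setNames(integer(nrow(rep_res)), rep_res$otu_id)
  n_raw <- n_fdr
  raw_called <- character(0)
  for (i in seq_len(nrow(m$bal))) {
    for (j in seq_len(nrow(m$ow))) {
      pw <- pairwise_outlier_test(m$bal[i, ], m$ow[j, ], alpha = alpha,
                                  otu_ids = colnames(m$bal))
      hit_fdr <- pw$otu_id[pw$significant_fdr]
      hit_raw <- pw$otu_id[pw$significant_raw]
      known <- intersect(hit_fdr, names(n_fdr))
      n_fdr[known] <- n_fdr[known] + 1L
      known <- intersect(hit_raw, names(n_raw))
      n_raw[known] <- n_raw[known] + 1L
      raw_called <- union(raw_called, hit_raw)
    }
  }
  out <- rep_res
  out$n_pairwise_fdr <- unname(n_fdr[out$otu_id])
  out$n_pairwise_raw <- unname(n_raw[out$otu_id])
  out <- out[order(out$q_value, out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("outlier_comparison", "outlier_result", "data.frame")
  for (at in c("alpha", "n_trials", "seed", "p_floor", "theta")) {
    attr(out, at) <- attr(rep_res, at)
  }
  additional <- setdiff(raw_called, out$otu_id[out$significant_fdr])
  attr(out, "n_pairs") <- nrow(m$bal) * nrow(m$ow)
  attr(out, "additional_otus") <- additional
  attr(out, "n_additional") <- length(additional)
  out
}
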