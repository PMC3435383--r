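# Pooled-replicate outlier test with Monte-Carlo null, and the comparison
# against pairwise calls.

make_planted <- function(seed, n_otus = 40, fold = 300, target = NULL,
                         depth = 5000L, reps = 3L) {
  base <- rank_abundance_baseline(n_otus, ratio = 0.85)
  if (is.null(target)) target <- which.min(abs(base - 0.002))
  des <- synthetic_design(
    n_otus = n_otus, baseline = base, theta = 0.003,
    depths_bal = rep(depth, reps), depths_ow = rep(depth, reps),
    enriched_otus = target, fold_changes = fold, seed = seed)
  list(data = generate_paired_dataset(des), target = names(base)[target])
}

test_that("the Monte-Carlo p-value stream is seed-reproducible and floored", {
  pl <- make_planted(seed = 101)
  r1 <- replicate_outlier_test(pl$data$bal, pl$data$ow, n_trials = 2000,
                               seed = 77)
  r2 <- replicate_outlier_test(pl$data$bal, pl$data$ow, n_trials = 2000,
                               seed = 77)
  expect_identical(r1, r2)
  r3 <- replicate_outlier_test(pl$data$bal, pl$data$ow, n_trials = 2000,
                               seed = 78)
  expect_false(identical(r1$p_value, r3$p_value))

  floor_p <- 1 / 2001
  expect_true(all(r1$p_value >= floor_p))
  expect_true(all(r1$p_value <= 1))
  expect_equal(attr(r1, "p_floor"), floor_p)
  expect_error(replicate_outlier_test(pl$data$bal, pl$data$ow,
                                      n_trials = 2000),
               "seed")
})

test_that("an OTU more extreme than every null trial sits exactly at the
          p-value floor and prints below it", {
  pl <- make_planted(seed = 102, n_otus = 100, fold = 400)
  res <- replicate_outlier_test(pl$data$bal, pl$data$ow, n_trials = 10000,
                                seed = 5)
  i <- match(pl$target, res$otu_id)
  expect_identical(res$p_value[i], 1 / 10001)
  expect_lt(res$p_value[i], 1e-4)
  expect_identical(format_p_value(res$p_value[i], 10000), "<0.0001")
  expect_true(res$significant_fdr[i])
})

test_that("Monte-Carlo p-values agree with the analytic tail for a single
          replicate", {
  set.seed(19)
  base <- rank_abundance_baseline(12, ratio = 0.7)
  dm <- dm_params(base * (1 - 0.005) / 0.005)
  pair <- sample_dm(dm, rep(3000, 2))
  bal <- pair[1, , drop = FALSE]
  ow <- pair[2, , drop = FALSE]

  n_trials <- 100000L
  mc <- replicate_outlier_test(bal, ow, n_trials = n_trials, seed = 13)
  an <- pairwise_outlier_test(pair[1, ], pair[2, ])
  an <- an[match(mc$otu_id, an$otu_id), ]
  for (i in seq_len(nrow(mc))) {
    se <- sqrt(an$p_value[i] * (1 - an$p_value[i]) / n_trials)
    expect_lt(abs(mc$p_value[i] - an$p_value[i]), 3 * se + 2 / n_trials)
  }
})

test_that("null calibration: pooled test keeps its level on same-distribution
          replicates", {
  set.seed(20)
  dm <- dm_params(rank_abundance_baseline(60) * (1 - 0.003) / 0.003)
  frac <- replicate(12, {
    x <- sample_dm(dm, rep(5000, 6))
    res <- replicate_outlier_test(x[1:3, ], x[4:6, ], n_trials = 1000,
                                  seed = sample.int(1e6, 1))
    c(mean(res$p_value <= 0.05), any(res$significant_fdr))
  })
  expect_lt(mean(frac[1, ]), 0.10)
  expect_lt(mean(frac[2, ]), 0.35)
})

test_that("pairwise tallies and the pooled test agree on a strongly planted
          OTU", {
  pl <- make_planted(seed = 103, n_otus = 60, fold = 300)
  cmp <- compare_pairwise_vs_replicate(pl$data$bal, pl$data$ow,
                                       n_trials = 2000, seed = 7)
  i <- match(pl$target, cmp$otu_id)
  expect_identical(cmp$n_pairwise_fdr[i], 9L)
  expect_identical(cmp$n_pairwise_raw[i], 9L)
  expect_true(cmp$significant_fdr[i])
  expect_true(all(cmp$n_pairwise_raw <= attr(cmp, "n_pairs")))
  expect_false(pl$target %in% attr(cmp, "additional_otus"))
})

test_that("with one replicate per fluid the tally degenerates to the pairwise
          result", {
  pl <- make_planted(seed = 104, reps = 1L)
  cmp <- compare_pairwise_vs_replicate(pl$data$bal, pl$data$ow,
                                       n_trials = 2000, seed = 3)
  expect_identical(attr(cmp, "n_pairs"), 1L)
  pw <- pairwise_outlier_test(pl$data$bal[1, ], pl$data$ow[1, ])
  pw <- pw[match(cmp$otu_id, pw$otu_id), ]
  expect_identical(cmp$n_pairwise_raw, as.integer(pw$significant_raw))
  expect_identical(cmp$n_pairwise_fdr, as.integer(pw$significant_fdr))
})

test_that("replication improves power over a single pairwise comparison", {
  set.seed(22)
  base <- rank_abundance_baseline(40, ratio = 0.85)
  target <- which.min(abs(base - 0.002))
  hits <- vapply(c(one = 1L, three = 3L), function(reps) {
    mean(replicate(10, {
      des <- synthetic_design(
        n_otus = 40, baseline = base, theta = 0.003,
        depths_bal = rep(5000L, reps), depths_ow = rep(5000L, reps),
        enriched_otus = target, fold_changes = 25,
        seed = sample.int(1e6, 1))
      d <- generate_paired_dataset(des)
      res <- replicate_outlier_test(d$bal, d$ow, n_trials = 1000,
                                    seed = sample.int(1e6, 1))
      res$q_value[match(names(base)[target], res$otu_id)] <= 0.05
    }))
  }, 0)
  expect_gte(hits[["three"]] + 0.2, hits[["one"]])
})
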