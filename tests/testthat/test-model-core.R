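# Beta-binomial and Dirichlet-multinomial probability functions, moment and
# maximum-likelihood estimation of the over-dispersion.

test_that("beta-binomial pmf matches closed forms and normalizes", {
  # a = b = 1 makes the beta-binomial uniform on 0..N
  expect_equal(bb_log_pmf(2, 10, bb_params(1, 1)), log(1 / 11))
  expect_equal(bb_prob_zero(100, bb_params(1, 1)), 1 / 101)
  expect_equal(bb_upper_tail(8, 10, bb_params(1, 1)), 3 / 11)

  # N = 1 is a Bernoulli draw with success probability a/(a+b)
  pars <- bb_params(2.3, 7.7)
  expect_equal(bb_log_pmf(0, 1, pars), log(7.7 / 10))
  expect_equal(bb_prob_zero(1, pars), 7.7 / 10)
  expect_equal(bb_upper_tail(1, 1, pars), 2.3 / 10)
  expect_identical(bb_upper_tail(0, 57, pars), 1)

  # direct beta-function oracle at small N
  expect_equal(exp(bb_log_pmf(0:12, 12, pars)),
               bb_pmf_direct(0:12, 12, pars$a, pars$b))

  set.seed(42)
  for (i in 1:20) {
    a <- exp(runif(1, -3, 3))
    b <- exp(runif(1, -3, 3))
    n <- sample(1:50, 1)
    p <- exp(bb_log_pmf(0:n, n, bb_params(a, b)))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    # inclusive tail + lower pmf mass is a partition of unity
    x <- sample(0:n, 1)
    lower <- if (x == 0) 0 else sum(p[seq_len(x)])
    expect_equal(bb_upper_tail(x, n, bb_params(a, b)) + lower, 1,
                 tolerance = 1e-10)
    # tail is non-increasing in x
    tails <- vapply(0:n, bb_upper_tail, 0, size = n,
                    params = bb_params(a, b))
    expect_true(all(diff(tails) <= 1e-12))
  }
})

test_that("beta-binomial approaches the binomial limit as theta -> 0", {
  set.seed(7)
  for (i in 1:10) {
    p <- runif(1, 0.001, 0.999)
    n <- sample(1:1000, 1)
    x <- rbinom(1, n, p)
    pars <- bb_from_mean_theta(p, 0)  # theta below 1e-6 internally
    expect_lt(abs(exp(bb_log_pmf(x, n, pars)) - dbinom(x, n, p)), 1e-6)
  }
})

test_that("domain violations raise errors", {
  pars <- bb_params(1, 2)
  expect_error(bb_log_pmf(5, 3, pars), "0 <= x <= size")
  expect_error(bb_log_pmf(-1, 3, pars), "0 <= x <= size")
  expect_error(bb_params(0, 1), "> 0")
  expect_error(bb_params(1, -2), "> 0")
  expect_error(bb_from_mean_theta(1.2, 0.01), "in \\(0, 1\\)")
  expect_error(bb_from_mean_theta(0.5, 1), "\\[0, 1\\)")
})

test_that("DM log-likelihood matches the Polya-urn enumeration oracle", {
  # (2,1) with unit concentrations: enumeration gives 1/3
  expect_equal(dm_log_likelihood(rbind(c(2, 1)), dm_params(c(1, 1))),
               log(urn_probability(c(2, 1), c(1, 1))))
  set.seed(11)
  for (i in 1:8) {
    k <- sample(2:3, 1)
    alpha <- exp(runif(k, -1, 2))
    counts <- rmultinom(1, sample(3:6, 1), rep(1 / k, k))[, 1]
    counts[1] <- counts[1] + 1  # depth >= 1 everywhere
    expect_equal(dm_log_likelihood(rbind(counts), dm_params(alpha)),
                 log(urn_probability(counts, alpha)),
                 tolerance = 1e-10)
  }
})

test_that("DM log-likelihood is additive, permutation-invariant, and has
          beta-binomial marginals at K = 2", {
  alpha <- c(4, 2, 1)
  row <- c(30, 12, 8)
  one <- dm_log_likelihood(rbind(row), dm_params(alpha))
  expect_equal(dm_log_likelihood(rbind(row, row), dm_params(alpha)), 2 * one)

  # single read lands in OTU i with probability pi_i
  expect_equal(dm_log_likelihood(rbind(c(0, 1, 0)), dm_params(alpha)),
               log(2 / 7))

  perm <- c(3, 1, 2)
  expect_equal(dm_log_likelihood(rbind(row[perm]), dm_params(alpha[perm])),
               one)

  set.seed(3)
  for (i in 1:10) {
    a <- exp(runif(2, -1, 3))
    n <- sample(5:200, 1)
    x <- rbinom(1, n, a[1] / sum(a))
    expect_equal(dm_log_likelihood(rbind(c(x, n - x)), dm_params(a)),
                 bb_log_pmf(x, n, bb_params(a[1], a[2])),
                 tolerance = 1e-10)
  }

  expect_error(dm_log_likelihood(rbind(c(1, 2, 3)), dm_params(c(1, 1))),
               "mismatch")
})

test_that("method-of-moments estimator recovers planted over-dispersion", {
  set.seed(21)
  # multinomial replicates: true theta = 0
  base <- rank_abundance_baseline(50, ratio = 0.85)
  est0 <- replicate(100, {
    x <- t(rmultinom(3, 5000, base))
    estimate_theta_mom(x, se = FALSE)$theta
  })
  expect_lt(mean(est0), 2e-4)

  # Dirichlet-multinomial with theta = 0.003
  dm <- dm_params(base * (1 - 0.003) / 0.003)
  est <- replicate(200, {
    x <- sample_dm(dm, rep(5000, 3))
    estimate_theta_mom(x, se = FALSE)$theta
  })
  expect_lt(abs(mean(est) / 0.003 - 1), 0.2)
})

test_that("moment estimator handles edge cases", {
  # maximally discordant replicates sit at the top of the theta range
  for (n in c(100L, 10000L)) {
    x <- rbind(c(n, 0L), c(0L, n))
    expect_gt(estimate_theta_mom(x, se = FALSE)$theta, 0.99)
  }
  # invariant to OTU column order; all-zero columns ignored
  set.seed(4)
  x <- sample_dm(dm_params(c(a = 5, b = 3, c = 2, d = 1)), rep(500, 3))
  x0 <- cbind(x, zero = 0L)
  perm <- sample(ncol(x))
  expect_equal(estimate_theta_mom(x, se = FALSE)$theta,
               estimate_theta_mom(x[, perm], se = FALSE)$theta)
  expect_equal(estimate_theta_mom(x, se = FALSE)$theta,
               estimate_theta_mom(x0, se = FALSE)$theta)
  # single replicate: unidentifiable
  expect_error(estimate_theta_mom(x[1, , drop = FALSE]), "2")
  # estimate object carries its inputs
  est <- estimate_theta_mom(x)
  expect_s3_class(est, "theta_estimate")
  expect_identical(est$n_samples, 3L)
  expect_identical(length(est$depths), 3L)
  expect_true(est$theta >= 0 && est$theta < 1)
})

test_that("maximum-likelihood fit recovers planted parameters", {
  set.seed(31)
  base <- rank_abundance_baseline(40, ratio = 0.8)
  theta <- 0.003
  dm_true <- dm_params(base * (1 - theta) / theta)
  x <- sample_dm(dm_true, rep(5000, 6))
  fit <- fit_dm_mle(x)

  # proportions recovered within simulation error for abundant OTUs
  pooled <- colSums(x) / sum(x)
  abundant <- base > 0.01
  expect_lt(max(abs(dm_proportions(fit)[names(base)[abundant]] -
                      base[abundant])), 0.05)
  # theta within 50% relative error
  expect_lt(abs(dm_theta(fit) / theta - 1), 0.5)
  # the fit cannot be worse than its moment initialization
  init <- pooled[colSums(x) > 0]
  init_par <- dm_params(init * (1 - 0.003) / 0.003)
  expect_gte(attr(fit, "logLik"), dm_log_likelihood(x[, colSums(x) > 0],
                                                    init_par))
})

test_that("maximum-likelihood fit is stable to the starting point", {
  set.seed(32)
  base <- rank_abundance_baseline(20, ratio = 0.8)
  x <- sample_dm(dm_params(base * 300), rep(2000, 4))
  fit <- fit_dm_mle(x, reltol = 1e-11)
  jitter <- exp(runif(ncol(x), -0.5, 0.5))
  fit2 <- fit_dm_mle(x, init = fit$concentration * jitter, reltol = 1e-11)
  expect_lt(abs(attr(fit, "logLik") - attr(fit2, "logLik")),
            1e-7 * abs(attr(fit, "logLik")))
})

test_that("identical replicates drive the fitted theta to zero", {
  row <- c(3000L, 1500L, 400L, 100L)
  x <- matrix(rep(row, 3), nrow = 3, byrow = TRUE)
  fit <- fit_dm_mle(x)
  expect_lt(dm_theta(fit), 1e-6)
})

test_that("moment and likelihood estimates track theta across its range", {
  # aggregate recovery across the plausible range; MLE on the pooled
  # 6-sample layout it is applied to in practice
  set.seed(33)
  base <- rank_abundance_baseline(60, ratio = 0.85)
  for (theta in c(0.003, 0.0325)) {
    dm <- dm_params(base * (1 - theta) / theta)
    mom <- numeric(30)
    mle <- numeric(30)
    for (r in 1:30) {
      x <- sample_dm(dm, rep(5000, 6))
      mom[r] <- estimate_theta_mom(x[1:3, ], se = FALSE)$theta
      mle[r] <- dm_theta(fit_dm_mle(x))
    }
    expect_lt(abs(mean(mom) / theta - 1), 0.35)
    expect_lt(abs(mean(mle) / theta - 1), 0.35)
    # MLE spread no worse than a single-fluid MoM (uses twice the data)
    expect_lte(sd(mle), sd(mom) * 1.5)
  }
})
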