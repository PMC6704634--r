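test_that("closed-form group fits match hand-computed estimates", {
  f <- fit_group(c(1, 3, 1, 3, 1, 5), c(0, 1, 0, 1, 0, 1))
  expect_equal(f$mu0, 1)
  expect_equal(f$mu1, 11 / 3)
  expect_equal(f$sigma2, 2 / 3)
  expect_equal(f$n_params, 3L)
  expect_false(f$degenerate)

  f0 <- fit_group(c(0, 1, 0, 1, 0, 1), rep(0, 6))
  expect_equal(f0$mu0, 0.5)
  expect_equal(f0$sigma2, 6 * 0.25 / 5)
  expect_equal(f0$n_params, 2L)
  expect_true(is.na(f0$mu1))

  fc <- fit_group(rep(2, 6), rep(0, 6))
  expect_equal(fc$mu0, 2)
  expect_equal(fc$sigma2, 0)
  expect_true(fc$degenerate)

  expect_error(fit_group(1:4, rep(0, 6)), "different lengths")
  expect_error(fit_group(c(1, NA, 1, 1, 1, 1), rep(0, 6)), "non-finite")
  expect_error(fit_group(1:6, rep(1, 6)), "non-empty")
})

test_that("fit likelihood equals the product of plug-in normal densities", {
  set.seed(3)
  pg <- egfr_patterns()
  for (rep in 1:20) {
    x <- rnorm(6, 7, 1)
    for (lab in pg$labels) {
      f <- fit_group(x, pg$indicators[lab, ])
      g <- pg$indicators[lab, ]
      m <- if (all(g == 0)) rep(f$mu0, 6) else ifelse(g == 1, f$mu1, f$mu0)
      expect_equal(f$log_likelihood,
                   sum(dnorm(x, m, sqrt(f$sigma2), log = TRUE)))
    }
  }
})

test_that("BIC marginal reproduces the published worked example", {
  lm_c <- bic_log_marginal(log(4.22), 3, 6)
  expect_equal(exp(lm_c), 4.22 / sqrt(6)^3)
  expect_equal(round(exp(lm_c), 3), 0.287)
  expect_equal(round(exp(bic_log_marginal(log(0.004), 2, 6)), 3), 0.001)
  expect_equal(bic_log_marginal(log(5), 0, 6), log(5))
  expect_error(bic_log_marginal(0, 2, 0), "n_obs")
})

test_that("marginal identity holds algebraically for every fitted gene", {
  sim <- simulate_profiles(50, seed = 2)
  fit <- bgsc(sim$x)
  for (j in seq_along(fit$patterns$labels)) {
    expect_equal(fit$log_marginal[, j],
                 fit$log_likelihood[, j] -
                   fit$n_params[j] / 2 * log(ncol(sim$x)))
  }
})

test_that("posteriors follow Bayes' formula at full precision", {
  lm_ <- bic_log_marginal(log(c(a = 0.004, b = 0.035, c = 4.22, d = 0.012)),
                          c(2, 3, 3, 3), 6)
  post <- group_posteriors(lm_, c(a = 0.7, b = 0.1, c = 0.1, d = 0.1))
  expect_equal(round(unname(post), 3), c(0.016, 0.008, 0.973, 0.003))
  expect_equal(sum(post), 1, tolerance = 1e-12)

  expect_equal(unname(group_posteriors(c(a = 1, b = 1, c = 1, d = 1),
                                       rep(0.25, 4))), rep(0.25, 4))
  degen <- group_posteriors(c(a = -5, b = 40, c = 0, d = 2),
                            c(a = 0, b = 0, c = 1, d = 0))
  expect_equal(unname(degen), c(0, 0, 1, 0))
  expect_error(group_posteriors(c(a = 1, b = 2), c(a = 0, b = 0)),
               "invalid priors")
  expect_error(group_posteriors(c(a = 1, b = 2), c(x = 0.5, y = 0.5)),
               "do not coincide")
})

test_that("single-gene classification agrees with an independent pipeline", {
  pg <- egfr_patterns()
  pr <- default_priors(pg)
  cl <- classify_gene(c(0, 5, 0.1, 0, -0.1, 0.05), pg)
  expect_equal(cl$assigned_group, "d")
  set.seed(21)
  for (rep in 1:50) {
    x <- rnorm(6, 7, 1) + sample(c(0, 2), 1) * pg$indicators[sample(4, 1), ]
    cl <- classify_gene(x, pg, pr)
    orc <- oracle_classify(x, pg$indicators, pr)
    expect_equal(unname(cl$posterior), unname(orc$posterior),
                 tolerance = 1e-10)
    expect_equal(cl$assigned_group, orc$assigned)
  }
})

test_that("constant profiles are assigned the unregulated group", {
  pg <- egfr_patterns()
  cl <- classify_gene(rep(3.3, 6), pg)
  expect_equal(cl$assigned_group, "a")
  expect_true(cl$degenerate)
  expect_equal(unname(cl$posterior), c(1, 0, 0, 0))
  expect_error(classify_gene(c(1, 2, NA, 4, 5, 6), pg, gene_id = "XYZ"),
               "XYZ")
})

test_that("matrix classification is row-wise and order independent", {
  pg <- egfr_patterns()
  sim <- simulate_profiles(20, seed = 4)
  res <- classify_matrix(sim$x, pg)
  expect_equal(nrow(res), 20L)
  for (i in c(1, 7, 20)) {
    cl <- classify_gene(sim$x[i, ], pg, gene_id = rownames(sim$x)[i])
    expect_equal(res$assigned_group[i], cl$assigned_group)
    expect_equal(res$posterior_c[i], unname(cl$posterior["c"]))
  }
  perm <- sample(20)
  res_p <- classify_matrix(sim$x[perm, ], pg)
  expect_equal(res_p$assigned_group, res$assigned_group[perm])
  expect_equal(res_p$posterior_a, res$posterior_a[perm])

  dup <- sim$x[c(1, 1, 2), ]
  expect_warning(res_d <- classify_matrix(dup, pg), "duplicate")
  expect_equal(anyDuplicated(res_d$gene_id), 0L)
})

test_that("posteriors sum to one and respect uniform-prior equivalence", {
  pg <- egfr_patterns()
  sim <- simulate_profiles(200, seed = 6)
  fit <- bgsc(sim$x)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
  unif <- bgsc(sim$x, priors = rep(0.25, 4))
  expect_equal(unif$assigned,
               pg$labels[apply(unif$log_marginal, 1, which.max)])
})

test_that("group fits carry the expected permutation invariances", {
  set.seed(8)
  x <- rnorm(6, 5, 2)
  fa <- fit_group(x, rep(0, 6))
  fa_p <- fit_group(x[sample(6)], rep(0, 6))
  expect_equal(fa[c("mu0", "sigma2", "log_likelihood")],
               fa_p[c("mu0", "sigma2", "log_likelihood")])
  g_b <- c(0, 1, 0, 1, 0, 1)
  fb <- fit_group(x, g_b)
  x_swap <- x[c(3, 6, 5, 2, 1, 4)]   # permute within odd and even classes
  fb_p <- fit_group(x_swap, g_b)
  expect_equal(fb[c("mu0", "mu1", "sigma2", "log_likelihood")],
               fb_p[c("mu0", "mu1", "sigma2", "log_likelihood")])
})

test_that("within-class scatter strictly lowers the pattern likelihood", {
  g_c <- c(0, 1, 0, 1, 0, 0)
  ll <- vapply(c(0.1, 0.3, 0.6, 1), function(s) {
    x <- c(5 - s, 8 - s, 5 + s, 8 + s, 5 - s, 5 + s)  # class means fixed
    fit_group(x, g_c)$log_likelihood
  }, numeric(1))
  expect_true(all(diff(ll) < 0))
})

test_that("mean estimators agree with numeric likelihood maximization", {
  set.seed(10)
  pg <- egfr_patterns()
  for (rep in 1:60) {
    x <- rnorm(6, 7, 1)
    lab <- sample(pg$labels, 1)
    g <- pg$indicators[lab, ]
    f <- fit_group(x, g)
    o <- oracle_fit_means(x, g)
    expect_equal(f$mu0, unname(o["mu0"]), tolerance = 1e-6)
    if (any(g == 1)) expect_equal(f$mu1, unname(o["mu1"]), tolerance = 1e-6)
    # variance uses the printed denominators, not the 1/n ML variance
    m <- if (all(g == 0)) rep(f$mu0, 6) else ifelse(g == 1, f$mu1, f$mu0)
    denom <- if (all(g == 0)) 5 else 4
    expect_equal(f$sigma2, sum((x - m)^2) / denom)
  }
})

test_that("default priors extend the 70 percent unregulated assumption", {
  pg <- egfr_patterns()
  expect_equal(unname(default_priors(pg)), c(0.7, 0.1, 0.1, 0.1))
  d2 <- knockdown_design(paste0("r", 1:3),
                         list(control = character(0),
                              kd_all = paste0("r", 1:3)))
  p2 <- default_priors(derive_pattern_groups(d2))
  expect_equal(unname(p2), c(0.7, 0.3))
  expect_error(bgsc(matrix(rnorm(12), 2), priors = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})
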