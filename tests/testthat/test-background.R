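# The background model works on the reversed-sign working scale: proximity
# values are <= 0, the Gamma response y = -bppc is positive, and expected
# values are reported back on the proximity scale. Synthetic responses below
# are generated directly on the working scale and passed in as -y.

test_that("an intercept-only fit returns the mean with zero explained deviance", {
  set.seed(1)
  y <- rgamma(500, shape = 20, rate = 5)
  fit <- fit_background(data.frame(row.names = 1:500), -y,
                        terms = gam_terms())
  expect_equal(explained_deviance(fit), 0, tolerance = 1e-9)
  expect_equal(fit$expected, rep(-mean(y), 500), tolerance = 1e-6)
})

test_that("a planted linear coefficient is recovered within two standard errors", {
  set.seed(2)
  n <- 5000
  x <- runif(n)
  mu <- 2 + 3 * x
  y <- rgamma(n, shape = 50, rate = 50 / mu)
  fit <- fit_background(data.frame(x = x), -y, terms = gam_terms(linear = "x"))
  est <- coef(fit)[["x"]]
  se <- summary(fit$fit)$p.table["x", "Std. Error"]
  expect_lt(abs(est - 3), 2 * se)
})

test_that("a planted smooth is recovered with small RMSE and beats permuted covariates", {
  set.seed(3)
  n <- 5000
  x <- runif(n)
  mu <- 3 + sin(2 * pi * x)
  y <- rgamma(n, shape = 80, rate = 80 / mu)
  fit <- fit_background(data.frame(x = x), -y,
                        terms = gam_terms(smooth = "x", k = 10))
  expect_lt(sqrt(mean((-fit$expected - mu)^2)), 0.05)
  ed_true <- explained_deviance(fit)
  fit_perm <- fit_background(data.frame(x = sample(x)), -y,
                             terms = gam_terms(smooth = "x", k = 10))
  expect_gte(ed_true - explained_deviance(fit_perm), 0.1)
})

test_that("adding an informative term never decreases explained deviance", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 800
    x <- runif(n); z <- runif(n)
    mu <- 2 + x + 0.5 * sin(2 * pi * z)
    y <- rgamma(n, shape = 60, rate = 60 / mu)
    f1 <- fit_background(data.frame(x = x, z = z), -y,
                         terms = gam_terms(linear = "x"))
    f2 <- fit_background(data.frame(x = x, z = z), -y,
                         terms = gam_terms(linear = "x", smooth = "z",
                                           k = 8))
    expect_gte(explained_deviance(f2), explained_deviance(f1) - 1e-8)
  }
})

test_that("factor-by smooths and tensor interactions build the expected bases", {
  set.seed(5)
  n <- 1200
  d <- data.frame(x = runif(n), z = runif(n),
                  LAD = factor(sample(c("0", "1"), n, TRUE)),
                  TADsegm_class = factor(sample(c("quiescent", "low-active",
                                                  "active"), n, TRUE)))
  y <- rgamma(n, shape = 40, rate = 40 / (3 + d$x))
  fit <- fit_background(d, -y,
                        terms = gam_terms(smooth = "x", smooth_by = "LAD",
                                          tensors = list(c("x", "z")),
                                          tensor_by = "TADsegm_class",
                                          k = 5, tk = 3))
  cf <- names(coef(fit))
  # one smooth copy per LAD level, k-1 basis columns each
  expect_equal(sum(grepl("^s\\(x\\):LAD0", cf)), 4L)
  expect_equal(sum(grepl("^s\\(x\\):LAD1", cf)), 4L)
  # tensor interaction: (tk-1)^2 columns per class level
  for (lv in c("quiescent", "low-active", "active")) {
    expect_equal(sum(grepl(paste0("^ti\\(x,z\\):TADsegm_class", lv), cf)), 4L)
  }
  # absent columns are dropped with a warning, not an error
  expect_warning(
    fit_background(d[, "x", drop = FALSE], -y,
                   terms = gam_terms(smooth = c("x", "missing"))),
    "dropped")
})

test_that("term significance is calibrated on null terms and powerful on real ones", {
  set.seed(6)
  # strong planted effect: decisive p-values
  for (rep in 1:10) {
    n <- 600
    x <- runif(n)
    y <- rgamma(n, shape = 60, rate = 60 / (2 + 2 * x))
    fit <- fit_background(data.frame(x = x), -y,
                          terms = gam_terms(smooth = "x", k = 6))
    p <- term_significance(fit)$p_value
    expect_lt(min(p), 1e-4)
  }
  # irrelevant covariate: rejection rate near the nominal level
  hits <- 0L
  pvals <- numeric(60)
  for (rep in 1:60) {
    n <- 400
    z <- runif(n)
    y <- rgamma(n, shape = 40, rate = 40 / 3)
    fit <- fit_background(data.frame(z = z), -y,
                          terms = gam_terms(smooth = "z", k = 6))
    pvals[rep] <- term_significance(fit)$p_value[1L]
  }
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.25)   # not systematically anti-conservative
})

test_that("partial effects recover a planted shape and flag extrapolation", {
  set.seed(7)
  n <- 2000
  x <- runif(n)
  mu <- 3 + x          # linear truth
  y <- rgamma(n, shape = 80, rate = 80 / mu)
  fit <- fit_background(data.frame(x = x), -y,
                        terms = gam_terms(smooth = "x", k = 8))
  pe <- partial_effects(fit, "x")
  # the partial effect is the planted straight line up to the smooth's
  # centering constant: unit slope, negligible curvature
  lf <- lm(effect ~ x, data = pe)
  expect_equal(unname(coef(lf)["x"]), 1, tolerance = 0.1)
  expect_lt(max(abs(residuals(lf))), 0.05)
  expect_true(all(pe$upper > pe$lower))
  expect_false(any(pe$extrapolated))
})

test_that("the fit is invariant to row order", {
  set.seed(8)
  n <- 1200
  x <- runif(n)
  y <- rgamma(n, shape = 50, rate = 50 / (2 + x))
  f1 <- fit_background(data.frame(x = x), -y,
                       terms = gam_terms(smooth = "x", k = 8))
  ord <- sample(n)
  f2 <- fit_background(data.frame(x = x[ord]), -y[ord],
                       terms = gam_terms(smooth = "x", k = 8))
  expect_equal(f1$expected[ord], f2$expected, tolerance = 1e-6)
})
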