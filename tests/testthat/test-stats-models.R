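test_that("standardization is exact and reversible", {
  set.seed(61)
  tab <- data.frame(a = rnorm(50, 5, 2), b = runif(50), c = rep(1, 50))
  expect_warning(out <- standardize_covariates(tab, c("a", "b", "c")),
                 "zero-variance")
  sc <- attr(out, "scaling")
  expect_equal(out$a, (tab$a - mean(tab$a)) / sd(tab$a))
  back <- out$a * sc$scale[sc$covariate == "a"] +
    sc$center[sc$covariate == "a"]
  expect_equal(back, tab$a, tolerance = 1e-12)
  expect_null(out$c)

  # standardized slope = raw slope * SD(x)
  tab2 <- data.frame(x = rnorm(200, 10, 3))
  tab2$y <- 2 + 0.7 * tab2$x + rnorm(200, 0, 0.5)
  raw <- coef(lm(y ~ x, tab2))[["x"]]
  std <- standardize_covariates(tab2, "x")
  expect_equal(coef(lm(y ~ x, std))[["x"]], raw * sd(tab2$x),
               tolerance = 1e-9)
})

test_that("thinning takes every k-th dive within individual", {
  tab <- data.frame(individual = rep(c("a", "b"), each = 50),
                    t = rep(1:50, 2))
  th <- thin_every_k(tab, 10)
  expect_equal(nrow(th), 10)
  expect_equal(th$t[th$individual == "a"], c(1, 11, 21, 31, 41))
  expect_identical(thin_every_k(tab, 1), tab)

  # AR(1) residual autocorrelation is broken by one-in-ten thinning
  set.seed(62)
  e <- as.numeric(arima.sim(list(ar = 0.6), 2000))
  tab2 <- data.frame(individual = "a", y = e)
  th2 <- thin_every_k(tab2, 10)
  expect_lt(abs(acf(th2$y, plot = FALSE)$acf[2]), 0.1)
})

test_that("VIF flags colinearity and reports infinity when perfect", {
  set.seed(63)
  tab <- data.frame(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
  v <- vif_screen(tab, c("x1", "x2", "x3"))
  expect_true(all(v < 1.2))

  tab$x4 <- tab$x1
  expect_warning(v2 <- vif_screen(tab, c("x1", "x2", "x4")), "VIF")
  expect_true(is.infinite(v2[["x4"]]))

  tab$x5 <- tab$x1 + rnorm(300, 0, 0.1)
  expect_warning(v3 <- vif_screen(tab, c("x1", "x2", "x5")), "VIF")
  expect_gt(v3[["x5"]], 5)
})

test_that("the negative binomial model honours its offset contract", {
  co <- list(intercept = 0.3, slopes = c(x1 = 0.4, x2 = -0.3), theta = 2)
  st <- simulate_covariate_table(800, 4, co, "nb", seed = 64)
  sp <- model_spec("negbin", "count", c(x1 = 1L, x2 = 1L),
                   offset = "bottom_duration_min", individual = "individual")
  f <- fit_negbin(sp, st$table)

  # doubling every exposure shifts only the intercept, by exactly -log(2)
  tab2 <- st$table
  tab2$bottom_duration_min <- 2 * tab2$bottom_duration_min
  f2 <- fit_negbin(sp, tab2)
  d <- f2$coefficients$estimate - f$coefficients$estimate
  expect_equal(d[1], -log(2), tolerance = 1e-6)
  expect_equal(d[-1], rep(0, length(d) - 1), tolerance = 1e-6)
  expect_equal(f2$theta, f$theta, tolerance = 1e-4)

  # AIC identity
  expect_equal(f$aic, 2 * f$df - 2 * f$logLik, tolerance = 1e-9)

  expect_error(fit_negbin(sp, transform(st$table, count = count + 0.5)),
               "integer")
})

test_that("negbin nests Poisson in the large-theta limit", {
  co <- list(intercept = 0.5, slopes = c(x1 = 0.3), theta = Inf)
  st <- simulate_covariate_table(1000, 2, co, "nb", seed = 65)
  sp <- model_spec("negbin", "count", c(x1 = 1L),
                   offset = "bottom_duration_min")
  f <- suppressWarnings(fit_negbin(sp, st$table))
  pf <- glm(count ~ x1 + offset(log(bottom_duration_min)),
            data = st$table, family = poisson)
  expect_gt(f$theta, 50)
  expect_lt(abs(f$logLik - as.numeric(logLik(pf))), 1)
})

test_that("deviance explained behaves like a GLM R-squared", {
  sp0 <- model_spec("negbin", "count",
                    stats::setNames(integer(0), character(0)),
                    offset = "bottom_duration_min")
  co <- list(intercept = 0.3, slopes = c(x1 = 0.9), theta = 3)
  st <- simulate_covariate_table(1000, 2, co, "nb", seed = 66)
  null_fit <- fit_negbin(sp0, st$table)
  expect_equal(deviance_explained(null_fit), 0, tolerance = 1e-6)

  sp1 <- model_spec("negbin", "count", c(x1 = 1L),
                    offset = "bottom_duration_min")
  f1 <- fit_negbin(sp1, st$table)
  expect_gt(deviance_explained(f1), 50)

  # a pure-noise covariate adds almost nothing
  st$table$junk <- rnorm(1000)
  sp2 <- model_spec("negbin", "count", c(x1 = 1L, junk = 1L),
                    offset = "bottom_duration_min")
  f2 <- fit_negbin(sp2, st$table)
  expect_lt(deviance_explained(f2) - deviance_explained(f1), 1)

  nde <- per_covariate_nde(f2)
  expect_true(all(nde >= -1e-9))
  expect_lt(nde[["junk"]], 1)
  expect_gt(nde[["x1"]], 40)
})

test_that("Nakagawa R2 partitions variance as designed", {
  # sd_individual = 0: marginal and conditional collapse
  co <- list(intercept = 0, slopes = c(x1 = 0.5), sd_individual = 0,
             sd_residual = 1)
  st <- simulate_covariate_table(500, 5, co, "lmm", seed = 7001)
  sp <- model_spec("lmm", "y", c(x1 = 1L), individual = "individual")
  f <- suppressMessages(fit_lmm(sp, st$table, REML = TRUE))
  r2 <- nakagawa_r2(f)
  expect_lt(f$sigma2_random, 1e-6)
  expect_equal(r2[["R2m"]], r2[["R2c"]], tolerance = 1e-9)

  # null fixed structure: R2m = 0
  sp0 <- model_spec("lmm", "y", stats::setNames(integer(0), character(0)),
                    individual = "individual")
  co0 <- list(intercept = 0, slopes = stats::setNames(numeric(0),
                                                      character(0)),
              sd_individual = 1, sd_residual = 1)
  st0 <- simulate_covariate_table(500, 10, co0, "lmm", seed = 68)
  f0 <- fit_lmm(sp0, st0$table, REML = TRUE)
  expect_equal(nakagawa_r2(f0)[["R2m"]], 0, tolerance = 1e-9)

  # variance partition fixed:random:residual = 1:1:2
  co2 <- list(intercept = 0, slopes = c(x1 = 1), sd_individual = 1,
              sd_residual = sqrt(2))
  st2 <- simulate_covariate_table(4000, 40, co2, "lmm", seed = 69)
  f2 <- fit_lmm(model_spec("lmm", "y", c(x1 = 1L),
                           individual = "individual"), st2$table,
                REML = TRUE)
  r22 <- nakagawa_r2(f2)
  expect_lt(abs(r22[["R2m"]] - 0.25), 0.05)
  expect_lt(abs(r22[["R2c"]] - 0.50), 0.05)
  # AIC identity for mixed fits
  expect_equal(f2$aic, 2 * f2$df - 2 * f2$logLik, tolerance = 1e-9)
})

test_that("the beta regression models mean and precision separately", {
  co <- list(intercept = 0, slopes = c(x1 = 0), phi_intercept = 2,
             phi_slopes = c(x1 = 0))
  st <- simulate_covariate_table(800, 2, co, "beta", seed = 70)
  sp <- model_spec("beta", "y", c(x1 = 1L))
  f <- fit_beta(sp, st$table)
  mu <- plogis(f$coefficients$estimate[f$coefficients$term == "(Intercept)"])
  expect_equal(mu, 0.5, tolerance = 0.05)
  # constant-precision data: precision slope ~ 0
  sl <- f$precision_coefficients
  expect_lt(abs(sl$estimate[sl$term == "x1"]), 3 * sl$se[sl$term == "x1"])
  expect_equal(f$aic, 2 * f$df - 2 * f$logLik, tolerance = 1e-6)

  bad <- st$table
  bad$y[1] <- 1
  expect_error(fit_beta(sp, bad), "strictly in")
})

test_that("pearson2 is a squared correlation on the link scale", {
  # near-perfect fit
  set.seed(71)
  tab <- data.frame(x1 = rnorm(300), individual = "a")
  tab$y <- 1 + 2 * tab$x1 + rnorm(300, 0, 1e-4)
  tab$individual <- factor(rep(c("a", "b"), 150))
  f <- suppressMessages(fit_lmm(model_spec("lmm", "y", c(x1 = 1L),
                                           individual = "individual"),
                                tab, REML = TRUE))
  expect_gt(pearson2(f), 0.999)

  # independent predictor: ~ 0
  set.seed(72)
  tab0 <- data.frame(x1 = rnorm(800),
                     individual = factor(rep(c("a", "b"), 400)))
  tab0$y <- rnorm(800)
  f0 <- suppressMessages(fit_lmm(model_spec("lmm", "y", c(x1 = 1L),
                                            individual = "individual"),
                                 tab0, REML = TRUE))
  p2 <- pearson2(f0)
  expect_lt(p2, 0.02)
  expect_gte(p2, 0)
})

test_that("stepwise AIC keeps strong covariates and mostly drops noise", {
  set.seed(73)
  n <- 400
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                    individual = factor(rep(c("a", "b"), each = n / 2)))
  tab$y <- 1 + tab$x1 + rnorm(n)
  sp <- model_spec("lmm", "y", c(x1 = 1L, x2 = 1L),
                   individual = "individual")
  sel <- stepwise_aic(sp, tab)
  expect_true("x1" %in% names(sel$covariates))
  tr <- attr(sel, "trace")
  expect_true(is.data.frame(tr) && nrow(tr) >= 1)

  # all-null covariates: intercept-only model selected in the majority of
  # replicates
  hits <- 0
  for (r in 1:10) {
    set.seed(200 + r)
    tab0 <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                       individual = factor(rep(c("a", "b"), each = n / 2)))
    tab0$y <- rnorm(n)
    s <- stepwise_aic(sp, tab0)
    if (length(s$covariates) == 0) hits <- hits + 1
  }
  expect_gt(hits, 5)
})

test_that("polynomial escalation finds curvature and respects its cap", {
  set.seed(74)
  n <- 600
  tab <- data.frame(x1 = rnorm(n),
                    individual = factor(rep(c("a", "b"), each = n / 2)))
  tab$y <- 1 + 0.5 * tab$x1 + 0.8 * tab$x1^2 + rnorm(n)
  sp <- model_spec("lmm", "y", c(x1 = 1L), individual = "individual")
  fin <- polynomial_escalation(sp, tab)
  expect_gte(fin$covariates[["x1"]], 2)
  expect_lte(fin$covariates[["x1"]], 4)

  # a linear effect usually stays linear; degree never exceeds the cap
  tab$y <- 1 + 0.5 * tab$x1 + rnorm(n)
  fin2 <- polynomial_escalation(sp, tab, max_degree = 2)
  expect_lte(fin2$covariates[["x1"]], 2)
})

test_that("the residual autocorrelation report is a per-individual ACF", {
  set.seed(75)
  n <- 500
  tab <- data.frame(x1 = rnorm(n),
                    individual = factor(rep(c("a", "b"), each = n / 2)))
  tab$y <- tab$x1 + as.numeric(arima.sim(list(ar = 0.8), n))
  f <- fit_lmm(model_spec("lmm", "y", c(x1 = 1L),
                          individual = "individual"), tab, REML = TRUE)
  rep_ <- residual_acf_report(f)
  expect_setequal(unique(rep_$individual), c("a", "b"))
  expect_true(all(rep_$acf[rep_$lag == 0] == 1))
  expect_true(all(rep_$acf[rep_$lag == 1] > 0.5))

  # white-noise residuals stay inside the reference bounds at lag 1
  tab$y <- tab$x1 + rnorm(n)
  f2 <- fit_lmm(model_spec("lmm", "y", c(x1 = 1L),
                           individual = "individual"), tab, REML = TRUE)
  rep2 <- residual_acf_report(f2)
  l1 <- rep2[rep2$lag == 1, ]
  expect_true(all(abs(l1$acf) < l1$bound))
})
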