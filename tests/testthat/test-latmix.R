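# Truncated-Gaussian mixture fitting, model selection, bootstrap.

test_that("truncated component densities integrate to one on the support", {
  for (par in list(c(0.08, 0.015), c(0.25, 0.04), c(0.45, 0.2), c(-0.05, 0.1))) {
    val <- integrate(function(z)
      odorcode:::trunc_comp_density(z, par[1], par[2], 0, 0.5), 0, 0.5,
      rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("k = 1 fits match the sample moments when truncation is negligible and the direct MLE otherwise", {
  set.seed(31)
  x <- rnorm(3000, 0.2, 0.02)             # far from both bounds
  f <- fit_truncgauss_mixture(x, 1)
  expect_equal(f$mu, mean(x), tolerance = 1e-4)
  expect_equal(f$sigma, sd(x), tolerance = 1e-2)

  # strong truncation: EM solution vs direct numerical likelihood maximization
  y <- rnorm(6000, 0.45, 0.12)
  y <- y[y >= 0 & y <= 0.5]
  f2 <- fit_truncgauss_mixture(y, 1, tol = 1e-10)
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    -sum(dnorm(y, mu, s, log = TRUE) -
           log(pnorm(0.5, mu, s) - pnorm(0, mu, s)))
  }
  o <- optim(c(mean(y), log(sd(y))), nll, method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(f2$mu, o$par[1], tolerance = 1e-4)
  expect_equal(f2$sigma, exp(o$par[2]), tolerance = 1e-3)
})

test_that("a two-component sample is recovered near its generating parameters", {
  set.seed(32)
  x <- c(rnorm(1000, 0.08, 0.015), rnorm(1000, 0.25, 0.04))
  x <- x[x >= 0 & x <= 0.5]
  f <- fit_truncgauss_mixture(x, 2, seed = 1)
  expect_true(f$converged)
  expect_lt(abs(f$mu[1] - 0.08), 0.005)
  expect_lt(abs(f$mu[2] - 0.25), 0.015)
  expect_equal(f$p, c(0.5, 0.5), tolerance = 0.1)
})

test_that("EM log-likelihood is non-decreasing and nested fits order correctly", {
  set.seed(33)
  for (i in 1:5) {
    x <- c(rnorm(150, runif(1, 0.05, 0.15), 0.02),
           rnorm(150, runif(1, 0.2, 0.4), 0.05))
    x <- pmin(pmax(x, 0), 0.5)
    f <- fit_truncgauss_mixture(x, 2, seed = i, trace = TRUE)
    expect_true(all(diff(f$ll_trace) > -1e-6 * length(x)))
    f1 <- fit_truncgauss_mixture(x, 1)
    expect_gte(f$log_lik, f1$log_lik - 1e-6)
  }
})

test_that("BIC selects one component for unimodal data and counts free parameters correctly", {
  set.seed(34)
  x <- rnorm(400, 0.2, 0.03)
  sel <- select_k_by_bic(x, 1:3, seed = 2)
  expect_equal(sel$best_k, 1)
  f3 <- fit_truncgauss_mixture(sample_peak_latencies(300, fx_default_config(),
                                                     seed = 3), 3, seed = 4)
  expect_equal(f3$q, 8)   # 3k - 1
  constr <- list(p = f3$p, mu = c(NA, NA, f3$mu[3]),
                 sigma = c(NA, NA, f3$sigma[3]))
  fc <- fit_truncgauss_mixture(sample_peak_latencies(300, fx_default_config(),
                                                     seed = 3), 3,
                               constraints = constr, seed = 5)
  expect_equal(fc$q, 4)   # two free mu + two free sigma, no free p
  # frozen parameters stay frozen
  expect_equal(fc$p, f3$p)
  expect_equal(fc$mu[3], f3$mu[3])
  expect_equal(fc$sigma[3], f3$sigma[3])
})

test_that("bootstrap intervals bracket the point estimate and shrink ~2-fold when n quadruples", {
  set.seed(35)
  gen <- function(n) {
    z <- c(rnorm(n / 2, 0.09, 0.02), rnorm(n / 2, 0.26, 0.05))
    z[z >= 0 & z <= 0.5]
  }
  x <- gen(400)
  b <- bootstrap_cis(x, 2, n_boot = 150, seed = 6)
  inside <- b$ci$point >= b$ci$lower & b$ci$point <= b$ci$upper
  expect_gte(mean(inside), 0.95)

  b4 <- bootstrap_cis(gen(1600), 2, n_boot = 150, seed = 7)
  w1 <- b$ci$upper - b$ci$lower
  w4 <- b4$ci$upper - b4$ci$lower
  ratio <- median(w1 / w4)   # sqrt(n) scaling predicts 2
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 3.0)

  expect_error(bootstrap_cis(rep(0.2, 50), 2), "degenerate")
  expect_error(fit_truncgauss_mixture(c(0.1, 0.2), 1), "5 observations")
  expect_error(fit_truncgauss_mixture(c(0.1, 0.7), 1), "bounds")
})

test_that("constrained refits hold the slow component fixed and flatten nothing that is identical", {
  cfg <- fx_default_config()
  samples <- lapply(cfg$concentrations, function(cc)
    sample_peak_latencies(350, cfg, "PCx", cc, seed = round(cc * 1e7)))
  names(samples) <- cfg$concentrations
  cf <- constrained_two_phase_fit(samples, seed = 8)
  for (f in cf$constrained) {
    expect_equal(f$p, cf$constraints$p)
    expect_equal(f$mu[3], cf$constraints$mu[3])
  }
  tab <- two_phase_summary(cf$constrained)
  # late component advances with concentration; early component barely moves
  expect_lt(tab$mu2[4], tab$mu2[1] - 0.03)
  expect_lt(abs(tab$mu1[4] - tab$mu1[1]), 0.02)

  # regional contrast: the late-component advance is steeper in cortex than bulb
  ob_samples <- lapply(cfg$concentrations, function(cc)
    sample_peak_latencies(350, cfg, "OB", cc, seed = round(cc * 1e7) + 3))
  names(ob_samples) <- cfg$concentrations
  cf_ob <- constrained_two_phase_fit(ob_samples, seed = 18)
  tab_ob <- two_phase_summary(cf_ob$constrained)
  shift_pcx <- tab$mu2[1] - tab$mu2[4]
  shift_ob <- tab_ob$mu2[1] - tab_ob$mu2[4]
  expect_gt(shift_pcx, shift_ob)

  # identical samples per concentration give flat component tracks
  same <- setNames(lapply(1:3, function(i) samples[[2]]), c("a", "b", "c"))
  cf2 <- constrained_two_phase_fit(same, seed = 9)
  tab2 <- two_phase_summary(cf2$unconstrained)
  expect_lt(max(tab2$mu2) - min(tab2$mu2), 1e-3)

  expect_error(two_phase_summary(list(`1` = cf$constrained[[1]],
                                      `2` = fit_truncgauss_mixture(
                                        samples[[1]], 2, seed = 1))),
               "component counts")
})
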