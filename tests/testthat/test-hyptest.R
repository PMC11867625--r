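test_that("fit_glm matches the normal-equations oracle", {
  # simple identities
  x <- withr::with_seed(1, rnorm(30))
  fit <- fit_glm(x, x)
  expect_equal(fit$betas, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)

  # y orthogonal to x: r2 = 0, adjusted r2 < 0
  y <- withr::with_seed(2, rnorm(30))
  y <- y - mean(y); xc <- x - mean(x)
  y <- y - sum(xc * y) / sum(xc * xc) * xc
  fit0 <- fit_glm(y, x)
  expect_equal(fit0$r2, 0, tolerance = 1e-10)
  expect_lt(fit0$adj_r2, 0)

  # toy n = 12, p = 2 against the explicit normal equations
  X <- withr::with_seed(3, matrix(rnorm(24), 12, 2))
  yy <- withr::with_seed(4, X %*% c(1, -2) + rnorm(12))
  got <- fit_glm(as.numeric(yy), X)
  oracle <- normal_equations_fit(as.numeric(yy), X)
  expect_equal(got$betas, oracle$betas, tolerance = 1e-10)
  expect_equal(got$adj_r2, oracle$adj_r2, tolerance = 1e-10)

  # random instances, n <= 200, p <= 3
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(10:200, 1))
    p <- withr::with_seed(s + 1000, sample(1:3, 1))
    X <- withr::with_seed(s + 2000, matrix(rnorm(n * p), n, p))
    y <- withr::with_seed(s + 3000, rnorm(n))
    got <- fit_glm(y, X)
    oracle <- normal_equations_fit(y, X)
    expect_equal(got$betas, oracle$betas, tolerance = 1e-8)
    expect_equal(got$r2, oracle$r2, tolerance = 1e-8)
    expect_equal(got$adj_r2, oracle$adj_r2, tolerance = 1e-8)
  }
  expect_error(fit_glm(x, cbind(x, x)), "collinear")
})

test_that("tidy and glance expose betas and fit statistics", {
  X <- withr::with_seed(5, matrix(rnorm(60), 30, 2))
  y <- withr::with_seed(6, rnorm(30))
  fit <- fit_glm(y, X)
  td <- tidy(fit)
  expect_equal(td$term, c("beta1", "beta2"))
  expect_equal(td$estimate, fit$betas)
  gl <- glance(fit)
  expect_equal(gl$adj.r.squared, fit$adj_r2)
  expect_equal(gl$nobs, 30)
  expect_lte(gl$adj.r.squared, gl$r.squared)
})

test_that("sliding-window switching GLM scores per-window best alliance", {
  T <- 100
  n1 <- zscore(withr::with_seed(7, rnorm(T)))
  n2 <- zscore(withr::with_seed(8, rnorm(T)))
  # o = n1 everywhere: every window fits perfectly
  sw <- glm_switching(n1, n1, n2)
  expect_equal(sw$mean_adj_r2, 1, tolerance = 1e-10)
  expect_equal(sw$n_windows, 91L)  # T - window + 1

  # block-alternating o: all within-block windows are perfect, so the mean
  # is at least the within-block window fraction
  block <- 20L
  o <- switch_blocks(n1, n2, block)
  sw2 <- glm_switching(o, n1, n2)
  n_boundary_windows <- (T / block - 1) * 9   # 9 straddling starts per switch
  frac_within <- (91 - n_boundary_windows) / 91
  expect_gte(sw2$mean_adj_r2, frac_within)
  expect_lt(sw2$mean_adj_r2, 1)

  expect_error(glm_switching(n1[1:5], n1[1:5], n2[1:5]), "shorter")
})

test_that("coupling GLMs recover exact generative structures", {
  T <- 80
  n1 <- zscore(withr::with_seed(9, rnorm(T)))
  n2 <- zscore(withr::with_seed(10, rnorm(T)))
  cp <- glm_coupling(n1 + n2, n1, n2)
  expect_equal(cp$linear$adj_r2, 1, tolerance = 1e-10)
  inter <- pmax(n1, 0) * pmax(n2, 0)
  cp2 <- glm_coupling(inter, n1, n2)
  expect_equal(cp2$nonlinear$adj_r2, 1, tolerance = 1e-10)

  # all three fits against the oracle on noisy data
  o <- withr::with_seed(11, n1 + 0.5 * n2 + 0.3 * rnorm(T))
  cp3 <- glm_coupling(o, n1, n2)
  zo <- zscore(o); zi <- zscore(inter)
  expect_equal(cp3$linear$adj_r2,
               normal_equations_fit(zo, cbind(n1, n2))$adj_r2, tolerance = 1e-10)
  expect_equal(cp3$combined$adj_r2,
               normal_equations_fit(zo, cbind(n1, n2, zi))$adj_r2, tolerance = 1e-10)
  expect_equal(cp3$nonlinear$adj_r2,
               normal_equations_fit(zo, cbind(zi))$adj_r2, tolerance = 1e-10)

  # nesting: r2_combined >= r2_linear >= 0
  expect_gte(cp3$combined$r2, cp3$linear$r2)
  expect_gte(cp3$linear$r2, 0)

  # disjoint positive supports give a zero interaction: nonlinear fits flagged
  a <- rep(c(2, -1, -1), 27); b <- rep(c(-1, 2, -1), 27)
  cp4 <- glm_coupling(withr::with_seed(20, rnorm(81)), a, b)
  expect_true(length(cp4$flags) > 0)
  expect_null(cp4$nonlinear)
  expect_false(is.null(cp4$linear))
})

test_that("spatial-mixture GLM averages per-vertex fits", {
  T <- 60
  n1 <- zscore(withr::with_seed(12, rnorm(T)))
  n2 <- zscore(withr::with_seed(13, rnorm(T)))
  # every vertex equals n1, or half n1 / half n2: perfect per-vertex fits
  expect_equal(glm_mixture(rbind(n1, n1, n1), n1, n2)$mean_adj_r2, 1,
               tolerance = 1e-10)
  expect_equal(glm_mixture(rbind(n1, n2, n1, n2), n1, n2)$mean_adj_r2, 1,
               tolerance = 1e-10)

  # toy 3-vertex data against the per-vertex oracle
  Y <- rbind(withr::with_seed(14, n1 + 0.2 * rnorm(T)),
             withr::with_seed(15, n2 - n1 + 0.3 * rnorm(T)),
             withr::with_seed(16, rnorm(T)))
  got <- glm_mixture(Y, n1, n2)
  oracle <- mean(vapply(1:3, function(v)
    normal_equations_fit(Y[v, ], cbind(n1, n2))$adj_r2, 1.0))
  expect_equal(got$mean_adj_r2, oracle, tolerance = 1e-10)

  # zero-variance vertices are skipped and counted
  Y2 <- rbind(Y, rep(1, T))
  got2 <- glm_mixture(Y2, n1, n2)
  expect_equal(got2$n_skipped, 1L)
  expect_equal(got2$mean_adj_r2, got$mean_adj_r2, tolerance = 1e-12)
})

test_that("power spectra sit on the one-sided grid with unit maximum", {
  tr <- 0.72; T <- 1200
  x <- withr::with_seed(17, rnorm(T))
  spec <- power_spectrum(x, tr)
  expect_equal(max(spec$power), 1)
  expect_equal(max(spec$frequency), 600 / (T * tr))  # Nyquist = 1/(2 TR)
  expect_equal(max(spec$frequency), 1 / (2 * tr), tolerance = 1e-12)

  # pure sinusoid with an integer number of periods peaks at its frequency
  f0 <- 0.1; T2 <- 500; tr2 <- 1
  s <- sin(2 * pi * f0 * (0:(T2 - 1)) * tr2)
  sp <- power_spectrum(s, tr2)
  expect_equal(sp$frequency[which.max(sp$power)], f0)

  # matches a direct DFT bin-by-bin
  direct <- Mod(stats::fft(x))[1:601]^2
  expect_equal(spec$power, direct / max(direct), tolerance = 1e-12)

  # scale invariance and degenerate input
  expect_equal(power_spectrum(5 * x, tr)$power, spec$power, tolerance = 1e-12)
  expect_error(power_spectrum(rep(2, 100), tr), "constant")
  expect_error(power_spectrum(x[1:4], tr), "at least 8")
})

test_that("correlation comparison and paired tests aggregate as specified", {
  T <- 120
  ds <- simulate_dataset(tiny_config(noise_sd = 0.1, n_timepoints = T))
  a <- assign_vertices(ds$maps, c(1, 2))
  st <- extract_summary(ds$runs[[1]], a)
  b <- withr::with_seed(2, semisim_bundle(ds$runs[[1]], ds$maps, a, st))
  cc <- compare_correlations(st$o, b)
  expect_equal(nrow(cc), 8L)
  expect_true(all(cc$r >= -1 & cc$r <= 1))
  expect_equal(cc$z, atanh(pmin(pmax(cc$r, -(1 - 1e-12)), 1 - 1e-12)))

  # variant identical / negated relative to o
  b$variants$linear_add <- st$o
  b$variants$nonlin_mult <- -st$o
  cc2 <- compare_correlations(st$o, b)
  expect_equal(cc2$r[cc2$variant == "linear_add"], 1, tolerance = 1e-12)
  expect_equal(cc2$r[cc2$variant == "nonlin_mult"], -1, tolerance = 1e-12)

  # paired t on toy z-vectors {0.2,0.3,0.4} vs {0.1,0.1,0.3}: t = 4 by hand
  df <- tibble::tibble(
    subject = rep(1:3, 2),
    variant = rep(c("a", "b"), each = 3),
    r = tanh(c(0.2, 0.3, 0.4, 0.1, 0.1, 0.3)),
    z = c(0.2, 0.3, 0.4, 0.1, 0.1, 0.3))
  glm_df <- tibble::tibble(subject = 1, model = "coupling_linear", adj_r2 = 0.5)
  rk <- rank_hypotheses(df, glm_df)
  expect_equal(rk$correlation$tests$statistic[1], 4, tolerance = 1e-12)
  expect_equal(rk$corr_winner, "a")
  expect_equal(rk$glm_winner, "coupling_linear")  # single model wins trivially
})
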