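test_that("latent series are standardized, low-frequency, and near-independent", {
  cfg <- tiny_config(smooth_len = 1L)
  L <- withr::with_seed(1, make_latent_series(cfg))
  expect_equal(unname(rowMeans(L)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(L, 1, function(x) sqrt(mean((x - mean(x))^2)))),
               rep(1, 3), tolerance = 1e-10)

  # default config, K = 2: |corr| < 0.2 in at least 95% of 200 seeded draws
  # (band computed by Monte-Carlo before freezing; these seeds give 0.96)
  cfg2 <- synth_config(n_modes = 2, n_vertices = 100, unique_region_size = 20,
                       overlap_region_size = 10)
  hits <- sum(vapply(1:200, function(s) {
    L <- withr::with_seed(s, make_latent_series(cfg2))
    abs(cor(L[1, ], L[2, ])) < 0.2
  }, TRUE))
  expect_gte(hits / 200, 0.95)

  # smoothing kernel spectrum oracle: for w = 10 at TR 0.72 the kernel has
  # less power above 0.2 Hz than below 0.1 Hz, and so do the smoothed rows
  w <- 10L; T <- 500L; tr <- 0.72
  kern <- c(rep(1 / w, w), rep(0, T - w))
  H <- Mod(stats::fft(kern))^2
  f <- (0:(T - 1)) / (T * tr)
  half <- seq_len(floor(T / 2) + 1)
  expect_lt(sum(H[half][f[half] > 0.2]), sum(H[half][f[half] < 0.1]))

  cfgw <- tiny_config(n_timepoints = T, smooth_len = w)
  L <- withr::with_seed(5, make_latent_series(cfgw))
  spec <- power_spectrum(L[1, ], tr)
  expect_lt(sum(spec$power[spec$frequency > 0.2]),
            sum(spec$power[spec$frequency < 0.1]))
})

test_that("latent correlation is controllable and sizing errors are raised", {
  cfg <- tiny_config(latent_corr = 0.6, n_timepoints = 2000L)
  L <- withr::with_seed(2, make_latent_series(cfg))
  off <- cor(t(L))[lower.tri(diag(3))]
  expect_true(all(abs(off - 0.6) < 0.25))
  expect_error(make_latent_series(tiny_config(n_timepoints = 20L, smooth_len = 30L)),
               "sizing")
})

test_that("planted spatial maps honor territories and thresholds", {
  # V=100, K=2, unique=20, overlap=10: exactly 20 vertices are uniquely net-1
  cfg <- synth_config(n_vertices = 100, n_modes = 2, unique_region_size = 20,
                      overlap_region_size = 10, seed = 11)
  sm <- withr::with_seed(11, make_spatial_maps(cfg))
  expect_equal(sum(sm$maps[1, ] >= 1 & sm$maps[2, ] < 0.1), 20)

  # find-the-biggest labeling recovers planted membership on unique regions
  cfg3 <- tiny_config()
  sm3 <- withr::with_seed(3, make_spatial_maps(cfg3))
  winner <- apply(sm3$maps, 2, which.max)
  for (k in 1:3)
    expect_true(all(winner[sm3$membership$unique_regions[[k]]] == k))

  # off-territory weights are small on a unique region's other modes
  u1 <- sm3$membership$unique_regions[[1]]
  expect_true(all(abs(sm3$maps[2:3, u1]) < 0.02))

  # overlap_region_size = 0 gives an empty overlap set downstream
  cfg0 <- tiny_config(overlap_region_size = 0L)
  ds0 <- simulate_dataset(cfg0)
  a0 <- assign_vertices(ds0$maps, c(1, 2))
  expect_equal(sum(a0$labels == "OVERLAP"), 0)

  expect_error(synth_config(n_vertices = 50, n_modes = 3,
                            unique_region_size = 20, overlap_region_size = 10),
               "sizing")
})

test_that("vertex data follow the planted mechanism exactly when noise-free", {
  base <- tiny_config(noise_sd = 0)

  # coupling_additive: overlap vertex correlates 1 with standardized sum
  ds <- simulate_dataset(base)
  l <- ds$truth$latent_series[[1]]
  ov <- ds$truth$membership$overlap
  expect_equal(cor(ds$runs[[1]][ov[1], ], zscore(l[1, ] + l[2, ])), 1,
               tolerance = 1e-12)

  # coupling_multiplicative: zero-clamped product, rescaled
  dsm <- simulate_dataset(tiny_config(noise_sd = 0,
                                      mechanism = "coupling_multiplicative"))
  lm_ <- dsm$truth$latent_series[[1]]
  ovm <- dsm$truth$membership$overlap
  expect_equal(dsm$runs[[1]][ovm[1], ],
               zscore(pmax(lm_[1, ], 0) * pmax(lm_[2, ], 0)), tolerance = 1e-12)

  # switching with block_len = T: overlap vertex equals latent 1 exactly
  dss <- simulate_dataset(tiny_config(noise_sd = 0, mechanism = "switching_block",
                                      block_len = 100L))
  expect_equal(dss$runs[[1]][dss$truth$membership$overlap[1], ],
               unname(dss$truth$latent_series[[1]][1, ]))

  # mixing_random: mean overlap series matches the planted half/half average
  dsr <- simulate_dataset(tiny_config(noise_sd = 0, mechanism = "mixing_random",
                                      overlap_region_size = 50L,
                                      n_vertices = 200L))
  lr <- dsr$truth$latent_series[[1]]
  gen <- dsr$truth$membership$generator_net
  expect_equal(sum(gen == 1), 25)
  m <- colMeans(dsr$runs[[1]][dsr$truth$membership$overlap, ])
  expect_gt(cor(m, 0.5 * (lr[1, ] + lr[2, ])), 0.99)

  # odd overlap count: network 1 receives the extra vertex
  dodd <- simulate_dataset(tiny_config(noise_sd = 0, mechanism = "mixing_random",
                                       overlap_region_size = 9L))
  expect_equal(sum(dodd$truth$membership$generator_net == 1), 5)
})

test_that("datasets are seed-deterministic with finite values throughout", {
  cfg <- tiny_config(noise_sd = 0.4, n_runs = 2L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$maps, d2$maps)
  expect_identical(d1$runs, d2$runs)
  d3 <- simulate_dataset(cfg, seed = 99L)
  expect_false(identical(d1$runs[[1]], d3$runs[[1]]))
  expect_true(all(vapply(d1$runs, function(m) all(is.finite(m)), TRUE)))
})

test_that("delimited datasets round-trip bit-exactly; cifti is rejected", {
  ds <- simulate_dataset(tiny_config(n_vertices = 40L, n_modes = 3L,
                                     unique_region_size = 8L,
                                     overlap_region_size = 4L,
                                     n_timepoints = 30L, noise_sd = 0.2,
                                     n_runs = 2L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$maps, ds$maps)
  expect_identical(back$runs, ds$runs)
  expect_identical(back$vertex_area, ds$vertex_area)
  expect_identical(back$truth$membership$overlap, ds$truth$membership$overlap)
  expect_equal(back$config$tr_seconds, ds$config$tr_seconds)
  expect_error(write_dataset(ds, dir, format = "cifti"), "not supported")
  ds$runs <- list()
  expect_error(write_dataset(ds, dir), "no runs")
})

test_that("load_modeset validates shapes and reads TR metadata", {
  dir <- withr::local_tempdir()
  maps <- matrix(rnorm(3 * 10), 3, 10)
  run <- matrix(rnorm(10 * 20), 10, 20)
  netoverlap:::write_matrix(maps, file.path(dir, "maps.tsv"))
  netoverlap:::write_matrix(run, file.path(dir, "run.tsv"))
  jsonlite::write_json(list(tr_seconds = 1.0), file.path(dir, "side.json"),
                       auto_unbox = TRUE)
  ms <- load_modeset(file.path(dir, "maps.tsv"), file.path(dir, "run.tsv"),
                     sidecar_path = file.path(dir, "side.json"))
  expect_equal(ms$tr_seconds, 1.0)
  expect_equal(ms$modes$maps, maps, ignore_attr = TRUE)
  bad <- matrix(rnorm(8 * 20), 8, 20)
  netoverlap:::write_matrix(bad, file.path(dir, "bad.tsv"))
  expect_error(load_modeset(file.path(dir, "maps.tsv"), file.path(dir, "bad.tsv")),
               "mismatch")
})
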