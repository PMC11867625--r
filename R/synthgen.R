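#' Configuration for the synthetic grayordinate data generator
#'
#' Builds the configuration object consumed by [simulate_dataset()]. The
#' generator emulates the structure of surface-based resting-state data: `K`
#' weighted network spatial maps over `V` grayordinate-like vertices, several
#' runs of vertex timeseries per subject, and a designated pair of networks
#' whose shared territory is generated under a known, controllable overlap
#' mechanism. Every downstream stage of the package (vertex assignment,
#' semi-simulation, GLM model comparison) can therefore be validated by
#' checking that it recovers the planted mechanism.
#'
#' @param n_vertices Number of vertices `V`.
#' @param n_modes Number of network modes `K` (at least 2).
#' @param n_runs Number of runs per subject.
#' @param n_timepoints Timepoints `T` per run (at least 20).
#' @param tr_seconds Repetition time in seconds (default 0.72, the 3T HCP TR).
#' @param mechanism Ground-truth overlap mechanism; one of
#'   `"mixing_random"`, `"mixing_interdigitated"`, `"switching_block"`,
#'   `"coupling_additive"`, `"coupling_multiplicative"`.
#' @param block_len Block length in TRs for `switching_block` (default 50).
#' @param noise_sd Additive vertex noise sd, in units of the standardized
#'   network signal.
#' @param unique_region_size Vertices in each mode's unique territory.
#' @param overlap_region_size Vertices in the designated pair's shared
#'   territory (may be 0).
#' @param overlap_pair Integer pair `(i, j)` of modes sharing territory.
#' @param weight_high Map weight planted inside a mode's territory
#'   (default 1.5; comfortably above the default binarization threshold of 1).
#' @param smooth_len Width (TRs) of the boxcar kernel that temporally smooths
#'   the latent network timeseries; 1 disables smoothing. The default of 7 TRs
#'   concentrates latent power at low frequencies, mimicking the slow
#'   autocorrelated character of hemodynamic signals.
#' @param latent_corr Target pairwise correlation between latent network
#'   timeseries, in `[0, 1)`; default 0 (independent networks).
#' @param background_amp Half-width of the uniform distribution for
#'   off-territory map weights (default 0.005; small enough that summed
#'   bleed-through of the remaining modes stays below the default exclusion
#'   threshold).
#' @param seed Integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return An object of class `synth_config` (a validated list).
#' @seealso [simulate_dataset()], [simulate_cohort()]
#' @export
synth_config <- function(n_vertices = 500L,
                         n_modes = 12L,
                         n_runs = 4L,
                         n_timepoints = 500L,
                         tr_seconds = 0.72,
                         mechanism = c("coupling_additive", "mixing_random",
                                       "mixing_interdigitated", "switching_block",
                                       "coupling_multiplicative"),
                         block_len = 50L,
                         noise_sd = 0.3,
                         unique_region_size = 30L,
                         overlap_region_size = 25L,
                         overlap_pair = c(1L, 2L),
                         weight_high = 1.5,
                         seed = 1L,
                         smooth_len = 7L,
                         latent_corr = 0,
                         background_amp = 0.005) {
  mechanism <- match.arg(mechanism)
  stopifnot_scalar(n_vertices, "n_vertices", integerish = TRUE)
  stopifnot_scalar(n_modes, "n_modes", integerish = TRUE)
  stopifnot_scalar(n_runs, "n_runs", integerish = TRUE)
  stopifnot_scalar(n_timepoints, "n_timepoints", integerish = TRUE)
  stopifnot_scalar(tr_seconds, "tr_seconds")
  stopifnot_scalar(block_len, "block_len", integerish = TRUE)
  stopifnot_scalar(weight_high, "weight_high")
  stopifnot_scalar(smooth_len, "smooth_len", integerish = TRUE)
  stopifnot_scalar(unique_region_size, "unique_region_size", integerish = TRUE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (!is.numeric(overlap_region_size) || overlap_region_size < 0 ||
      overlap_region_size != round(overlap_region_size))
    stop("`overlap_region_size` must be a nonnegative whole number", call. = FALSE)
  if (n_modes < 2L) stop("`n_modes` must be at least 2", call. = FALSE)
  if (n_timepoints < 20L) stop("`n_timepoints` must be at least 20", call. = FALSE)
  if (latent_corr < 0 || latent_corr >= 1)
    stop("`latent_corr` must be in [0, 1)", call. = FALSE)
  overlap_pair <- as.integer(overlap_pair)
  if (length(overlap_pair) != 2L || overlap_pair[1] == overlap_pair[2] ||
      any(overlap_pair < 1L) || any(overlap_pair > n_modes))
    stop("`overlap_pair` must be two distinct mode indices in 1..n_modes",
         call. = FALSE)
  needed <- n_modes * unique_region_size + overlap_region_size
  if (needed > n_vertices)
    stop(sprintf(paste0("region sizing error: %d modes x %d unique vertices ",
                        "+ %d overlap vertices exceed n_vertices = %d"),
                 n_modes, unique_region_size, overlap_region_size, n_vertices),
         call. = FALSE)
  structure(list(
    n_vertices = as.integer(n_vertices), n_modes = as.integer(n_modes),
    n_runs = as.integer(n_runs), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, mechanism = mechanism,
    block_len = as.integer(block_len), noise_sd = noise_sd,
    unique_region_size = as.integer(unique_region_size),
    overlap_region_size = as.integer(overlap_region_size),
    overlap_pair = overlap_pair, weight_high = weight_high,
    smooth_len = as.integer(smooth_len), latent_corr = latent_corr,
    background_amp = background_amp, seed = as.integer(seed)
  ), class = "synth_config")
}

# deterministic territory layout: unique regions first, then the shared region
planted_regions <- function(config) {
  u <- config$unique_region_size
  unique_regions <- lapply(seq_len(config$n_modes),
                           function(k) ((k - 1L) * u + 1L):(k * u))
  n_o <- config$overlap_region_size
  overlap <- if (n_o > 0L) {
    (config$n_modes * u + 1L):(config$n_modes * u + n_o)
  } else integer(0)
  list(unique_regions = unique_regions, overlap = overlap)
}

#' Generate latent network timeseries
#'
#' Each of the `K` latent network timeseries is Gaussian white noise smoothed
#' with a circular boxcar kernel of `smooth_len` TRs and standardized to mean 0,
#' population sd 1. Smoothing concentrates spectral power at low frequencies
#' (for the default 7-TR kernel at TR 0.72 s the first spectral null is near
#' 0.2 Hz), which is what makes downstream spectral comparisons of
#' semi-simulated series meaningful. A nonzero `latent_corr` mixes a shared
#' component into every network to induce pairwise correlation.
#'
#' Uses the current RNG state; seed upstream (e.g. via [simulate_dataset()]).
#'
#' @param config A [synth_config()].
#' @return `K x T` matrix; each row has mean 0 and population sd 1.
#' @export
make_latent_series <- function(config) {
  K <- config$n_modes; T <- config$n_timepoints; w <- config$smooth_len
  if (T < w)
    stop(sprintf("sizing error: n_timepoints (%d) < smoothing kernel length (%d)",
                 T, w), call. = FALSE)
  smooth1 <- function(x) {
    if (w > 1L) x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L,
                                              circular = TRUE))
    x
  }
  rho <- config$latent_corr
  shared <- if (rho > 0) zscore(smooth1(stats::rnorm(T))) else NULL
  out <- matrix(0, K, T)
  for (k in seq_len(K)) {
    zk <- zscore(smooth1(stats::rnorm(T)))
    if (rho > 0) zk <- sqrt(1 - rho) * zk + sqrt(rho) * shared
    out[k, ] <- zscore(zk)
  }
  rownames(out) <- paste0("mode", seq_len(K))
  out
}

# per-TR network allegiance for the switching mechanism; starts with network 1
switch_schedule <- function(n_timepoints, block_len) {
  n_blocks <- ceiling(n_timepoints / block_len)
  rep(rep(c(1L, 2L), length.out = n_blocks), each = block_len)[seq_len(n_timepoints)]
}

#' Generate planted network spatial maps
#'
#' Builds `K x V` signed weight maps with known territories: each mode gets a
#' unique region at `weight_high`, the designated pair additionally shares an
#' overlap region where both modes carry `weight_high`, and all other weights
#' are small zero-mean background noise. For the
#' `mixing_interdigitated` mechanism the generating network of each overlap
#' vertex carries a slightly higher weight (`weight_high + 0.25`) so the
#' weight-argmax interdigitation rule reflects the planted alternation.
#'
#' Uses the current RNG state (background weights and, for `mixing_random`,
#' the planted donor assignment are random); seed upstream.
#'
#' @param config A [synth_config()].
#' @return List with `maps` (`K x V` matrix) and `membership` (planted
#'   per-vertex ground truth: unique regions, overlap vertices and — for the
#'   mixing mechanisms — each overlap vertex's generating network).
#' @export
make_spatial_maps <- function(config) {
  K <- config$n_modes; V <- config$n_vertices
  regions <- planted_regions(config)
  maps <- matrix(stats::runif(K * V, -config$background_amp, config$background_amp),
                 K, V)
  for (k in seq_len(K)) maps[k, regions$unique_regions[[k]]] <- config$weight_high
  ov <- regions$overlap
  i <- config$overlap_pair[1]; j <- config$overlap_pair[2]
  generator_net <- NULL
  if (length(ov) > 0L) {
    maps[i, ov] <- config$weight_high
    maps[j, ov] <- config$weight_high
    if (config$mechanism == "mixing_random") {
      n_o <- length(ov)
      pick1 <- sort(sample.int(n_o, ceiling(n_o / 2)))  # network 1 gets the extra
      generator_net <- rep(2L, n_o); generator_net[pick1] <- 1L
    } else if (config$mechanism == "mixing_interdigitated") {
      generator_net <- rep(c(1L, 2L), length.out = length(ov))
      maps[i, ov[generator_net == 1L]] <- config$weight_high + 0.25
      maps[j, ov[generator_net == 2L]] <- config$weight_high + 0.25
    }
  }
  rownames(maps) <- paste0("mode", seq_len(K))
  list(maps = maps,
       membership = list(unique_regions = regions$unique_regions,
                         overlap = ov, overlap_pair = c(i, j),
                         generator_net = generator_net))
}

#' Generate vertex timeseries under a ground-truth overlap mechanism
#'
#' Each unique-region vertex carries its network's latent timeseries; overlap
#' vertices carry a mechanism-specific combination of the designated pair's
#' latents; background vertices carry noise only. Additive Gaussian noise of
#' sd `noise_sd` is applied everywhere.
#'
#' Mechanism rules for an overlap vertex:
#' \describe{
#'   \item{mixing_random}{copies latent 1 or latent 2 according to the planted
#'     random half/half assignment (network 1 receives the extra vertex when
#'     the count is odd).}
#'   \item{mixing_interdigitated}{copies latent 1 or 2 alternating by vertex
#'     index (first overlap vertex from network 1).}
#'   \item{switching_block}{follows the block schedule: latent 1 for the first
#'     `block_len` TRs, then latent 2, and so on; trailing partial block kept.}
#'   \item{coupling_additive}{`latent1 + latent2`, rescaled to sd 1.}
#'   \item{coupling_multiplicative}{elementwise product of the zero-clamped
#'     latents, rescaled to sd 1.}
#' }
#'
#' Uses the current RNG state for noise; seed upstream.
#'
#' @param config A [synth_config()].
#' @param latents `K x T` latent matrix from [make_latent_series()].
#' @param membership Planted membership from [make_spatial_maps()].
#' @return `V x T` matrix of vertex timeseries.
#' @export
make_vertex_data <- function(config, latents, membership) {
  V <- config$n_vertices; T <- config$n_timepoints
  i <- config$overlap_pair[1]; j <- config$overlap_pair[2]
  data <- matrix(0, V, T)
  for (k in seq_len(config$n_modes))
    data[membership$unique_regions[[k]], ] <-
      matrix(latents[k, ], length(membership$unique_regions[[k]]), T, byrow = TRUE)
  ov <- membership$overlap
  if (length(ov) > 0L) {
    l1 <- latents[i, ]; l2 <- latents[j, ]
    sig <- switch(config$mechanism,
      mixing_random = ,
      mixing_interdigitated = {
        gen <- membership$generator_net
        out <- matrix(0, length(ov), T)
        out[gen == 1L, ] <- matrix(l1, sum(gen == 1L), T, byrow = TRUE)
        out[gen == 2L, ] <- matrix(l2, sum(gen == 2L), T, byrow = TRUE)
        out
      },
      switching_block = {
        sched <- switch_schedule(T, config$block_len)
        s <- ifelse(sched == 1L, l1, l2)
        matrix(s, length(ov), T, byrow = TRUE)
      },
      coupling_additive = {
        s <- zscore(l1 + l2)
        matrix(s, length(ov), T, byrow = TRUE)
      },
      coupling_multiplicative = {
        s <- zscore(pmax(l1, 0) * pmax(l2, 0))
        matrix(s, length(ov), T, byrow = TRUE)
      },
      stop(sprintf("unknown mechanism '%s'", config$mechanism), call. = FALSE)
    )
    data[ov, ] <- sig
  }
  if (config$noise_sd > 0)
    data <- data + config$noise_sd * matrix(stats::rnorm(V * T), V, T)
  data
}

#' Simulate a complete synthetic dataset for one subject
#'
#' Draws spatial maps, latent network timeseries per run, and vertex
#' timeseries under the configured ground-truth mechanism, all from the single
#' seed in `config`. The result carries the planted ground truth so recovery
#' can be checked exactly.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Object of class `synth_dataset`: a list with `config`, `maps`
#'   (`K x V`), `vertex_area` (length `V`, all 1 mm^2 by default), `runs`
#'   (list of `V x T` matrices), and `truth` (mechanism, planted membership,
#'   per-run latent series, and — for switching — the block schedule).
#' @export
#' @examples
#' ds <- simulate_dataset(synth_config(n_vertices = 80, n_modes = 3,
#'                                     n_runs = 1, n_timepoints = 60,
#'                                     unique_region_size = 10,
#'                                     overlap_region_size = 6, seed = 7))
#' dim(ds$maps); dim(ds$runs[[1]])
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  withr::with_seed(config$seed, {
    sm <- make_spatial_maps(config)
    latents <- vector("list", config$n_runs)
    runs <- vector("list", config$n_runs)
    for (r in seq_len(config$n_runs)) {
      latents[[r]] <- make_latent_series(config)
      runs[[r]] <- make_vertex_data(config, latents[[r]], sm$membership)
    }
    sched <- if (config$mechanism == "switching_block")
      switch_schedule(config$n_timepoints, config$block_len) else NULL
    structure(list(
      config = config, maps = sm$maps,
      vertex_area = rep(1, config$n_vertices),
      runs = runs,
      truth = list(mechanism = config$mechanism,
                   membership = sm$membership,
                   latent_series = latents,
                   switch_schedule = sched)
    ), class = "synth_dataset")
  })
}

#' Simulate a cohort of subjects
#'
#' @param config A [synth_config()] shared by all subjects.
#' @param n_subjects Number of subjects.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return List of `synth_dataset` objects (one per subject).
#' @export
simulate_cohort <- function(config, n_subjects = 20L, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, n_subjects))
  lapply(seq_len(n_subjects),
         function(s) simulate_dataset(config, seed = sub_seeds[s]))
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<synth_dataset> mechanism=%s  K=%d modes, V=%d vertices, ",
                     "%d run(s) x %d TRs (TR %.2fs), noise_sd=%.2f\n"),
              cfg$mechanism, cfg$n_modes, cfg$n_vertices, cfg$n_runs,
              cfg$n_timepoints, cfg$tr_seconds, cfg$noise_sd))
  invisible(x)
}
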