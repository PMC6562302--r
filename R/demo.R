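#' Simulated three-landscape study
#'
#' Builds a small synthetic study emulating the structure of an urban
#' movement-ecology data set: two territorial resident animals per landscape
#' class (natural fragment, suburban, highly urbanized), each monitored for
#' 91 days on a mixed collar schedule (one fix every 7.25 h, plus two
#' 30-h windows of 15-min fixes), with one injected teleportation spike per
#' animal, and a blockwise imperviousness raster placing each pair of
#' territories in its landscape class. Movement parameters per class are
#' the field-scale state values for coyotes: a 2-state
#' (encamped/moving) model in natural fragments and 3-state
#' (encamped/foraging/traveling) models in the suburban and highly
#' urbanized classes.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_days monitoring span in days.
#' @return list with `tracks` (named list of track data frames), `raster`
#'   (an `imperv_raster`), and `truth` (the generating `sim_config`s).
#' @export
demo_study <- function(seed = 1, n_days = 91) {
  class_specs <- list(
    natural_fragment = list(
      mu = c(7.4, 306), sigma = c(8.3, 238), zmass = c(0.01, 0.01),
      angle_mean = c(pi, 0), kappa = c(0.5, 1.5), delta = c(0.57, 0.43),
      anchors = list(c(0, 0), c(9000, 0)), level = 10),
    suburban = list(
      mu = c(7.6, 130, 528), sigma = c(7.2, 114, 218),
      zmass = c(0.01, 0.01, 0.01), angle_mean = c(pi, pi, 0),
      kappa = c(0.5, 0.7, 2), delta = c(0.56, 0.25, 0.19),
      anchors = list(c(30000, 0), c(39000, 0)), level = 35),
    highly_urbanized = list(
      mu = c(7.5, 122, 625), sigma = c(7.2, 114, 385),
      zmass = c(0.01, 0.01, 0.01), angle_mean = c(pi, pi, 0),
      kappa = c(0.5, 0.7, 2), delta = c(0.62, 0.19, 0.19),
      anchors = list(c(60000, 0), c(69000, 0)), level = 60))
  n_steps <- n_days * 96
  tracks <- list()
  truth <- list()
  aid <- 0
  for (cl in names(class_specs)) {
    spec <- class_specs[[cl]]
    K <- length(spec$mu)
    Gamma <- persistent_gamma(spec$delta, persistence = 0.8)
    for (j in seq_along(spec$anchors)) {
      aid <- aid + 1
      id <- sprintf("animal%02d", aid)
      cfg <- sim_config(K, spec$mu, spec$sigma, spec$zmass, spec$angle_mean,
                        spec$kappa, Gamma, fix_interval = 900,
                        n_steps = n_steps, start = spec$anchors[[j]],
                        seed = seed + aid, anchor = spec$anchors[[j]],
                        attraction = 0.3)
      sim <- simulate_territorial_track(cfg)
      fixes <- sim$fixes
      fixes$animal_id <- id
      ## mixed collar schedule: 7.25-h grid (every 29th 15-min fix) plus two
      ## dense 45-h windows of 15-min fixes
      dense <- c(2000:2180, 5000:5180)
      keep <- sort(unique(c(seq(1, nrow(fixes), by = 29), dense)))
      fixes <- fixes[keep, , drop = FALSE]
      ## one teleportation spike inside the first dense window
      spike_at <- which(keep == 2060)
      theta <- runif(1, -pi, pi)
      fixes$x[spike_at] <- fixes$x[spike_at] + 15000 * cos(theta)
      fixes$y[spike_at] <- fixes$y[spike_at] + 15000 * sin(theta)
      rownames(fixes) <- NULL
      tracks[[id]] <- fixes
      truth[[id]] <- list(class = cl, config = cfg)
    }
  }
  raster <- demo_raster(class_specs)
  list(tracks = tracks, raster = raster, truth = truth)
}

## Blockwise-uniform imperviousness raster covering the demo territories:
## columns are split at the midpoints between adjacent classes' territory
## clusters, and each block takes that class's level.
demo_raster <- function(class_specs) {
  levels <- vapply(class_specs, `[[`, numeric(1), "level")
  anchor_x <- lapply(class_specs, function(s)
    vapply(s$anchors, `[`, numeric(1), 1))
  xs <- unlist(anchor_x)
  extent <- c(min(xs) - 15000, max(xs) + 15000, -15000, 15000)
  cell <- 120
  r <- make_imperviousness_raster(extent, cell_size = cell,
                                  pattern = "uniform", level = levels[[1]])
  cells_x <- r$xmin + (seq_len(ncol(r$values)) - 0.5) * cell
  n_cl <- length(class_specs)
  cuts <- vapply(seq_len(n_cl - 1), function(i)
    (max(anchor_x[[i]]) + min(anchor_x[[i + 1]])) / 2, numeric(1))
  breaks <- c(-Inf, cuts, Inf)
  for (i in seq_len(n_cl)) {
    cols <- cells_x > breaks[i] & cells_x <= breaks[i + 1]
    r$values[, cols] <- levels[[i]]
  }
  r
}

#' Transition matrix with a prescribed stationary distribution
#'
#' `Gamma = persistence * I + (1 - persistence) * 1 delta'` is
#' row-stochastic with stationary distribution exactly `delta` and
#' self-transition probabilities near `persistence`, the sticky-state
#' structure typical of 15-min movement data.
#'
#' @param delta target stationary distribution (sums to 1).
#' @param persistence diagonal weight in `[0, 1)`.
#' @return K x K transition matrix.
#' @export
persistent_gamma <- function(delta, persistence = 0.8) {
  stopifnot(abs(sum(delta) - 1) < 1e-9, persistence >= 0, persistence < 1)
  K <- length(delta)
  persistence * diag(K) + (1 - persistence) *
    matrix(delta, K, K, byrow = TRUE)
}

#' Pipeline configuration for the simulated demo study
#'
#' The default configuration with a reduced starting grid (two starts per
#' model) and fewer permutations, sized for the demo's data volume.
#'
#' @param seed pipeline seed.
#' @return configuration list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 1) {
  cfg <- default_pipeline_config()
  cfg$seed <- seed
  cfg$hmm$kappa_candidates <- 0.5
  cfg$compare$n_permutations <- 199
  cfg
}
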