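#' Configuration for a simulated movement track
#'
#' Bundles the parameters of a K-state hidden Markov movement model together
#' with the sampling schedule used to generate synthetic GPS tracks. Step
#' lengths are zero-inflated gamma (parameterized by mean and SD in meters),
#' turning angles are von Mises.
#'
#' @param n_states number of behavioral states K (>= 1).
#' @param mu,sigma per-state gamma mean and SD of positive step lengths (m).
#' @param zmass per-state probability of a zero-length step, each in `[0, 1)`.
#' @param angle_mean per-state von Mises mean turning angle in `(-pi, pi]`.
#' @param kappa per-state von Mises concentration (>= 0).
#' @param Gamma K x K transition probability matrix; rows must sum to 1.
#' @param fix_interval time between fixes in seconds (default 900 = 15 min).
#' @param n_steps number of movement steps to simulate.
#' @param start numeric length-2 start position (m).
#' @param seed optional integer seed; identical seed and config give
#'   bit-identical tracks.
#' @param anchor optional length-2 anchor point for territorial attraction.
#' @param attraction mixture weight `w` in `[0, 1)` pulling headings toward
#'   the anchor (used by [simulate_territorial_track()]).
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_states, mu, sigma, zmass = rep(0, n_states),
                       angle_mean = rep(0, n_states),
                       kappa = rep(0, n_states), Gamma,
                       fix_interval = 900, n_steps = 1000,
                       start = c(0, 0), seed = NULL,
                       anchor = NULL, attraction = 0) {
  stopifnot(n_states >= 1, length(mu) == n_states, length(sigma) == n_states,
            length(zmass) == n_states, length(angle_mean) == n_states,
            length(kappa) == n_states)
  if (any(sigma <= 0)) stop("sigma must be positive for every state")
  if (any(mu <= 0)) stop("mu must be positive for every state")
  if (any(zmass < 0 | zmass >= 1)) stop("zmass must lie in [0, 1)")
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  Gamma <- as.matrix(Gamma)
  if (!all(dim(Gamma) == c(n_states, n_states)))
    stop("Gamma must be ", n_states, " x ", n_states)
  if (any(Gamma < 0) || any(abs(rowSums(Gamma) - 1) > 1e-12))
    stop("Gamma rows must be nonnegative and sum to 1 (tolerance 1e-12)")
  if (attraction < 0 || attraction >= 1)
    stop("attraction weight must lie in [0, 1)")
  if (fix_interval <= 0) stop("fix_interval must be positive")
  structure(list(n_states = n_states, mu = mu, sigma = sigma, zmass = zmass,
                 angle_mean = angle_mean, kappa = kappa, Gamma = Gamma,
                 fix_interval = fix_interval, n_steps = n_steps,
                 start = start, seed = seed, anchor = anchor,
                 attraction = attraction),
            class = "sim_config")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampling; `kappa = 0` reduces to the circular
#' uniform. Angles are returned wrapped to `(-pi, pi]`.
#'
#' @param n number of draws.
#' @param mean mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles.
#' @export
rvonmises <- function(n, mean = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out + mean)
}

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

## Internal: draw a Markov state sequence.
markov_states <- function(Gamma, n, start_state = NULL) {
  K <- nrow(Gamma)
  s <- integer(n)
  if (is.null(start_state)) {
    delta <- stationary_distribution(Gamma)
    s[1] <- sample.int(K, 1, prob = delta)
  } else {
    s[1] <- start_state
  }
  if (n > 1) {
    for (t in 2:n) s[t] <- sample.int(K, 1, prob = Gamma[s[t - 1], ])
  }
  s
}

sim_origin <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")

## Internal core shared by the plain and territorial simulators.
simulate_track_core <- function(config, start_state, territorial) {
  if (territorial) {
    if (is.null(config$anchor)) stop("anchor must be set for territorial simulation")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_steps
  K <- config$n_states
  if (is.null(start_state)) {
    if (K > 1 && max(abs(config$Gamma - diag(K))) < 1e-12)
      stop("Gamma is the identity: no unique stationary start; fix start_state")
    states <- markov_states(config$Gamma, n)
  } else {
    states <- markov_states(config$Gamma, n, start_state = start_state)
  }
  angles <- numeric(n)
  lens <- numeric(n)
  for (k in seq_len(K)) {
    idx <- which(states == k)
    if (!length(idx)) next
    angles[idx] <- rvonmises(length(idx), config$angle_mean[k], config$kappa[k])
    zero <- runif(length(idx)) < config$zmass[k]
    npos <- sum(!zero)
    shape <- config$mu[k]^2 / config$sigma[k]^2
    scale <- config$sigma[k]^2 / config$mu[k]
    lens[idx[!zero]] <- rgamma(npos, shape = shape, scale = scale)
    lens[idx[zero]] <- 0
  }
  w <- if (territorial) config$attraction else 0
  heading0 <- runif(1, -pi, pi)
  x <- numeric(n + 1)
  y <- numeric(n + 1)
  x[1] <- config$start[1]
  y[1] <- config$start[2]
  heading <- heading0
  if (territorial) pull <- runif(n) < w
  for (t in seq_len(n)) {
    if (territorial && pull[t]) {
      bearing <- atan2(config$anchor[2] - y[t], config$anchor[1] - x[t])
      heading <- wrap_angle(bearing + angles[t])
    } else {
      heading <- wrap_angle(heading + angles[t])
    }
    x[t + 1] <- x[t] + lens[t] * cos(heading)
    y[t + 1] <- y[t] + lens[t] * sin(heading)
  }
  times <- sim_origin + config$fix_interval * (0:n)
  fixes <- data.frame(animal_id = "sim", timestamp = times, x = x, y = y,
                      true_state = c(NA_integer_, states),
                      stringsAsFactors = FALSE)
  structure(list(fixes = fixes, states = states, step_lengths = lens,
                 turning_draws = angles, config = config),
            class = "sim_track")
}

#' Simulate a track from a K-state hidden Markov movement model
#'
#' States follow the Markov chain started from the stationary distribution of
#' the transition matrix (or from `start_state` when given). At each step the
#' model draws a turning angle (von Mises) that increments the current
#' heading, and a step length that is zero with the state's zero-mass
#' probability and gamma-distributed otherwise. The initial heading is
#' uniform. Positions are the cumulative sum of headings times step lengths.
#'
#' @param config a [sim_config()].
#' @param start_state optional fixed initial state (bypasses the stationary
#'   start; required when `Gamma` is the identity).
#' @return a `sim_track`: list with `fixes` (data frame of
#'   timestamp/x/y/true_state), the true `states`, `step_lengths`, the raw
#'   turning-angle draws, and the config.
#' @export
simulate_hmm_track <- function(config, start_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  simulate_track_core(config, start_state, territorial = FALSE)
}

#' Simulate a territorial (anchored) movement track
#'
#' As [simulate_hmm_track()], but at each step, with probability equal to the
#' attraction weight `w`, the heading is re-aimed at the anchor point (the
#' drawn turning angle becomes a deviation around the bearing to the anchor)
#' rather than accumulated. With `w > 0` the excursion distance from the
#' anchor is stochastically bounded, giving the bounded space use a resident
#' territorial animal shows; with `w = 0` the output is identical to
#' [simulate_hmm_track()] under the same seed.
#'
#' @inheritParams simulate_hmm_track
#' @return a `sim_track`.
#' @export
simulate_territorial_track <- function(config, start_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$attraction == 0) return(simulate_hmm_track(config, start_state))
  simulate_track_core(config, start_state, territorial = TRUE)
}

#' Build a GPS fix schedule with Bernoulli dropout
#'
#' Regular grid of fix times over `duration` seconds at `interval` seconds,
#' with each fix independently dropped with probability `dropout_prob`
#' (emulating failed fix attempts). A 24-h schedule at 15-min intervals has
#' 97 grid points.
#'
#' @param duration schedule span in seconds.
#' @param interval fix interval in seconds (> 0).
#' @param dropout_prob per-fix dropout probability in `[0, 1)`.
#' @param seed optional seed for the dropout draw.
#' @param origin POSIXct start time of the schedule.
#' @return POSIXct vector of retained fix times.
#' @export
make_fix_schedule <- function(duration, interval, dropout_prob = 0,
                              seed = NULL, origin = sim_origin) {
  if (interval <= 0) stop("interval must be positive")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, duration, by = interval)
  keep <- runif(length(grid)) >= dropout_prob
  origin + grid[keep]
}

#' Inject out-and-back position spikes into a track
#'
#' Displaces `n_spikes` randomly chosen interior fixes by `spike_distance`
#' meters in a uniform random direction, producing the teleportation
#' artifacts (two successive impossible speeds) that the cleaning stage must
#' remove. First and last fixes are never displaced.
#'
#' @param track a track data frame (`timestamp`, `x`, `y`) or `sim_track`.
#' @param n_spikes number of fixes to displace (< number of interior fixes).
#' @param spike_distance displacement in meters (> 0).
#' @param seed optional seed.
#' @return the track data frame with displaced coordinates and an attribute
#'   `spike_indices` listing the displaced row indices.
#' @export
inject_position_errors <- function(track, n_spikes, spike_distance,
                                   seed = NULL) {
  fixes <- as_track_df(track)
  if (spike_distance <= 0) stop("spike_distance must be positive")
  n <- nrow(fixes)
  interior <- seq_len(n)[-c(1, n)]
  if (n_spikes >= length(interior))
    stop("n_spikes must be smaller than the number of interior fixes")
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample(interior, n_spikes))
  if (n_spikes > 0) {
    theta <- runif(n_spikes, -pi, pi)
    fixes$x[idx] <- fixes$x[idx] + spike_distance * cos(theta)
    fixes$y[idx] <- fixes$y[idx] + spike_distance * sin(theta)
  }
  attr(fixes, "spike_indices") <- idx
  fixes
}

#' Generate a synthetic surface-imperviousness raster
#'
#' Gridded percent-imperviousness surface (values 0-100) standing in for a
#' national land-cover imperviousness product, on a regular grid of square
#' cells (30 m by default, the resolution of such products).
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param cell_size cell edge length in meters.
#' @param pattern `"uniform"` (all cells equal `level`), `"gradient"`
#'   (linear ramp from 0 at the west edge to `level` at the east edge), or
#'   `"patches"` (seeded high-imperviousness blobs at `level` on a low
#'   background).
#' @param level imperviousness percentage in `[0, 100]`.
#' @param seed optional seed (used by `"patches"`).
#' @param n_patches number of blobs for the `"patches"` pattern.
#' @param background background level for `"patches"`.
#' @return an `imperv_raster`: list with `values` (ny x nx matrix, row 1 at
#'   the south edge), `xmin`, `ymin`, `cell_size`.
#' @export
make_imperviousness_raster <- function(extent, cell_size = 30,
                                       pattern = c("uniform", "gradient", "patches"),
                                       level = 50, seed = NULL,
                                       n_patches = 5, background = 5) {
  pattern <- match.arg(pattern)
  stopifnot(length(extent) == 4)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans")
  if (level < 0 || level > 100) stop("level must lie in [0, 100]")
  nx <- max(1L, ceiling((extent[2] - extent[1]) / cell_size))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / cell_size))
  xc <- extent[1] + (seq_len(nx) - 0.5) * cell_size
  yc <- extent[3] + (seq_len(ny) - 0.5) * cell_size
  values <- switch(pattern,
    uniform = matrix(level, ny, nx),
    gradient = {
      ramp <- if (nx == 1) level else level * (seq_len(nx) - 1) / (nx - 1)
      matrix(ramp, ny, nx, byrow = TRUE)
    },
    patches = {
      if (!is.null(seed)) set.seed(seed)
      v <- matrix(background, ny, nx)
      cx <- runif(n_patches, extent[1], extent[2])
      cy <- runif(n_patches, extent[3], extent[4])
      r <- runif(n_patches, 2, 6) * cell_size
      for (p in seq_len(n_patches)) {
        d2 <- outer(yc, xc, function(Y, X) (X - cx[p])^2 + (Y - cy[p])^2)
        v[d2 <= r[p]^2] <- level
      }
      v
    })
  structure(list(values = values, xmin = extent[1], ymin = extent[3],
                 cell_size = cell_size),
            class = "imperv_raster")
}

#' Cell-center coordinates of an imperviousness raster
#' @param raster an `imperv_raster`.
#' @return data frame with `x`, `y`, `value` for every cell.
#' @export
raster_cells <- function(raster) {
  stopifnot(inherits(raster, "imperv_raster"))
  ny <- nrow(raster$values)
  nx <- ncol(raster$values)
  xc <- raster$xmin + (seq_len(nx) - 0.5) * raster$cell_size
  yc <- raster$ymin + (seq_len(ny) - 0.5) * raster$cell_size
  data.frame(x = rep(xc, each = ny), y = rep(yc, nx),
             value = as.vector(raster$values))
}
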