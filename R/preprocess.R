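#' Per-segment movement speeds
#'
#' Euclidean distance between successive fixes divided by elapsed time,
#' reported in km/h (the units used for telemetry screening thresholds).
#'
#' @param track track-like object with at least 2 fixes.
#' @return numeric vector of length `n_fixes - 1`.
#' @export
compute_speeds <- function(track) {
  fixes <- as_track_df(track)
  if (nrow(fixes) < 2) stop("need at least 2 fixes to compute speeds")
  dt_h <- as.numeric(diff(fixes$timestamp), units = "hours")
  if (any(dt_h <= 0)) stop("zero or negative elapsed time between fixes")
  d_km <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2) / 1000
  d_km / dt_h
}

#' Flag fixes adjacent to fast segments for review
#'
#' Advisory screening: a fix is flagged when either adjacent segment exceeds
#' `review_kmh`. Nothing is removed; flags mark the locations a human analyst
#' would inspect. The automatic removal rule ([remove_spikes()]) only fires
#' at much higher speeds, so its removals are always a subset of these flags
#' when `review_kmh` is below the removal threshold.
#'
#' @param track track-like object.
#' @param review_kmh review threshold in km/h (default 10).
#' @return integer vector of flagged fix indices (possibly empty).
#' @export
flag_speed_outliers <- function(track, review_kmh = 10) {
  fixes <- as_track_df(track)
  v <- compute_speeds(fixes)
  fast <- which(v > review_kmh)
  sort(unique(c(fast, fast + 1L)))
}

#' Remove teleportation spikes by the impossible-speed rule
#'
#' Iteratively removes interior fixes implicated in segments faster than
#' `hard_kmh` (default 50 km/h, a speed no coyote attains). A fix is removed
#' when it is the apex of an out-and-back spike: both adjacent segments
#' exceed the threshold, or one does and bridging directly between its
#' neighbors brings the speed below the threshold. The procedure repeats
#' until no such fix remains, so it is idempotent.
#'
#' @param track track-like object with at least 3 fixes.
#' @param hard_kmh removal threshold in km/h.
#' @return the cleaned track data frame with attribute `removal_log`, a data
#'   frame of removed fixes (original index, timestamp, coordinates, reason).
#' @export
remove_spikes <- function(track, hard_kmh = 50) {
  fixes <- as_track_df(track)
  if (nrow(fixes) < 3) stop("need at least 3 fixes")
  orig_index <- seq_len(nrow(fixes))
  log_rows <- list()
  repeat {
    n <- nrow(fixes)
    if (n < 2) stop("spike removal reduced the track below 2 fixes")
    if (n < 3) break
    v <- compute_speeds(fixes)
    candidate <- NA_integer_
    reason <- NA_character_
    ## out-and-back apexes (both adjacent segments impossible) are removed
    ## before any single-sided bridging candidate, so a spike never drags a
    ## legitimate neighboring fix out with it
    for (i in 2:(n - 1)) {
      if (v[i - 1] > hard_kmh && v[i] > hard_kmh) {
        candidate <- i
        reason <- "both adjacent segments exceed threshold"
        break
      }
    }
    if (is.na(candidate)) {
      for (i in 2:(n - 1)) {
        if (v[i - 1] <= hard_kmh && v[i] <= hard_kmh) next
        dt_h <- as.numeric(fixes$timestamp[i + 1] - fixes$timestamp[i - 1],
                           units = "hours")
        bridge <- sqrt((fixes$x[i + 1] - fixes$x[i - 1])^2 +
                       (fixes$y[i + 1] - fixes$y[i - 1])^2) / 1000 / dt_h
        if (bridge <= hard_kmh) {
          candidate <- i
          reason <- "removal drops bridging speed below threshold"
          break
        }
      }
    }
    if (is.na(candidate)) break
    log_rows[[length(log_rows) + 1]] <- data.frame(
      index = orig_index[candidate],
      timestamp = fixes$timestamp[candidate],
      x = fixes$x[candidate], y = fixes$y[candidate],
      reason = reason, stringsAsFactors = FALSE)
    fixes <- fixes[-candidate, , drop = FALSE]
    orig_index <- orig_index[-candidate]
  }
  rownames(fixes) <- NULL
  attr(fixes, "removal_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(index = integer(), timestamp = sim_origin[0],
               x = numeric(), y = numeric(), reason = character(),
               stringsAsFactors = FALSE)
  }
  fixes
}

#' Subsample a track to a coarser fix schedule
#'
#' Keeps, for each slot of a regular time grid anchored at the first fix, the
#' fix nearest the grid time (within `tolerance`), at most one fix per slot.
#' The default target reproduces the long-term collar schedule of one fix
#' about every 7.25 h used for home-range estimation.
#'
#' @param track track-like object spanning at least `target_interval`.
#' @param target_interval desired interval in seconds (default 7.25 h).
#' @param tolerance maximum offset from a grid time in seconds (default 30
#'   min).
#' @return subsampled track data frame (timestamps are a subset of the
#'   input's).
#' @export
subsample_track <- function(track, target_interval = 7.25 * 3600,
                            tolerance = 30 * 60) {
  fixes <- as_track_df(track)
  span <- as.numeric(fixes$timestamp[nrow(fixes)] - fixes$timestamp[1],
                     units = "secs")
  if (span < target_interval)
    stop("track must span at least one target interval")
  t0 <- as.numeric(fixes$timestamp[1])
  rel <- as.numeric(fixes$timestamp) - t0
  grid <- seq(0, span, by = target_interval)
  keep <- integer(0)
  used <- logical(nrow(fixes))
  for (g in grid) {
    off <- abs(rel - g)
    off[used] <- Inf
    i <- which.min(off)
    if (off[i] <= tolerance) {
      keep <- c(keep, i)
      used[i] <- TRUE
    }
  }
  if (!length(keep)) stop("no fixes matched the subsampling grid")
  out <- fixes[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract bursts of consecutive high-frequency fixes
#'
#' Splits a track into maximal runs whose inter-fix gaps stay within
#' `nominal_interval` plus or minus `tolerance`, then keeps runs lasting at
#' least `min_duration`. The defaults select at least 24 h of consecutive
#' 15-min fixes, the unit of movement-model analysis.
#'
#' @param track track-like object.
#' @param nominal_interval expected fix spacing in seconds (default 15 min).
#' @param tolerance allowed deviation per gap in seconds (default 2 min).
#' @param min_duration minimum burst span in seconds (default 24 h).
#' @return list of `burst` objects (fix data frame, burst id, duration in
#'   hours); possibly empty.
#' @export
extract_bursts <- function(track, nominal_interval = 15 * 60,
                           tolerance = 2 * 60, min_duration = 24 * 3600) {
  fixes <- as_track_df(track)
  n <- nrow(fixes)
  if (n < 2) return(list())
  gaps <- as.numeric(diff(fixes$timestamp), units = "secs")
  ok <- abs(gaps - nominal_interval) <= tolerance
  breaks <- c(0, which(!ok), n)
  bursts <- list()
  for (b in seq_len(length(breaks) - 1)) {
    idx <- (breaks[b] + 1):breaks[b + 1]
    if (length(idx) < 2) next
    span <- as.numeric(fixes$timestamp[idx[length(idx)]] - fixes$timestamp[idx[1]],
                       units = "secs")
    if (span < min_duration) next
    bursts[[length(bursts) + 1]] <- structure(
      list(fixes = fixes[idx, , drop = FALSE],
           burst_id = paste0(fixes$animal_id[idx[1]], "_b", length(bursts) + 1),
           duration_h = span / 3600),
      class = "burst")
  }
  bursts
}

#' Step lengths and turning angles of a burst
#'
#' Converts a burst of fixes into the bivariate observation series of the
#' movement model: step length `L_t` (m) between fixes t and t+1, and
#' turning angle `phi_t`, the signed change in movement heading wrapped to
#' `(-pi, pi]` (left turns positive). The first angle is missing, as is any
#' angle adjacent to a zero-length step (the heading there is undefined).
#'
#' @param burst a `burst` or track-like object with at least 3 fixes.
#' @return a `step_series`: list with `L`, `phi`, `burst_id`.
#' @export
steps_and_angles <- function(burst) {
  fixes <- if (inherits(burst, "burst")) burst$fixes else as_track_df(burst)
  burst_id <- if (inherits(burst, "burst")) burst$burst_id else "track"
  n <- nrow(fixes)
  if (n < 3) stop("need at least 3 fixes to form steps and angles")
  dx <- diff(fixes$x)
  dy <- diff(fixes$y)
  L <- sqrt(dx^2 + dy^2)
  heading <- atan2(dy, dx)
  m <- length(L)
  phi <- rep(NA_real_, m)
  for (t in 2:m) {
    if (L[t] > 0 && L[t - 1] > 0) {
      phi[t] <- wrap_angle(heading[t] - heading[t - 1])
    }
  }
  structure(list(L = L, phi = phi, burst_id = burst_id), class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat("step_series", x$burst_id, ":", length(x$L), "steps,",
      sum(is.na(x$phi)), "missing angles\n")
  invisible(x)
}
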