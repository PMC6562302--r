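#' Behavioral time budget of decoded steps
#'
#' Proportion of decoded steps in each state, pooled over bursts.
#'
#' @param decoded a `decoded_burst`, list of them, or integer state vector(s).
#' @param K number of states (inferred from the data when missing).
#' @param labels optional state labels used to name the proportions.
#' @return list with `proportions` (named, summing to 1) and `n_steps`.
#' @export
time_budget <- function(decoded, K = NULL, labels = NULL) {
  if (inherits(decoded, "decoded_burst") || is.numeric(decoded))
    decoded <- list(decoded)
  states <- unlist(lapply(decoded, function(d) {
    if (inherits(d, "decoded_burst")) d$states else as.integer(d)
  }))
  if (!length(states)) stop("no decoded steps")
  if (is.null(K)) K <- max(states)
  prop <- tabulate(states, nbins = K) / length(states)
  names(prop) <- if (!is.null(labels)) labels else paste0("state", seq_len(K))
  list(proportions = prop, n_steps = length(states))
}

#' Foraging-to-traveling time ratio
#'
#' Ratio of time spent foraging to time spent traveling under a 3-state
#' model, computed on unrounded proportions.
#'
#' @param budget a [time_budget()] whose proportions are named with the
#'   3-state labels (`encamped`, `foraging`, `traveling`).
#' @return the ratio.
#' @export
foraging_travel_ratio <- function(budget) {
  prop <- budget$proportions
  if (!all(c("foraging", "traveling") %in% names(prop)))
    stop("budget must have foraging and traveling proportions (3-state labels)")
  if (prop[["traveling"]] == 0)
    stop("traveling proportion is zero; ratio undefined")
  prop[["foraging"]] / prop[["traveling"]]
}

#' Permutation test for between-landscape differences
#'
#' Two-sided permutation test on the difference of group means for every
#' pair of groups. With `method = "exact"` all label assignments are
#' enumerated; otherwise `n_permutations` random shuffles are drawn and
#' `p = (1 + #(|T_perm| >= |T_obs|)) / (1 + n_permutations)`.
#'
#' @param values_by_group named list of numeric vectors (>= 2 values each).
#' @param n_permutations number of random permutations.
#' @param seed optional seed.
#' @param method `"permutation"` or `"exact"` (enumeration; feasible for
#'   small samples).
#' @return data frame with one row per group pair: groups, observed
#'   difference of means, and p-value.
#' @export
compare_groups <- function(values_by_group, n_permutations = 9999,
                           seed = NULL, method = c("permutation", "exact")) {
  method <- match.arg(method)
  stopifnot(length(values_by_group) >= 2,
            all(vapply(values_by_group, length, 1L) >= 2))
  if (!is.null(seed)) set.seed(seed)
  gnames <- names(values_by_group)
  if (is.null(gnames)) gnames <- paste0("group", seq_along(values_by_group))
  pairs <- t(combn(length(values_by_group), 2))
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- values_by_group[[pairs[r, 1]]]
    b <- values_by_group[[pairs[r, 2]]]
    obs <- mean(a) - mean(b)
    pooled <- c(a, b)
    na <- length(a)
    if (method == "exact") {
      idx <- combn(length(pooled), na)
      stats <- apply(idx, 2, function(i)
        mean(pooled[i]) - mean(pooled[-i]))
      p <- mean(abs(stats) >= abs(obs) - 1e-12)
    } else {
      stats <- replicate(n_permutations, {
        i <- sample(length(pooled), na)
        mean(pooled[i]) - mean(pooled[-i])
      })
      p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (1 + n_permutations)
    }
    data.frame(group_a = gnames[pairs[r, 1]], group_b = gnames[pairs[r, 2]],
               diff_means = obs, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-landscape summary of space use and movement behavior
#'
#' Aggregates, for each landscape class: mean and SE (sample SD / sqrt(n))
#' of home-range and core areas and complexity, the range of noncontiguous
#' polygon counts, per-state step-length summaries of the decoded steps,
#' the time budget, and (for 3-state models) the foraging:traveling ratio.
#' SE is reported as `NA` for a single home range.
#'
#' @param hr_table data frame of home ranges (one row per estimate-level)
#'   with columns `class`, `animal_id`, `level`, `area_km2`, `complexity`,
#'   `components`.
#' @param fits_by_class named list of `hmm_fit` per class (the selected
#'   model), or `NULL` entries.
#' @param decoded_by_class named list (per class) of lists of
#'   `decoded_burst`.
#' @param series_by_class named list (per class) of lists of `step_series`
#'   aligned with `decoded_by_class`.
#' @return list with `space_use` (one row per class) and `movement` (one row
#'   per class-state).
#' @export
summarize_landscape <- function(hr_table, fits_by_class = NULL,
                                decoded_by_class = NULL,
                                series_by_class = NULL) {
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  classes <- sort(unique(hr_table$class))
  space_use <- do.call(rbind, lapply(classes, function(cl) {
    hr <- hr_table[hr_table$class == cl & hr_table$level == 0.95, ]
    core <- hr_table[hr_table$class == cl & hr_table$level == 0.50, ]
    data.frame(class = cl, n_home_ranges = nrow(hr),
               hr_mean_km2 = mean(hr$area_km2), hr_se_km2 = se(hr$area_km2),
               core_mean_km2 = if (nrow(core)) mean(core$area_km2) else NA_real_,
               core_se_km2 = se(core$area_km2),
               complexity_mean = mean(hr$complexity),
               complexity_se = se(hr$complexity),
               core_complexity_mean = if (nrow(core)) mean(core$complexity) else NA_real_,
               core_complexity_se = se(core$complexity),
               components_min = if (nrow(hr)) min(hr$components) else NA_integer_,
               components_max = if (nrow(hr)) max(hr$components) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  movement <- NULL
  if (!is.null(fits_by_class)) {
    rows <- list()
    for (cl in names(fits_by_class)) {
      fit <- fits_by_class[[cl]]
      if (is.null(fit)) next
      decoded <- decoded_by_class[[cl]]
      series <- series_by_class[[cl]]
      labels <- state_labels(fit$params)
      states <- unlist(lapply(decoded, `[[`, "states"))
      L <- unlist(lapply(series, `[[`, "L"))
      tb <- time_budget(decoded, K = fit$K, labels = labels)
      ratio <- if (all(c("foraging", "traveling") %in% labels) &&
                   tb$proportions[["traveling"]] > 0)
        foraging_travel_ratio(tb) else NA_real_
      for (k in seq_len(fit$K)) {
        Lk <- L[states == k]
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, state = labels[k], n_steps = length(Lk),
          step_mean_m = mean(Lk), step_sd_m = sd(Lk),
          step_min_m = if (length(Lk)) min(Lk) else NA_real_,
          step_max_m = if (length(Lk)) max(Lk) else NA_real_,
          time_spent = tb$proportions[[k]],
          foraging_travel_ratio = ratio, stringsAsFactors = FALSE)
      }
    }
    movement <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(space_use = space_use, movement = movement)
}

#' Run the full movement and space-use analysis
#'
#' Orchestrates: spike cleaning; home-range estimation (a-LoCoH and MCP at
#' the 50% and 95% isopleths from 7.25-h subsampled fixes, for animals
#' monitored more than `min_days` days), complexity, landscape
#' classification, and social-group deduplication; burst extraction and
#' movement-model fitting (each candidate number of states, per landscape
#' class, pooled across individuals); model assessment (plausibility,
#' predictive power, AIC) and selection; Viterbi decoding; and the
#' per-landscape behavioral summaries and permutation comparisons. The run
#' is a pure function of (tracks, raster, config, seed).
#'
#' @param tracks named list of track data frames (one per animal; names are
#'   animal ids).
#' @param raster an `imperv_raster` covering the tracks.
#' @param config list of settings; see [default_pipeline_config()].
#' @return a report bundle: home-range table, model table, per-class fits
#'   and decoded bursts, summaries, group comparisons, and a stage log.
#' @export
run_pipeline <- function(tracks, raster, config = default_pipeline_config()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  set.seed(cfg$seed)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  ## stage 1: cleaning
  cleaned <- lapply(names(tracks), function(id) {
    tr <- as_track_df(tracks[[id]])
    tr$animal_id <- id
    flags <- flag_speed_outliers(tr, cfg$clean$review_kmh)
    out <- remove_spikes(tr, cfg$clean$hard_kmh)
    note("clean ", id, ": ", length(flags), " fixes flagged >",
         cfg$clean$review_kmh, " km/h, ",
         nrow(attr(out, "removal_log")), " removed >", cfg$clean$hard_kmh,
         " km/h")
    out
  })
  names(cleaned) <- names(tracks)

  ## stage 2: home ranges, complexity, landscape class
  hr_rows <- list()
  hr95 <- list()
  animal_class <- character(0)
  for (id in names(cleaned)) {
    tr <- cleaned[[id]]
    span_days <- as.numeric(tr$timestamp[nrow(tr)] - tr$timestamp[1],
                            units = "days")
    if (span_days <= cfg$homerange$min_days && !cfg$homerange$allow_short) {
      note("homerange ", id, ": skipped, monitored ", round(span_days, 1),
           " days (requires > ", cfg$homerange$min_days, ")")
      next
    }
    sub <- subsample_track(tr, cfg$subsample$interval, cfg$subsample$tolerance)
    pts <- cbind(sub$x, sub$y)
    lo <- alocoh(pts, isopleth_targets = cfg$homerange$targets,
                 animal_id = id, coverage_days = span_days)
    names(lo) <- as.character(cfg$homerange$targets)
    cls <- classify_landscape(lo[["0.95"]], raster)
    animal_class[id] <- cls$class
    for (tg in cfg$homerange$targets) {
      hr_l <- lo[[as.character(tg)]]
      hr_m <- mcp(pts, percent = tg * 100, animal_id = id,
                  coverage_days = span_days)
      cx <- withCallingHandlers(
        complexity_index(hr_m$area_km2, hr_l$area_km2),
        warning = function(w) {
          note("complexity ", id, " level ", tg, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      hr_rows[[length(hr_rows) + 1]] <- data.frame(
        animal_id = id, class = cls$class, level = tg,
        achieved = hr_l$achieved, area_km2 = hr_l$area_km2,
        mcp_area_km2 = hr_m$area_km2, complexity = cx,
        components = hr_l$components, coverage_days = span_days,
        mean_imperviousness = cls$mean_imperviousness,
        stringsAsFactors = FALSE)
    }
    hr95[[id]] <- lo[["0.95"]]
    note("homerange ", id, ": class ", cls$class, ", 95% LoCoH ",
         round(lo[["0.95"]]$area_km2, 3), " km2")
  }
  hr_table <- if (length(hr_rows)) do.call(rbind, hr_rows) else
    data.frame()

  ## stage 2b: social-group deduplication at the 95% isopleth
  if (length(hr95) >= 2) {
    dd <- dedup_homeranges(hr95, threshold = cfg$homerange$overlap_threshold)
    dropped_ids <- names(hr95)[dd$dropped_idx]
    if (length(dropped_ids)) {
      note("dedup: dropped ", paste(dropped_ids, collapse = ", "),
           " (>90% overlap, smaller temporal coverage)")
      hr_table <- hr_table[!hr_table$animal_id %in% dropped_ids, ]
      hr95 <- hr95[setdiff(names(hr95), dropped_ids)]
    }
  }

  ## stage 3: bursts and observation series per landscape class
  series_by_class <- list()
  for (id in names(cleaned)) {
    cl <- animal_class[id]
    if (is.na(cl)) next
    bursts <- extract_bursts(cleaned[[id]], cfg$bursts$interval,
                             cfg$bursts$tolerance, cfg$bursts$min_duration)
    if (!length(bursts)) next
    ser <- lapply(bursts, steps_and_angles)
    for (s in seq_along(ser)) ser[[s]]$burst_id <- paste0(id, "_b", s)
    series_by_class[[cl]] <- c(series_by_class[[cl]], ser)
    note("bursts ", id, ": ", length(bursts), " burst(s), ",
         sum(vapply(ser, function(s) length(s$L), 1L)), " steps")
  }

  ## stage 4: fit candidate state numbers per class, assess, select
  model_rows <- list()
  fits_by_class <- list()
  decoded_by_class <- list()
  for (cl in names(series_by_class)) {
    ser <- series_by_class[[cl]]
    fits <- list()
    for (K in cfg$hmm$n_states) {
      grid <- build_start_grid(ser, K,
        step_quantile_levels = cfg$hmm$step_quantile_levels[[as.character(K)]],
        angle_mean_candidates = cfg$hmm$angle_mean_candidates,
        kappa_candidates = cfg$hmm$kappa_candidates)
      fit <- suppressWarnings(
        fit_hmm(ser, K, start_grid = grid, maxit = cfg$hmm$maxit,
                separation_ratio = cfg$hmm$separation_ratio))
      fits[[as.character(K)]] <- fit
      model_rows[[length(model_rows) + 1]] <- data.frame(
        class = cl, K = K, loglik = fit$loglik, aic = fit$aic, p = fit$p,
        predictive_power = fit$predictive_power$index,
        strong = fit$predictive_power$strong,
        plausible = fit$plausibility$plausible,
        reasons = paste(fit$plausibility$reasons, collapse = "; "),
        stringsAsFactors = FALSE)
      note("fit ", cl, " K=", K, ": AIC ", round(fit$aic, 1),
           if (!fit$plausibility$plausible)
             " [implausible, excluded from report body]" else "")
    }
    ok <- Filter(function(f) f$plausibility$plausible &&
                   f$predictive_power$strong, fits)
    if (!length(ok)) {
      note("select ", cl, ": no plausible and strongly predictive model")
      fits_by_class[cl] <- list(NULL)
      next
    }
    best <- ok[[which.min(vapply(ok, `[[`, 1, "aic"))]]
    note("select ", cl, ": ", best$K, "-state model (AIC ",
         round(best$aic, 1), ")")
    fits_by_class[[cl]] <- best
    decoded_by_class[[cl]] <- decode(ser, best$params)
  }
  model_table <- if (length(model_rows)) do.call(rbind, model_rows) else
    data.frame()

  ## stage 5: summaries and group comparisons
  summaries <- if (nrow(hr_table))
    summarize_landscape(hr_table, fits_by_class, decoded_by_class,
                        series_by_class) else NULL
  comparisons <- NULL
  if (nrow(hr_table)) {
    hr95_tab <- hr_table[hr_table$level == 0.95, ]
    by_class <- split(hr95_tab$complexity, hr95_tab$class)
    by_class <- by_class[vapply(by_class, length, 1L) >= 2]
    if (length(by_class) >= 2) {
      comparisons <- compare_groups(by_class,
                                    n_permutations = cfg$compare$n_permutations)
      comparisons$metric <- "complexity_95"
    }
  }

  structure(list(hr_table = hr_table, model_table = model_table,
                 fits_by_class = fits_by_class,
                 decoded_by_class = decoded_by_class,
                 series_by_class = series_by_class,
                 homeranges_95 = hr95, summaries = summaries,
                 comparisons = comparisons, log = log, config = cfg),
            class = "movement_report")
}

#' Default pipeline configuration
#'
#' Cleaning at the 10 km/h review and 50 km/h removal thresholds;
#' subsampling to 7.25 h for home ranges; 15-min bursts of at least 24 h for
#' movement models; 50%/95% isopleths; the > 90-day monitoring requirement;
#' 2-, 3- and 4-state candidate models.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(seed = 1,
       clean = list(review_kmh = 10, hard_kmh = 50),
       subsample = list(interval = 7.25 * 3600, tolerance = 30 * 60),
       bursts = list(interval = 15 * 60, tolerance = 2 * 60,
                     min_duration = 24 * 3600),
       homerange = list(targets = c(0.5, 0.95), min_days = 90,
                        allow_short = FALSE, overlap_threshold = 0.90),
       hmm = list(n_states = c(2, 3, 4), maxit = 500, separation_ratio = 2,
                  step_quantile_levels = list(),
                  angle_mean_candidates = c(0, pi),
                  kappa_candidates = c(0.5, 2)),
       compare = list(n_permutations = 999))
}

#' Write a report bundle to disk
#'
#' Delimited tables (home ranges, model assessment, summaries), a JSON
#' summary, GeoJSON home-range polygons, and the stage log.
#'
#' @param report a `movement_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "movement_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$hr_table, file.path(out_dir, "home_ranges.csv"),
            row.names = FALSE)
  write.csv(report$model_table, file.path(out_dir, "model_assessment.csv"),
            row.names = FALSE)
  if (!is.null(report$summaries)) {
    write.csv(report$summaries$space_use,
              file.path(out_dir, "space_use_summary.csv"), row.names = FALSE)
    if (!is.null(report$summaries$movement))
      write.csv(report$summaries$movement,
                file.path(out_dir, "movement_summary.csv"), row.names = FALSE)
  }
  if (!is.null(report$comparisons))
    write.csv(report$comparisons, file.path(out_dir, "group_comparisons.csv"),
              row.names = FALSE)
  if (length(report$homeranges_95))
    write_homeranges_geojson(report$homeranges_95,
                             file.path(out_dir, "homeranges_95.geojson"))
  summary_json <- list(
    n_animals_with_home_range = length(report$homeranges_95),
    classes = unique(report$hr_table$class),
    selected_models = lapply(report$fits_by_class, function(f)
      if (is.null(f)) NULL else list(K = f$K, aic = f$aic,
                                     predictive_power = f$predictive_power$index)))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' @export
print.movement_report <- function(x, ...) {
  cat("movement_report:", length(x$homeranges_95), "home ranges,",
      length(x$fits_by_class), "landscape class(es) with fitted models\n")
  if (nrow(x$hr_table)) {
    cat("home-range table:\n")
    print(head(x$hr_table, 10), digits = 3)
  }
  invisible(x)
}
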