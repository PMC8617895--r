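# End-to-end orchestration and I/O: simulate a pulling data set to disk,
# read trace tables back, and run the full detection -> rates -> Bell-Evans
# -> TS-mapping analysis, writing every intermediate table.

#' Write a pulling trace to a delimited text file
#'
#' Tab-separated, header mandatory, columns \code{time_s}, \code{lambda_nm},
#' \code{force_pN}. Numeric columns round-trip at full double precision.
#'
#' @param trace A [pulling_trace()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_table <- function(trace, path) {
  stopifnot(inherits(trace, "pulling_trace"))
  d <- data.frame(time_s = trace$time, lambda_nm = trace$lambda,
                  force_pN = trace$force)
  utils::write.table(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pulling traces from a delimited text file
#'
#' Reads a tab- (or whitespace-) separated trace table with mandatory header
#' and columns \code{time_s}, \code{lambda_nm}, \code{force_pN}. A long
#' format with an additional \code{cycle_id} column is split into one trace
#' per cycle. The ramp direction is inferred from the sign of the force
#' trend unless given.
#'
#' @param path Input file path.
#' @param direction Optional direction override ("unfold"/"fold").
#' @return A [pulling_trace()], or a list of them for long-format input.
#' @export
read_trace_table <- function(path, direction = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.table(path, header = TRUE, sep = "", check.names = TRUE)
  need <- c("time_s", "lambda_nm", "force_pN")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop(sprintf("malformed header in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  build <- function(dd, cycle_id = NA_integer_) {
    bad <- which(diff(dd$time_s) <= 0)
    if (length(bad) > 0) {
      stop(sprintf("non-monotone time in %s at data line %d", path, bad[1] + 1L),
           call. = FALSE)
    }
    dir <- direction
    if (is.null(dir)) {
      dir <- if (stats::cor(dd$time_s, dd$force_pN) >= 0) "unfold" else "fold"
    }
    pulling_trace(dd$time_s, dd$lambda_nm, dd$force_pN, direction = dir,
                  cycle_id = cycle_id)
  }
  if ("cycle_id" %in% names(d)) {
    lapply(split(d, d$cycle_id), function(dd) build(dd, dd$cycle_id[1]))
  } else {
    build(d)
  }
}

config_record <- function(cfg) {
  list(
    be = unclass(cfg$be),
    elastic = unclass(cfg$elastic),
    temperature_K = cfg$ctx$temperature,
    loading_rate = cfg$loading_rate, f_start = cfg$f_start,
    f_end = cfg$f_end, k_eff = cfg$k_eff, noise_sigma = cfg$noise_sigma,
    sampling_rate = cfg$sampling_rate, n_cycles = cfg$n_cycles,
    seed = cfg$seed
  )
}

#' Simulate a pulling data set to disk
#'
#' Generates \code{n_cycles} unfolding and folding traces from a
#' [simulation_config()], writing one trace file per cycle and direction
#' (\code{cycleNNN_unfold.tsv}, \code{cycleNNN_fold.tsv}), a ground-truth
#' sidecar per trace (same stem, suffix \code{.truth}), and a
#' \code{manifest.json} recording the seed and the full parameter set. All
#' randomness flows from the configuration seed, so identical
#' configurations produce byte-identical files.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the vector of trace file paths.
#' @export
run_simulate <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    stop(sprintf("cannot create output directory %s", outdir), call. = FALSE)
  }
  set.seed(cfg$seed)
  paths <- character(0)
  for (cyc in seq_len(cfg$n_cycles)) {
    for (dir in c("unfold", "fold")) {
      g <- generate_fdc_trace(cfg, dir, cycle_id = cyc)
      stem <- file.path(outdir, sprintf("cycle%03d_%s", cyc, dir))
      write_trace_table(g$trace, paste0(stem, ".tsv"))
      truth <- data.frame(
        cycle_id = cyc, direction = dir,
        true_force_pN = g$truth$true_force,
        true_index = g$truth$true_index,
        sampled_force_pN = g$truth$sampled_force,
        has_event = g$truth$has_event
      )
      utils::write.table(format(truth, digits = 17, trim = TRUE),
                         paste0(stem, ".truth"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, paste0(stem, ".tsv"))
    }
  }
  jsonlite::write_json(
    list(seed = cfg$seed, n_traces = length(paths),
         config = config_record(cfg)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full pulling-experiment analysis
#'
#' Orchestrates the chain trace detection -> rupture forces -> densities and
#' survival probabilities -> kinetic rates -> Bell-Evans fit ->
#' transition-state profile on a directory of trace files (as written by
#' [run_simulate()] or supplied by the user in the same format). Each stage
#' consumes the previous stage's table, so any stage can also be run by hand
#' from the exported functions.
#'
#' The folded baseline is fitted on the unfolding traces (their low-force
#' region is unambiguously native) and reused to classify the folding
#' traces of the same data set. Folding forces below \code{fold_cutoff} are
#' counted as censored and excluded from densities. Alongside the fit, the
#' released extension predicted by the elastic models at the fitted
#' coexistence force is reported for comparison with
#' \code{x_m_exp = x_dagger + x_star}, and a moving-TS folding-rate
#' prediction is anchored at the most probable folding force.
#'
#' @param trace_dir Directory containing \code{*.tsv} trace files.
#' @param elastic An [elastic_params()] description of the construct.
#' @param ctx A [thermal_context()].
#' @param outdir Optional output directory; when given, every table is
#'   written there together with \code{results.json} and a run log.
#' @param loading_rate Loading rate of the ramps (pN/s).
#' @param bin_width Force bin width for densities (pN).
#' @param median_window Median filter window (samples).
#' @param debounce Classification debounce (samples).
#' @param fold_cutoff Censoring cutoff for folding forces (pN).
#' @param min_P,min_count Rate-curve bin retention thresholds.
#' @param n_boot Bootstrap resamples for rate standard errors.
#' @param seed Root seed for the bootstrap stages.
#' @param ts_grid Force grid for the transition-state profile (pN).
#' @return A results bundle (list) with the rupture table, rate curves,
#'   \code{be_fit}, \code{ts_profile}, the theoretical released extension at
#'   the fitted coexistence force, the moving-TS folding-rate prediction and
#'   per-stage counts.
#' @export
run_analysis <- function(trace_dir, elastic, ctx = thermal_context(),
                         outdir = NULL, loading_rate = 6, bin_width = 0.5,
                         median_window = 11L, debounce = 51L, fold_cutoff = 2,
                         min_P = 0.05, min_count = 5L, n_boot = 200L,
                         seed = 1L, ts_grid = seq(2, 25, by = 0.1)) {
  stopifnot(inherits(elastic, "elastic_params"))
  files <- sort(list.files(trace_dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no trace files (*.tsv) found in %s", trace_dir), call. = FALSE)
  }
  traces <- list()
  for (i in seq_along(files)) {
    tr <- read_trace_table(files[i])
    for (t1 in if (inherits(tr, "pulling_trace")) list(tr) else tr) {
      if (is.na(t1$cycle_id)) {
        num <- regmatches(basename(files[i]), regexpr("[0-9]+", basename(files[i])))
        t1$cycle_id <- if (length(num) == 1L) as.integer(num) else i
      }
      traces[[length(traces) + 1L]] <- t1
    }
  }
  traces <- lapply(traces, median_filter, window = median_window)

  unfold_traces <- Filter(function(tr) tr$direction == "unfold", traces)
  if (length(unfold_traces) == 0L) {
    stop("no unfolding traces found; cannot fit the folded baseline", call. = FALSE)
  }
  baselines <- lapply(unfold_traces, fit_folded_baseline)
  baseline <- structure(
    list(k_eff = mean(vapply(baselines, `[[`, numeric(1), "k_eff")),
         intercept = 0,
         sigma = mean(vapply(baselines, `[[`, numeric(1), "sigma")),
         n = sum(vapply(baselines, `[[`, numeric(1), "n")),
         region = NULL),
    class = "folded_baseline"
  )

  detections <- lapply(traces, function(tr) {
    labels <- classify_states(tr, baseline, elastic = elastic, ctx = ctx,
                              debounce = debounce)
    ft <- first_transition_force(labels, tr, fold_cutoff = fold_cutoff)
    data.frame(cycle_id = if (is.na(tr$cycle_id)) NA_integer_ else tr$cycle_id,
               direction = tr$direction, force_pN = ft$force_pN,
               censored = ft$censored, index = ft$index)
  })
  ruptures <- do.call(rbind, detections)
  detected <- ruptures[!is.na(ruptures$force_pN), , drop = FALSE]
  if (nrow(detected) == 0L) {
    stop("no detectable events in any trace: empty result", call. = FALSE)
  }

  get_sample <- function(dir) {
    sub <- detected[detected$direction == dir, , drop = FALSE]
    keep <- !sub$censored
    if (sum(keep) < 1L) return(NULL)
    rupture_sample(sub$force_pN[keep], dir, loading_rate,
                   n_censored = sum(!keep),
                   window = range(sub$force_pN[keep]))
  }
  s_unfold <- get_sample("unfold")
  s_fold <- get_sample("fold")
  if (is.null(s_unfold) || is.null(s_fold)) {
    stop("need uncensored events in both directions to fit the Bell-Evans model",
         call. = FALSE)
  }
  rates_unfold <- extract_rates(s_unfold, bin_width, min_P, min_count,
                                n_boot, seed = seed + 1L)
  rates_fold <- extract_rates(s_fold, bin_width, min_P, min_count,
                              n_boot, seed = seed + 2L)
  fit <- fit_be(rates_unfold, rates_fold, ctx)

  profile <- ts_profile(fit$params$x_dagger, elastic, ctx, f_grid = ts_grid)
  x_m_th_fc <- released_extension(fit$coexistence_force, elastic, ctx)

  fold_dens <- rupture_density(s_fold, bin_width)
  anchor_f <- fold_dens$mids[which.max(fold_dens$density)]
  anchor_f <- min(max(anchor_f, min(profile$force_pN)), max(profile$force_pN))
  moving_ts <- predicted_fold_rate_moving_ts(
    profile$force_pN, profile, anchor_f,
    fold_rate(anchor_f, fit$params, ctx), ctx)

  counts <- list(
    n_traces = length(traces),
    n_unfold_traces = length(unfold_traces),
    n_events_detected = nrow(detected),
    n_censored = sum(detected$censored),
    n_rate_bins_unfold = nrow(rates_unfold),
    n_rate_bins_fold = nrow(rates_fold)
  )
  bundle <- list(
    ruptures = ruptures, baseline = baseline,
    rates_unfold = rates_unfold, rates_fold = rates_fold,
    be_fit = fit, ts_profile = profile,
    x_m_th_at_fc = x_m_th_fc, moving_ts_prediction = moving_ts,
    anchor_force = anchor_f, counts = counts, seed = seed
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, nm) {
      utils::write.table(d, file.path(outdir, nm), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wt(ruptures, "ruptures.tsv")
    wt(rates_unfold, "rates_unfold.tsv")
    wt(rates_fold, "rates_fold.tsv")
    wt(as.data.frame(profile), "ts_profile.tsv")
    wt(moving_ts, "moving_ts_prediction.tsv")
    jsonlite::write_json(
      list(seed = seed,
           x_dagger_nm = fit$params$x_dagger, x_star_nm = fit$params$x_star,
           se_x_dagger_nm = fit$se$x_dagger, se_x_star_nm = fit$se$x_star,
           log_k0_unfold = fit$params$log_k0_unfold,
           log_k0_fold = fit$params$log_k0_fold,
           coexistence_force_pN = fit$coexistence_force,
           x_m_exp_nm = fit$x_m_exp, x_m_th_at_fc_nm = x_m_th_fc,
           counts = counts),
      file.path(outdir, "results.json"), auto_unbox = TRUE, digits = NA)
    writeLines(
      c(sprintf("seed: %d", seed),
        sprintf("traces read: %d", counts$n_traces),
        sprintf("events detected: %d (censored: %d)",
                counts$n_events_detected, counts$n_censored),
        sprintf("rate bins retained: %d unfold, %d fold",
                counts$n_rate_bins_unfold, counts$n_rate_bins_fold),
        sprintf("x_dagger = %.3f nm, x_star = %.3f nm, fc = %.3f pN",
                fit$params$x_dagger, fit$params$x_star, fit$coexistence_force)),
      file.path(outdir, "run_log.txt"))
  }
  bundle
}
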