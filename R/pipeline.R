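.as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.serialize_selection <- function(sel) {
  list(comparison = sel$comparison,
       best_variant = sel$best_variant,
       estimation = sel$best_fit$estimation,
       logLik = sel$best_fit$logLik,
       aicc = sel$best_fit$aicc,
       n = sel$best_fit$n, n_groups = sel$best_fit$n_groups,
       fixed_effects = sel$best_fit$fixed_effects,
       variance_components = as.list(sel$best_fit$variance_components),
       per_whale_coefficients = sel$best_fit$coefficients,
       diagnostics = sel$diagnostics)
}

#' Run the full baleen T cycle analysis
#'
#' Per whale: optional analysis window, Gaussian detrending, AR spectral
#' period estimation for the T series (and the isotope series when present),
#' peak detection and cycle segmentation with plate summaries, phase offset
#' against the isotope cycle, and per-cycle age assignment from the whale's
#' best available terminal age. At the cohort level: AICc-selected mixed
#' models of per-cycle peak T and cycle period against age, and Pearson
#' correlations of the plate summaries against terminal age under each
#' configured age mode. A stage failure for one whale is recorded and the
#' cohort stages run on the whales that succeeded.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{profiles}{path to a profiles CSV, or a named list of
#'       [hormone_profile] objects.}
#'     \item{metadata}{path to a metadata CSV, or a `whale_metadata` frame.}
#'     \item{output_dir}{optional; when set, report files are written there.}
#'     \item{windows}{optional named list `whale_id -> c(start_cm, end_cm)`.}
#'     \item{detrend}{list, e.g. `list(sigma_cm = 8)`.}
#'     \item{spectral}{list: `max_order`, `grid_points`, `period_band_cm`.}
#'     \item{age_modes}{character subset of `c("best", "length_only")`
#'       (default both).}
#'     \item{ratio_mode}{`"per_cycle"` (default) or `"plate"`.}
#'     \item{min_prominence}{peak-prominence margin in ng/g passed to
#'       [detect_peaks()]: a scalar, or a named list per whale. Default 0
#'       (the pure four-neighbour rule).}
#'     \item{growth_params}{optional path to a growth-model YAML (used when
#'       a whale lacks a precomputed length age).}
#'     \item{comparator_ages}{optional numeric vector for whales exceeding
#'       both growth-model asymptotes.}
#'     \item{seed}{recorded in the run log (the analysis itself is
#'       deterministic).}
#'   }
#' @return object of class `baleen_analysis`: per-whale results, the
#'   per-whale `summary_table`, `phase_table` and `cycle_table`, per-mode
#'   `trends` (peak and period model selections) and `correlations`, and a
#'   `failures` record.
#' @export
run_analysis <- function(config) {
  config <- .as_config(config)
  profiles <- config$profiles
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  metadata <- config$metadata
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  sigma_cm <- config$detrend$sigma_cm %||% 8
  spectral <- config$spectral %||% list()
  grid_points <- spectral$grid_points %||% 4096
  band <- as.numeric(spectral$period_band_cm %||% c(4, 60))
  max_order <- spectral$max_order
  age_modes <- config$age_modes %||% c("best", "length_only")
  ratio_mode <- config$ratio_mode %||% "per_cycle"
  min_prom <- config$min_prominence %||% 0
  prom_of <- function(id) {
    if (is.list(min_prom)) min_prom[[id]] %||% 0 else min_prom
  }
  gp <- config$growth_params
  if (is.character(gp)) gp <- read_growth_params(gp)
  comparator_ages <- config$comparator_ages

  ages_by_mode <- lapply(age_modes, function(m) {
    best_available_age(metadata, mode = m, params_list = gp,
                       comparator_ages = comparator_ages)
  })
  names(ages_by_mode) <- age_modes
  primary_ages <- ages_by_mode[[1L]]

  whale_ids <- sort(names(profiles))
  whales <- list()
  failures <- list()
  for (id in whale_ids) {
    res <- tryCatch({
      prof <- profiles[[id]]
      win <- config$windows[[id]]
      if (!is.null(win)) prof <- apply_window(prof, win[1L], win[2L])
      t_spec <- estimate_period(prof, sigma_cm = sigma_cm,
                                max_order = max_order,
                                grid_points = grid_points,
                                period_band_cm = band)
      n_spec <- if (!is.null(prof$d15n)) {
        tryCatch(estimate_period(prof, sigma_cm = sigma_cm,
                                 max_order = max_order,
                                 grid_points = grid_points,
                                 period_band_cm = band,
                                 series_name = "d15n"),
                 error = function(e) NULL)
      }
      peaks <- detect_peaks(prof, min_prominence = prom_of(id))
      cycles <- segment_cycles(prof, peaks)
      arow <- primary_ages[primary_ages$whale_id == id, ]
      terminal <- if (nrow(arow)) arow$age_yr else NA_real_
      peak_ages <- NULL
      if (peaks$n >= 1L && is.finite(terminal) && terminal > peaks$n) {
        # assign_cycle_ages is oldest-first; peaks are index-ascending
        # (recent growth first), so reverse to align
        peak_ages <- rev(assign_cycle_ages(peaks$n, terminal))
      }
      if (!is.null(peak_ages) && cycles$n_cycles) {
        # a cycle carries the age of its older bounding peak
        cycles$cycles$age_yr <- peak_ages[match(cycles$cycles$peak_hi_idx,
                                                peaks$indices)]
      }
      phase <- if (!is.null(prof$d15n)) {
        estimate_phase(detrend(prof$testosterone, prof$spacing_cm, sigma_cm),
                       detrend(prof$d15n, prof$spacing_cm, sigma_cm),
                       prof$spacing_cm, t_spec$period_cm,
                       if (!is.null(n_spec)) n_spec$period_cm
                       else t_spec$period_cm)
      }
      list(profile = prof, spectral = t_spec, spectral_n = n_spec,
           peaks = peaks, cycles = cycles, peak_ages = peak_ages,
           terminal_age = terminal,
           age_source = if (nrow(arow)) arow$source else NA_character_,
           phase = phase,
           summary = summarize_plate(prof, peaks, cycles,
                                     ratio_mode = ratio_mode))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      whales[[id]] <- res
    }
  }
  if (!length(whales)) {
    stop("every whale failed; first error: ", failures[[1L]], call. = FALSE)
  }

  summary_table <- do.call(rbind, lapply(names(whales), function(id) {
    w <- whales[[id]]
    cbind(data.frame(whale_id = id, est_age_yr = w$terminal_age,
                     age_source = w$age_source,
                     t_period_cm = w$spectral$period_cm,
                     n_period_cm = if (!is.null(w$spectral_n))
                       w$spectral_n$period_cm else NA_real_,
                     phase_offset_months = if (!is.null(w$phase))
                       w$phase$offset_months else NA_real_),
          as.data.frame(w$summary))
  }))
  phase_table <- do.call(rbind, lapply(names(whales), function(id) {
    w <- whales[[id]]
    if (is.null(w$phase)) return(NULL)
    p <- w$phase
    data.frame(whale_id = id, lag_samples = p$lag_samples, lag_cm = p$lag_cm,
               max_ccf = p$max_ccf, offset_months = p$offset_months,
               t_precedes_n = p$t_precedes_n, significant = p$significant)
  }))
  if (is.null(phase_table)) {
    phase_table <- data.frame(whale_id = character(0),
                              lag_samples = integer(0), lag_cm = numeric(0),
                              max_ccf = numeric(0), offset_months = numeric(0),
                              t_precedes_n = logical(0),
                              significant = logical(0))
  }
  cycle_table <- do.call(rbind, lapply(names(whales), function(id) {
    w <- whales[[id]]
    if (!w$cycles$n_cycles) return(NULL)
    cc <- w$cycles$cycles
    data.frame(whale_id = id, cycle = seq_len(nrow(cc)), age_yr = cc$age_yr,
               peak_ng_g = cc$peak_height, min_ng_g = cc$min_value,
               period_cm = cc$period_cm, ratio = cc$ratio)
  }))

  trends <- list()
  correlations <- list()
  for (m in age_modes) {
    ages <- ages_by_mode[[m]]
    age_of <- function(id) ages$age_yr[ages$whale_id == id]
    peak_obs <- do.call(rbind, lapply(names(whales), function(id) {
      w <- whales[[id]]
      if (is.null(w$peak_ages)) return(NULL)
      term <- age_of(id)
      pa <- if (term > w$peaks$n) rev(assign_cycle_ages(w$peaks$n, term))
        else return(NULL)
      data.frame(whale_id = id, age_yr = pa, response = w$peaks$heights)
    }))
    period_obs <- do.call(rbind, lapply(names(whales), function(id) {
      w <- whales[[id]]
      if (!w$cycles$n_cycles || is.null(w$peak_ages)) return(NULL)
      term <- age_of(id)
      if (term <= w$peaks$n) return(NULL)
      pa <- rev(assign_cycle_ages(w$peaks$n, term))
      cc <- w$cycles$cycles
      data.frame(whale_id = id,
                 age_yr = pa[match(cc$peak_hi_idx, w$peaks$indices)],
                 response = cc$period_cm)
    }))
    trends[[m]] <- list(
      peak = if (!is.null(peak_obs) && length(unique(peak_obs$whale_id)) >= 2)
        select_model(peak_obs),
      period = if (!is.null(period_obs) &&
                     length(unique(period_obs$whale_id)) >= 2)
        select_model(period_obs))

    st <- summary_table
    ages_v <- vapply(st$whale_id, age_of, numeric(1))
    metrics <- c(mean_t = "mean_t", median_t = "median_t", max_t = "max_t",
                 min_t = "min_t", baseline = "baseline",
                 cv_peaks = "cv_peaks")
    correlations[[m]] <- do.call(rbind, lapply(names(metrics), function(nm) {
      v <- st[[metrics[[nm]]]]
      ok <- is.finite(v) & is.finite(ages_v)
      if (sum(ok) < 3L || stats::sd(v[ok]) == 0) return(NULL)
      ct <- pearson_corr_test(ages_v[ok], v[ok])
      data.frame(age_mode = m, metric = nm, n = ct$n, r = ct$r,
                 r_squared = ct$r_squared, p_two_tailed = ct$p_two_tailed,
                 significant = ct$significant)
    }))
  }
  correlations <- do.call(rbind, correlations)

  out <- structure(list(whales = whales, summary_table = summary_table,
                        phase_table = phase_table, cycle_table = cycle_table,
                        trends = trends, correlations = correlations,
                        failures = failures, age_modes = age_modes,
                        config = config),
                   class = "baleen_analysis")
  if (!is.null(config$output_dir)) write_reports(out, config$output_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the report bundle of an analysis
#'
#' Writes `summary.csv`, `cycles.csv`, `phase.csv`, `correlations.csv`,
#' per-mode `lmm_peak_<mode>.json` / `lmm_period_<mode>.json`, and
#' `run_log.txt`. All files except the run log are byte-stable for identical
#' inputs.
#'
#' @param analysis a `baleen_analysis`.
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_reports <- function(analysis, output_dir) {
  stopifnot(inherits(analysis, "baleen_analysis"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  wcsv(analysis$summary_table, "summary.csv")
  if (!is.null(analysis$cycle_table)) wcsv(analysis$cycle_table, "cycles.csv")
  wcsv(analysis$phase_table, "phase.csv")
  if (!is.null(analysis$correlations)) {
    wcsv(analysis$correlations, "correlations.csv")
  }
  for (m in names(analysis$trends)) {
    for (what in c("peak", "period")) {
      sel <- analysis$trends[[m]][[what]]
      if (is.null(sel)) next
      jsonlite::write_json(
        .serialize_selection(sel),
        file.path(output_dir, paste0("lmm_", what, "_", m, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    }
  }
  log <- c(paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
           paste("baleenT version:",
                 as.character(utils::packageVersion("baleenT"))),
           paste("R version:", R.version.string),
           paste("seed:", analysis$config$seed %||% "none"),
           paste("age modes:", paste(analysis$age_modes, collapse = ", ")),
           paste("detrend sigma_cm:",
                 analysis$config$detrend$sigma_cm %||% 8),
           if (length(analysis$failures)) {
             paste("FAILED whale", names(analysis$failures), ":",
                   unlist(analysis$failures))
           } else "all whales analysed")
  writeLines(log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' @export
print.baleen_analysis <- function(x, ...) {
  cat("Baleen T cycle analysis: ", nrow(x$summary_table), " whales",
      if (length(x$failures)) paste0(" (", length(x$failures), " failed)"),
      "\n", sep = "")
  st <- x$summary_table
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-10s age %5.0f  %2d peaks  period %5.2f cm  offset %s\n",
                st$whale_id[i], st$est_age_yr[i], st$n_peaks[i],
                st$t_period_cm[i],
                if (is.finite(st$phase_offset_months[i]))
                  sprintf("%.2f mo", st$phase_offset_months[i]) else "--"))
  }
  for (m in names(x$trends)) {
    for (what in c("peak", "period")) {
      sel <- x$trends[[m]][[what]]
      if (is.null(sel)) next
      fe <- sel$best_fit$fixed_effects
      sl <- fe$estimate[fe$term == "age_yr"]
      cat(sprintf("  [%s] %s T ~ age: %s model%s\n", m, what,
                  sel$best_variant,
                  if (length(sl)) sprintf(", slope %.3g", sl) else ""))
    }
  }
  invisible(x)
}

#' Simulate a cohort and write analysis-ready files
#'
#' Delegates to [generate_cohort()]; the outputs can be fed straight back
#' into [run_analysis()].
#'
#' @param config list (or YAML path) with `specs` (a list of
#'   [synthetic_whale_spec]s, or of plain lists of spec arguments), optional
#'   `seed`, and optional output paths `out_profiles` (CSV) and `out_truth`
#'   (JSON).
#' @return the cohort (list of `profiles` and `truths`), invisibly.
#' @export
run_simulation <- function(config) {
  config <- .as_config(config)
  specs <- lapply(config$specs, function(s) {
    if (inherits(s, "synthetic_whale_spec")) s else
      do.call(synthetic_whale_spec, s)
  })
  cohort <- generate_cohort(specs, seed = config$seed)
  if (!is.null(config$out_profiles)) {
    write_profiles(cohort$profiles, config$out_profiles)
  }
  if (!is.null(config$out_truth)) {
    jsonlite::write_json(cohort$truths, config$out_truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(cohort)
}
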