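#' Pipeline configuration
#'
#' Validates every setting against the stage that consumes it; unknown keys
#' are rejected. Defaults mirror the analysis conventions of the pipeline:
#' 250 Hz analysis rate, 2-s windows with 50% overlap, density grid
#' 0.1-0.9 in steps of 0.05 with 0.35 as the illustration density, and a
#' strict 60% electrode-selection cutoff.
#'
#' @param ... named settings overriding the defaults: `target_fs`,
#'   `window_s`, `overlap_frac`, `edges` (band edges), `freqs` (frequency
#'   grid), `order` (`"auto"` or a fixed integer), `p_min`, `p_max`,
#'   `n_boot`, `alpha`, `t_min`, `t_max`, `t_step`, `fixed_T`,
#'   `cutoff_pct`, `k_energy`, `seed`, `run_bootstrap`,
#'   `mask_before_threshold`, `pdc_squared`, `select_electrodes`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(target_fs = 250, window_s = 2, overlap_frac = 0.5,
              edges = band_edges(), freqs = default_freq_grid(),
              order = "auto", p_min = 2, p_max = 20,
              n_boot = 200, alpha = 0.05,
              t_min = 0.1, t_max = 0.9, t_step = 0.05, fixed_T = 0.35,
              cutoff_pct = 60, k_energy = 4, seed = 1,
              run_bootstrap = FALSE, mask_before_threshold = FALSE,
              pdc_squared = FALSE, select_electrodes = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (target_fs <= 60) stop("target_fs must exceed 60 Hz")
    if (window_s <= 0) stop("window_s must be positive")
    if (overlap_frac < 0 || overlap_frac >= 1)
      stop("overlap_frac must be in [0, 1)")
    if (!identical(order, "auto")) {
      if (!is.numeric(order) || order < 1) stop("order must be 'auto' or a ",
                                                "positive integer")
    } else if (p_max < p_min || p_min < 1) stop("need p_max >= p_min >= 1")
    if (n_boot < 100) stop("n_boot must be >= 100")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (t_min > t_max || t_step <= 0) stop("invalid threshold grid")
    if (fixed_T <= 0 || fixed_T > 1) stop("fixed_T must be in (0, 1]")
    if (cutoff_pct < 0 || cutoff_pct > 100)
      stop("cutoff_pct must be a percentage")
    if (any(freqs <= 0) || any(freqs > target_fs / 2))
      stop("frequency grid must lie in (0, target_fs/2]")
    if (k_energy < 1) stop("k_energy must be >= 1")
  })
  invisible(cfg)
}

#' Deterministic per-stage, per-subject seed splitting
#'
#' Expands one master seed into independent substream seeds via an affine
#' hash of the stage name and index, so stages and subjects can run in any
#' order (or in parallel) with reproducible randomness.
#'
#' @param seed master integer seed.
#' @param stage stage name (character).
#' @param index subject/replicate index (integer, default 0).
#' @return A positive integer seed below 2^31.
#' @export
split_seed <- function(seed, stage, index = 0) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 100003 + h * 1009 + index * 7919) %%
               2147483629) + 1L
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) recordings, down-sample and window, optional
#' LMD/SVM electrode selection, per-window MVAR + PDC, rhythm-band
#' connectivity (optionally bootstrap-masked), proportional-threshold graph
#' sweep, efficiency metrics, and group statistics. Every artifact is
#' written under `out_dir` as TSV/JSON, stamped with the config hash and
#' master seed; re-running with identical config and seed reproduces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param recordings list of [eeg_recording()]s, or NULL to use `simulate`.
#' @param simulate list with `n_subjects`, plus optional arguments of
#'   [make_task_pair()] (`n_channels`, `effect_size`, `fs`, `duration_s`,
#'   `model_fs`); used when `recordings` is NULL.
#' @param out_dir output directory (created if missing); NULL skips file
#'   output.
#' @return List with `table` (tidy efficiency table), `paired` (per-
#'   threshold paired tests for every metric/band), `anova`, `headline`,
#'   `orders` (per-subject MVAR orders), `selected_electrodes`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), recordings = NULL,
                         simulate = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(recordings)) {
    if (is.null(simulate))
      stop("supply recordings or a simulate = list(n_subjects = ...) request")
    n_sub <- simulate$n_subjects
    if (is.null(n_sub)) stop("simulate needs n_subjects")
    sim_args <- simulate[setdiff(names(simulate), "n_subjects")]
    recordings <- list()
    for (s in seq_len(n_sub)) {
      pair <- do.call(make_task_pair, c(
        list(seed = split_seed(config$seed, "simulate", s),
             subject_id = sprintf("S%02d", s)), sim_args))
      recordings <- c(recordings, list(pair$play, pair$rest))
    }
  }
  subjects <- unique(vapply(recordings, function(r) r$subject_id,
                            character(1)))
  # stage 1: prep
  prepped <- lapply(recordings, downsample, target_fs = config$target_fs)
  wsets <- lapply(prepped, slide_windows, window_s = config$window_s,
                  overlap_frac = config$overlap_frac)
  names(wsets) <- vapply(prepped, function(r)
    paste(r$subject_id, r$condition, sep = "/"), character(1))
  # stage 2: electrode selection (optional; defaults to all channels)
  selected <- prepped[[1]]$channel_labels
  screen <- NULL
  if (isTRUE(config$select_electrodes)) {
    s1 <- subjects[1]
    wp <- wsets[[paste(s1, "play", sep = "/")]]
    wr <- wsets[[paste(s1, "rest", sep = "/")]]
    screen <- electrode_screen(wp, wr, k = config$k_energy,
                               cutoff_pct = config$cutoff_pct)
    selected <- select_electrodes(screen, config$cutoff_pct)
    if (length(selected) < 3) stop("electrode selection kept fewer than 3 ",
                                   "channels; cannot build a network")
    keep <- match(selected, prepped[[1]]$channel_labels)
    wsets <- lapply(wsets, function(ws) {
      ws$windows <- lapply(ws$windows, function(w)
        w[keep, , drop = FALSE])
      ws$channel_labels <- selected
      ws
    })
  }
  # stage 3: MVAR order per subject, PDC, band connectivity
  orders <- stats::setNames(integer(length(subjects)), subjects)
  conns <- list()
  for (s in subjects) {
    both <- wsets[grepl(paste0("^", s, "/"), names(wsets))]
    p_s <- if (identical(config$order, "auto"))
      select_order_aic(c(both[[1]]$windows, both[[2]]$windows),
                       config$p_min, config$p_max)
    else as.integer(config$order)
    orders[s] <- p_s
    for (nm in names(both)) {
      ws <- both[[nm]]
      spectra <- lapply(ws$windows, window_pdc, order_p = p_s,
                        freqs = config$freqs, fs = ws$fs)
      bc <- band_average(spectra, config$edges,
                         squared = config$pdc_squared,
                         channel_labels = ws$channel_labels)
      if (isTRUE(config$run_bootstrap)) {
        masks <- bootstrap_significance(
          ws, p_s, config$freqs, ws$fs, config$edges,
          n_boot = config$n_boot, alpha = config$alpha,
          seed = split_seed(config$seed, "bootstrap", match(nm, names(wsets))),
          squared = config$pdc_squared)
        for (b in names(bc)) {
          bc[[b]]$sig_mask <- masks[[b]]
          if (isTRUE(config$mask_before_threshold))
            bc[[b]]$matrix <- bc[[b]]$matrix * masks[[b]]
        }
      }
      conns[[nm]] <- bc
    }
  }
  # stage 4: graphs and efficiency over the density sweep
  tgrid <- round(seq(config$t_min, config$t_max + config$t_step / 4,
                     by = config$t_step), 10)
  tgrid <- sort(unique(c(tgrid[tgrid <= config$t_max + 1e-9],
                         config$fixed_T)))
  reports <- list()
  for (nm in names(conns)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    for (b in names(conns[[nm]]))
      for (T in tgrid) {
        g <- threshold_proportional(conns[[nm]][[b]], T)
        reports[[length(reports) + 1L]] <-
          efficiency_report(g, band = b, condition = parts[2],
                            subject_id = parts[1])
      }
  }
  table <- group_table(reports)
  # stage 5: group statistics
  paired <- list()
  for (metric in c("e_glob", "e_loc"))
    for (b in names(config$edges))
      paired[[paste(metric, b, sep = ".")]] <-
        paired_test_per_threshold(table, metric, b)
  anova <- lapply(stats::setNames(nm = c("e_glob", "e_loc")), function(metric)
    two_way_anova(table, metric, config$fixed_T))
  headline <- headline_report(table, config$fixed_T, config$alpha)
  result <- list(table = table, paired = paired, anova = anova,
                 headline = headline, orders = orders,
                 selected_electrodes = selected, screen = screen,
                 connectivity = conns, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Serialize pipeline outputs as TSV/JSON under out_dir, stamped with the
# config hash (md5 of the canonical config JSON) and master seed.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  hash <- unname(tools::md5sum(cfg_json))
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# config_md5 %s seed %d", hash, cfg$seed), con)
    utils::write.table(format(df, digits = 10, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(result$table, "efficiency_table.tsv")
  for (nm in names(result$paired))
    wr(result$paired[[nm]], paste0("paired_", nm, ".tsv"))
  for (nm in names(result$anova))
    wr(result$anova[[nm]], paste0("anova_", nm, ".tsv"))
  wr(result$headline$contrasts, "headline_contrasts.tsv")
  if (!is.null(result$screen)) wr(result$screen, "electrode_screen.tsv")
  for (nm in names(result$connectivity)) {
    safe <- gsub("/", "_", nm)
    for (b in names(result$connectivity[[nm]])) {
      mat <- result$connectivity[[nm]][[b]]$matrix
      wr(as.data.frame(signif(mat, 10)), sprintf("pdc_%s_%s.tsv", safe, b))
    }
  }
  jsonlite::write_json(
    list(config_md5 = hash, seed = cfg$seed,
         orders = as.list(result$orders),
         selected_electrodes = result$selected_electrodes),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
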