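#' Default end-to-end pipeline configuration
#'
#' Nested sections mirroring each stage's configuration, plus a global seed
#' and output directory. Unknown keys are rejected by [run_pipeline()], and
#' every run writes the resolved configuration next to its outputs.
#'
#' @param seed global seed.
#' @param n_subjects,n_control,trials_per_subject cohort size (demo-scale
#'   defaults).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 2L, n_control = 0L,
                            trials_per_subject = 2L) {
  structure(list(
    seed = as.integer(seed),
    simulation = list(n_subjects = as.integer(n_subjects),
                      n_control = as.integer(n_control),
                      trials_per_subject = as.integer(trials_per_subject),
                      sampling_rate_hz = 50, noise_sd = 0.05,
                      rest_between_s = 20),
    filter = list(order = 3L, cutoff_hz = 0.5, zero_phase = TRUE),
    features = list(window_samples = 128L, overlap = 0.5),
    tremor_label = list(f_lo = 3.5, f_hi = 7.5, threshold = NA,
                        min_duration_s = 1.0, merge_gap_s = 0.5),
    analysis = list(perplexity = 30, mapping_item = "3.17",
                    tsne_max_rows = 2000L)
  ), class = "pipeline_config")
}

.check_config_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (k in names(cfg))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      .check_config_keys(cfg[[k]], template[[k]], paste0(path, ".", k))
  invisible(TRUE)
}

.merge_config <- function(user, template) {
  for (k in names(user)) {
    template[[k]] <- if (is.list(template[[k]]) && is.list(user[[k]]))
      .merge_config(user[[k]], template[[k]]) else user[[k]]
  }
  template
}

#' Run the full pipeline: simulate, validate, extract, label, correlate, embed
#'
#' Stages, each writing file artifacts under `out_dir`:
#' \enumerate{
#'   \item simulate a synthetic cohort into `sessions/`;
#'   \item validate the on-disk sessions (abort on any invalid trial);
#'   \item extract per-segment features (`features_segments.csv`) and
#'     windowed features (`features_windows.csv`);
#'   \item calibrate the tremor threshold on the cohort ground truth (unless
#'     fixed in the config) and label rest segments
#'     (`labels/<trial>.json` + per-window power traces);
#'   \item Pearson feature-vs-score correlations (`correlations.csv`);
#'   \item t-SNE embedding of the windowed features (`embedding.csv`).
#' }
#' A `report.json` summarizes counts, the per-label data share (which sums
#' to 100\%), hours of signal and per-stage timings; `config.json` records
#' the resolved configuration. Everything is deterministic under the global
#' seed.
#'
#' @param config a [pipeline_config()] or nested list overriding parts of it.
#' @param out_dir artifact directory.
#' @return list with the in-memory results (`cohort`, `features`,
#'   `correlations`, `embedding`, `report`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  template <- pipeline_config()
  .check_config_keys(config, template)
  cfg <- .merge_config(config, template)
  # fail fast on invalid stage parameters before any computation
  fspec <- filter_spec(cfg$filter$order, cfg$filter$cutoff_hz,
                       cfg$filter$zero_phase)
  if (fspec$cutoff_hz >= cfg$simulation$sampling_rate_hz / 2)
    stop(sprintf("stage 'validate-config': cutoff_hz (%g) is at or above Nyquist (%g Hz)",
                 fspec$cutoff_hz, cfg$simulation$sampling_rate_hz / 2))
  wcfg <- windowing_config(cfg$features$window_samples, cfg$features$overlap)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  scfg <- sim_config(seed = cfg$seed,
                     n_subjects = cfg$simulation$n_subjects,
                     n_control = cfg$simulation$n_control,
                     trials_per_subject = cfg$simulation$trials_per_subject,
                     sampling_rate_hz = cfg$simulation$sampling_rate_hz,
                     noise_sd = cfg$simulation$noise_sd,
                     rest_between_s = cfg$simulation$rest_between_s)
  sess_dir <- file.path(out_dir, "sessions")
  cohort <- stage("simulate", simulate_cohort(scfg, out_dir = sess_dir))

  stage("validate", {
    v <- validate_session(sess_dir)
    if (!v$ok) stop(paste(v$issues, collapse = "; "))
    v
  })

  trials <- lapply(cohort, `[[`, "trial")
  segfeat <- stage("extract", {
    sf <- segment_feature_table(trials, spec = fspec)
    write.csv(sf, file.path(out_dir, "features_segments.csv"),
              row.names = FALSE)
    wf <- do.call(rbind, lapply(trials, windowed_features, cfg = wcfg,
                                spec = fspec))
    write.csv(wf, file.path(out_dir, "features_windows.csv"),
              row.names = FALSE)
    list(segments = sf, windows = wf)
  })

  labels <- stage("label", {
    tcfg0 <- tremor_label_config(f_lo = cfg$tremor_label$f_lo,
                                 f_hi = cfg$tremor_label$f_hi,
                                 min_duration_s = cfg$tremor_label$min_duration_s,
                                 merge_gap_s = cfg$tremor_label$merge_gap_s)
    thr <- cfg$tremor_label$threshold
    calib <- NULL
    if (is.na(thr)) {
      calib <- tryCatch(calibrate_threshold(cohort, tcfg0, fspec),
                        error = function(e) NULL)
      thr <- if (is.null(calib)) tcfg0$threshold else calib$threshold
    }
    tcfg <- tremor_label_config(f_lo = tcfg0$f_lo, f_hi = tcfg0$f_hi,
                                threshold = thr,
                                min_duration_s = tcfg0$min_duration_s,
                                merge_gap_s = tcfg0$merge_gap_s)
    lab_dir <- file.path(out_dir, "labels")
    dir.create(lab_dir, showWarnings = FALSE)
    per_trial <- list()
    for (entry in cohort) {
      trial <- entry$trial
      id <- sprintf("%s_w%02d", trial$subject_id, trial$week)
      segs <- trial$segments[trial$segments$label_code == 1L, , drop = FALSE]
      ivs <- list()
      for (si in seq_len(nrow(segs))) {
        idx <- (segs$start[si] + 1L):segs$end[si]
        sub <- triaxial_signal(trial$signal$t[idx], trial$signal$ax[idx],
                               trial$signal$ay[idx], trial$signal$az[idx],
                               trial$signal$sampling_rate_hz)
        res <- suppressWarnings(label_tremor(norm_highpass(sub, fspec), tcfg))
        if (nrow(res$intervals)) ivs[[length(ivs) + 1L]] <- res$intervals
      }
      iv <- if (length(ivs)) do.call(rbind, ivs)
        else data.frame(start_s = numeric(0), end_s = numeric(0))
      jsonlite::write_json(iv, file.path(lab_dir, paste0(id, ".json")),
                           digits = NA, pretty = TRUE)
      per_trial[[id]] <- iv
    }
    list(threshold = thr, calibration = calib, intervals = per_trial)
  })

  correlations <- stage("correlate", {
    res <- correlation_matrix(segfeat$segments)
    write.csv(res, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    res
  })

  embedding <- stage("embed", {
    wf <- segfeat$windows
    n <- nrow(wf)
    cap <- cfg$analysis$tsne_max_rows
    set.seed(cfg$seed)
    if (n > cap) wf <- wf[sort(sample.int(n, cap)), , drop = FALSE]
    perp <- min(cfg$analysis$perplexity, floor((nrow(wf) - 2) / 3))
    emb <- tsne_embed(wf, mapping_item = cfg$analysis$mapping_item,
                      seed = cfg$seed, perplexity = perp)
    write.csv(as.data.frame(emb), file.path(out_dir, "embedding.csv"),
              row.names = FALSE)
    emb
  })

  report <- stage("report", {
    all_labels <- unlist(lapply(trials, `[[`, "labels"))
    rate <- cfg$simulation$sampling_rate_hz
    tab <- table(factor(all_labels, levels = LABEL_CODES))
    share <- as.numeric(tab) / length(all_labels) * 100
    rep <- list(
      n_subjects = cfg$simulation$n_subjects,
      n_trials = length(trials),
      hours_of_data = round(length(all_labels) / rate / 3600, 3),
      label_share_percent = setNames(as.list(round(share, 4)),
                                     paste0("label_", LABEL_CODES)),
      label_share_total = sum(share),
      tremor_threshold = labels$threshold,
      timings_s = timings)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })
  cfg_out <- cfg
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(cohort = cohort, features = segfeat,
                 labels = labels, correlations = correlations,
                 embedding = embedding, report = report))
}
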