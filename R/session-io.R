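#' Construct a trial record
#'
#' One weekly session for one subject: the triaxial signal, per-sample
#' exercise/rest labels, and the session's clinical scores. Labels follow the
#' protocol taxonomy: 0 = postural transition, 1 = resting interval (which
#' also covers the rest-tremor exercise posture), 2..8 = exercises 2..8.
#'
#' @param subject_id subject identifier (character).
#' @param group one of "remote", "supervised", "control".
#' @param week trial week index (integer >= 1).
#' @param signal a [triaxial_signal()].
#' @param labels integer vector of per-sample label codes in 0..8, same
#'   length as the signal.
#' @param scores named numeric vector of MDS-UPDRS item scores (0-4), named
#'   by item id ("3.17", "3.15", "3.4", "3.5", "3.6", "3.10"); items may be
#'   missing (NA or absent).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, group, week, signal, labels,
                         scores = numeric(0)) {
  stopifnot(inherits(signal, "triaxial_signal"))
  group <- match.arg(group, c("remote", "supervised", "control"))
  labels <- as.integer(labels)
  if (length(labels) != length(signal$t))
    stop("labels must have one entry per sample")
  if (length(labels) && !all(labels %in% LABEL_CODES))
    stop("unknown label code: labels must be integers in 0..8")
  scores <- .validate_scores(scores)
  segs <- segments_from_labels(labels)
  ex_labels <- segs$label_code[segs$label_code >= 2L]
  if (anyDuplicated(ex_labels))
    stop("every exercise label (2..8) may appear at most once per trial")
  structure(list(subject_id = as.character(subject_id), group = group,
                 week = as.integer(week), signal = signal, labels = labels,
                 segments = segs, scores = scores),
            class = "trial_record")
}

.validate_scores <- function(scores) {
  if (length(scores) == 0) return(setNames(numeric(0), character(0)))
  if (is.list(scores)) scores <- unlist(scores)
  if (is.null(names(scores)) || any(names(scores) == ""))
    stop("scores must be named by MDS-UPDRS item id")
  bad <- setdiff(names(scores), SCORE_ITEMS)
  if (length(bad)) stop("unknown score item(s): ", paste(bad, collapse = ", "))
  ok <- is.na(scores) | (scores == round(scores) & scores >= 0 & scores <= 4)
  if (!all(ok))
    stop("scores must be integers in 0..4 (0 = no impairment, 4 = severe)")
  scores
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record: subject %s, %s group, week %d, %d samples, %d segments>\n",
              x$subject_id, x$group, x$week, length(x$labels),
              nrow(x$segments)))
  invisible(x)
}

#' Run-length segmentation of per-sample labels
#'
#' Contiguous runs of equal label become segments with 0-based half-open
#' `[start, end)` sample indices. The segments partition the trial: every
#' sample index belongs to exactly one segment.
#'
#' @param labels integer vector of per-sample label codes.
#' @return data.frame with columns `label_code`, `start`, `end`.
#' @export
segments_from_labels <- function(labels) {
  if (length(labels) == 0)
    return(data.frame(label_code = integer(0), start = integer(0),
                      end = integer(0)))
  r <- rle(as.integer(labels))
  end <- cumsum(r$lengths)
  data.frame(label_code = r$values, start = c(0L, head(end, -1L)),
             end = as.integer(end))
}

#' Write a trial to its on-disk layout
#'
#' Emits `samples.csv` (header `t,ax,ay,az,label`; decimal point, UTF-8, LF)
#' and `trial.json` (`subject_id`, `group`, `week`, `scores`). Numbers are
#' printed with 17 significant digits so that [read_trial()] inverts the
#' write exactly.
#'
#' @param trial a [trial_record()].
#' @param path directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  s <- trial$signal
  lines <- c("t,ax,ay,az,label",
             sprintf("%.17g,%.17g,%.17g,%.17g,%d",
                     s$t, s$ax, s$ay, s$az, trial$labels))
  con <- file(file.path(path, "samples.csv"), open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  scores <- as.list(trial$scores[!is.na(trial$scores)])
  meta <- list(subject_id = trial$subject_id, group = trial$group,
               week = trial$week, scores = scores,
               sampling_rate_hz = s$sampling_rate_hz)
  jsonlite::write_json(meta, file.path(path, "trial.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trial from its on-disk layout
#'
#' Reads `samples.csv` and `trial.json` from `path`, validates the format,
#' and segments contiguous label runs. Rows with non-finite sample values are
#' counted, dropped, and reported via the `n_malformed` attribute (and a
#' warning). Gaps longer than 3 nominal sample periods are reported via the
#' `gaps` attribute, never interpolated: silent infill would bias band powers.
#'
#' @param path directory containing `samples.csv` and `trial.json`.
#' @return A validated [trial_record()].
#' @export
read_trial <- function(path) {
  fsam <- file.path(path, "samples.csv")
  fmeta <- file.path(path, "trial.json")
  if (!file.exists(fsam)) stop("missing samples.csv in ", path)
  if (!file.exists(fmeta)) stop("missing trial.json in ", path)
  df <- read.csv(fsam, colClasses = "numeric")
  need <- c("t", "ax", "ay", "az", "label")
  if (!all(need %in% names(df)))
    stop("format error: samples.csv must have columns ",
         paste(need, collapse = ","))
  bad <- !stats::complete.cases(df) |
    !is.finite(df$t) | !is.finite(df$ax) | !is.finite(df$ay) |
    !is.finite(df$az)
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    warning(sprintf("%d malformed sample row(s) dropped in %s",
                    n_malformed, path))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) >= 2 && any(diff(df$t) <= 0))
    stop("format error: timestamps must be strictly increasing")
  if (!all(df$label %in% LABEL_CODES))
    stop("unknown label code in samples.csv (must be 0..8)")
  meta <- jsonlite::read_json(fmeta, simplifyVector = TRUE)
  rate <- meta$sampling_rate_hz
  if (is.null(rate)) {
    dt <- median(diff(df$t))
    rate <- if (is.na(dt) || dt <= 0) 50 else 1 / dt
  }
  scores <- meta$scores
  scores <- if (length(scores)) unlist(scores) else numeric(0)
  sig <- triaxial_signal(df$t, df$ax, df$ay, df$az, rate)
  tr <- trial_record(meta$subject_id, meta$group, meta$week, sig,
                     as.integer(df$label), scores)
  gaps <- which(diff(df$t) > 3.5 / rate)
  if (length(gaps)) {
    attr(tr, "gaps") <- data.frame(after_index = gaps - 1L,
                                   gap_s = diff(df$t)[gaps])
    warning(sprintf("%d gap(s) longer than 3 sample periods in %s",
                    length(gaps), path))
  }
  attr(tr, "n_malformed") <- n_malformed
  tr
}

#' Resample an (irregular) triaxial signal onto a uniform grid
#'
#' Linear interpolation onto a uniform grid at `target_rate_hz`, starting at
#' the first timestamp. The duration is preserved to within one sample
#' period. Sensor timestamps from phone/watch hardware are only nominally
#' uniform, so this normalization precedes all spectral analysis.
#'
#' @param sig a `triaxial_signal` whose `t` may be irregular.
#' @param target_rate_hz target sampling rate (Hz).
#' @return A uniform-grid [triaxial_signal()].
#' @export
resample_uniform <- function(sig, target_rate_hz = 50) {
  stopifnot(inherits(sig, "triaxial_signal"))
  t <- sig$t
  if (length(t) < 2) stop("need at least 2 samples to resample")
  if (any(diff(t) == 0)) stop("duplicate timestamps")
  if (any(diff(t) < 0)) stop("timestamps must be increasing")
  n_out <- floor((t[length(t)] - t[1]) * target_rate_hz) + 1L
  if (n_out < 2)
    stop("signal span shorter than 2 samples at the target rate")
  grid <- t[1] + (seq_len(n_out) - 1L) / target_rate_hz
  triaxial_signal(
    grid,
    approx(t, sig$ax, xout = grid)$y,
    approx(t, sig$ay, xout = grid)$y,
    approx(t, sig$az, xout = grid)$y,
    target_rate_hz
  )
}

#' Validate a session directory
#'
#' Attempts to read every trial listed in the directory's `manifest.json`
#' (or, failing that, every subdirectory containing `samples.csv`) and
#' collects validation issues.
#'
#' @param path session directory.
#' @return list with `ok` (logical), `n_trials`, and `issues` (character).
#' @export
validate_session <- function(path) {
  manifest <- file.path(path, "manifest.json")
  if (file.exists(manifest)) {
    trials <- unlist(jsonlite::read_json(manifest,
                                         simplifyVector = TRUE)$trials)
    dirs <- file.path(path, trials)
  } else {
    all_dirs <- list.dirs(path, recursive = FALSE)
    dirs <- all_dirs[file.exists(file.path(all_dirs, "samples.csv"))]
  }
  issues <- character(0)
  n_ok <- 0L
  for (d in dirs) {
    res <- tryCatch({
      suppressWarnings(read_trial(d))
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(res)) n_ok <- n_ok + 1L
    else issues <- c(issues, sprintf("%s: %s", basename(d), res))
  }
  if (length(dirs) == 0) issues <- c(issues, "no trial directories found")
  list(ok = length(issues) == 0, n_trials = length(dirs), issues = issues)
}
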