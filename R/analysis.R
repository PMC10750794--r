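#' Pearson correlation with a two-sided t-test
#'
#' Direct implementation of the product-moment formula
#' `r = sum((x - mx)(y - my)) / sqrt(sum((x - mx)^2) sum((y - my)^2))`
#' with the two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Pairs with a missing value in either variable
#' are dropped first.
#'
#' @param x,y paired numeric vectors.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: zero variance in one of the variables")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Default exercise-to-item pairing for the correlation analysis
#'
#' Exercise 1 (rest-tremor posture, label 1) pairs with item 3.17, exercise 2
#' with 3.15, 4 with 3.4, 5 with 3.5, 6 with 3.6 and 8 with 3.10. Exercises
#' 3 (no standardized clinical assessment) and 7 (too little signal per
#' trial) are excluded.
#'
#' @return data.frame with columns `label_code`, `item`.
#' @export
default_pairing <- function() {
  data.frame(label_code = c(1L, 2L, 4L, 5L, 6L, 8L),
             item = unname(EXERCISE_ITEMS))
}

#' Feature-versus-score Pearson correlation matrix
#'
#' For each paired exercise and each of the 15 per-segment features,
#' correlates the feature across trials with the trial's MDS-UPDRS item
#' score. For label 1 (rest intervals merged with the rest-tremor posture)
#' the longest label-1 segment of each trial is used — the 30 s exercise
#' posture — so inter-exercise rests do not dilute the pairing. Cells with
#' fewer than 3 complete pairs or zero score variance are marked undefined
#' (`r`, `p` = NA), never silently zero.
#'
#' @param feat per-segment feature table from [segment_feature_table()].
#' @param pairing exercise/item pairing, see [default_pairing()].
#' @param features character vector of feature column names; defaults to the
#'   15-feature set.
#' @param adjust_p optional p-value adjustment method (e.g. "BH"); default
#'   "none", matching conventional per-cell reporting.
#' @return data.frame of class `correlation_result` with columns
#'   `feature, label_code, item, r, p, n`.
#' @export
correlation_matrix <- function(feat, pairing = default_pairing(),
                               features = NULL, adjust_p = "none") {
  if (is.null(features)) {
    features <- c("std", "mean", "median", "p25", "p75", "skewness",
                  "max", "min",
                  grep("^bp_", names(feat), value = TRUE))
  }
  missing_cols <- setdiff(features, names(feat))
  if (length(missing_cols))
    stop("feature column(s) not in table: ",
         paste(missing_cols, collapse = ", "))
  out <- list()
  for (pi in seq_len(nrow(pairing))) {
    lab <- pairing$label_code[pi]
    item <- pairing$item[pi]
    score_col <- paste0("score_", item)
    rows <- feat[feat$label_code == lab, , drop = FALSE]
    if (lab == 1L && nrow(rows)) {
      keep <- unlist(lapply(split(seq_len(nrow(rows)), rows$trial_id),
                            function(ii) ii[which.max(rows$duration_s[ii])]))
      rows <- rows[keep, , drop = FALSE]
    }
    for (fname in features) {
      res <- if (nrow(rows) >= 3 && score_col %in% names(rows)) {
        tryCatch(pearson_cor(rows[[fname]], rows[[score_col]]),
                 error = function(e) NULL)
      } else NULL
      out[[length(out) + 1L]] <- data.frame(
        feature = fname, label_code = lab, item = item,
        r = if (is.null(res)) NA_real_ else res$r,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) NA_integer_ else res$n)
    }
  }
  res <- do.call(rbind, out)
  if (adjust_p != "none") {
    ok <- !is.na(res$p)
    res$p_adj <- NA_real_
    res$p_adj[ok] <- stats::p.adjust(res$p[ok], method = adjust_p)
  }
  rownames(res) <- NULL
  class(res) <- c("correlation_result", "data.frame")
  res
}

#' Reshape a correlation result into a feature-by-exercise matrix
#'
#' @param res a `correlation_result` from [correlation_matrix()].
#' @param value which quantity to tabulate: the signed `r`, `abs_r`
#'   (heat-map parity with absolute-magnitude displays), or `p`.
#' @return numeric matrix, rows = features, columns = "ex<label>_<item>".
#' @export
correlation_matrix_wide <- function(res, value = c("r", "abs_r", "p")) {
  value <- match.arg(value)
  v <- switch(value, r = res$r, abs_r = abs(res$r), p = res$p)
  feats <- unique(res$feature)
  cols <- unique(paste0("ex", res$label_code, "_", res$item))
  m <- matrix(NA_real_, length(feats), length(cols),
              dimnames = list(feats, cols))
  m[cbind(match(res$feature, feats),
          match(paste0("ex", res$label_code, "_", res$item), cols))] <- v
  m
}

#' 2-D t-SNE embedding of a windowed feature table, brushed by severity
#'
#' Standardizes the feature columns (zero mean, unit variance; constant or
#' non-finite columns are dropped), then embeds the rows into two dimensions
#' with t-SNE initialized from the first two principal components. The
#' returned coordinates carry the brushing variable: the trial score of
#' `mapping_item` (healthy-control rows score 0 on every item). The input
#' table is never modified.
#'
#' @param feat windowed feature table from [windowed_features()], or a
#'   plain numeric matrix.
#' @param mapping_item MDS-UPDRS item id used for brushing (default "3.17").
#' @param seed RNG seed; the same seed reproduces coordinates exactly.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `nrow >= 3 * perplexity + 2`.
#' @param max_iter gradient-descent iterations (default 1000).
#' @param theta Barnes-Hut accuracy trade-off (0 = exact; default 0.5).
#' @return data.frame of class `embedding_result`: `row_id, dim1, dim2,
#'   score`, with `seed` and `perplexity` attributes.
#' @export
tsne_embed <- function(feat, mapping_item = "3.17", seed = 1L,
                       perplexity = 30, max_iter = 1000L, theta = 0.5) {
  if (is.matrix(feat)) {
    X <- feat
    score <- rep(NA_real_, nrow(X))
  } else {
    meta <- c("trial_id", "subject_id", "group", "week", "label_code",
              "window_index", "score_item", "score")
    X <- as.matrix(feat[, setdiff(names(feat), meta), drop = FALSE])
    score_col <- paste0("score_", mapping_item)
    score <- if (score_col %in% names(feat)) feat[[score_col]]
      else ifelse(!is.na(feat$score_item) & feat$score_item == mapping_item,
                  feat$score, NA_real_)
    score[!is.na(feat$group) & feat$group == "control"] <- 0
  }
  n <- nrow(X)
  max_perp <- floor((n - 2) / 3)
  if (n < 3 * perplexity + 2)
    stop(sprintf(
      "too few rows (%d) for perplexity %g; try perplexity <= %d",
      n, perplexity, max_perp))
  keep <- apply(X, 2, function(v) all(is.finite(v)) && sd(v) > 0)
  X <- scale(X[, keep, drop = FALSE])
  # duplicate rows are legal input; jitter is not applied, Rtsne is run with
  # check_duplicates off so identical windows embed near each other
  set.seed(seed)
  pca <- prcomp(X, rank. = 2)$x
  y0 <- pca / sd(pca[, 1]) * 1e-4
  fit <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = theta,
                      max_iter = max_iter, Y_init = y0, pca = FALSE,
                      check_duplicates = FALSE,
                      eta = max(50, n / 12), verbose = FALSE)
  out <- data.frame(row_id = seq_len(n), dim1 = fit$Y[, 1],
                    dim2 = fit$Y[, 2], score = score)
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perplexity
  attr(out, "mapping_item") <- mapping_item
  class(out) <- c("embedding_result", "data.frame")
  out
}
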