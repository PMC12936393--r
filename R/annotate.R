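#' Distance-to-feature grid
#'
#' Euclidean distance transform (metres) to the pixels selected by a
#' qualifier from a feature layer, e.g. distance to mangrove pixels with at
#' least 20% canopy cover. If no pixel qualifies the result is all-infinite
#' and flagged.
#'
#' @param scene A scene (supplies the grid).
#' @param feature_layer Matrix on the scene grid, or the name of a scene
#'   layer (static layer or feature mask).
#' @param qualifier Function mapping the layer to a logical source mask,
#'   default `>= 20` percent (the canopy-cover rule); pass
#'   `function(v) v == 1` for binary masks.
#' @return Distance matrix (metres) with attribute `all_infinite`.
#' @export
distance_grid <- function(scene, feature_layer,
                          qualifier = function(v) v >= 20) {
  lay <- if (is.character(feature_layer)) {
    scene$static[[feature_layer]] %||% scene$features[[feature_layer]]
  } else feature_layer
  if (is.null(lay)) stop("unknown feature layer")
  src <- qualifier(lay)
  src[is.na(src)] <- FALSE
  d <- distance_transform(src, scene$grid$px)
  if (isTRUE(attr(d, "all_infinite"))) {
    warning("no pixel satisfies the qualifier; distance grid is all-infinite")
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate labelled points with all scene predictors
#'
#' Pure lookup in space and time: static layers by pixel containment,
#' dynamic layers at the nearest stack date not after the point's timestamp
#' (daily/monthly model output treated as step-valid in time). Points
#' outside the grid, or dated before the first dynamic date, keep their row
#' with the affected predictors set `NA` and flagged in the `missing_any`
#' column; nothing is imputed.
#'
#' @param points data.frame with `label`, `animal_id`, `timestamp`, `x`, `y`.
#' @param scene A scene.
#' @return AnnotatedTable: the input columns plus one column per predictor
#'   and `missing_any`; attribute `schema` gives column types.
#' @export
annotate <- function(points, scene) {
  preds <- sample_scene(scene, points$x, points$y, points$timestamp)
  out <- cbind(points, preds)
  out$missing_any <- !stats::complete.cases(preds)
  attr(out, "schema") <- data.frame(
    column = names(preds),
    type = ifelse(names(preds) %in% scene_predictors(scene, categorical = TRUE),
                  "categorical", "continuous"),
    source = ifelse(names(preds) %in% names(scene$dynamic), "dynamic", "static")
  )
  out
}

#' Clip an annotated table to the dynamic coverage window
#'
#' Drops every row (presence and pseudo-absence alike) whose timestamp falls
#' outside `[window[1], window[2]]`; source tracks losing all their rows are
#' logged. Because presences and their matched pseudo-absences share
#' timestamps, clipping preserves their count parity.
#'
#' @param table AnnotatedTable.
#' @param window Two dates (defaults to the scene coverage used upstream).
#' @return Clipped table with attributes `n_dropped`, `tracks_fully_dropped`.
#' @export
temporal_clip <- function(table, window) {
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] <= window[2])
  d <- as.Date(table$timestamp)
  keep <- d >= window[1] & d <= window[2]
  track_key <- paste(table$animal_id, table$segment_id %||% 1L)
  gone <- setdiff(unique(track_key), unique(track_key[keep]))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- attr(table, "schema")
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "tracks_fully_dropped") <- gone
  out
}

#' Pairwise-correlation screen of continuous predictors
#'
#' Pearson correlations on pairwise-complete rows; while any pair is
#' correlated strictly above the threshold (70%: a pair at exactly 0.70 is
#' retained), the member of the worst-offending pair with the larger mean
#' absolute correlation to all other predictors is dropped (ties broken by
#' column order). Zero-variance predictors are dropped first with a
#' warning. Categorical predictors are exempt.
#'
#' @param table AnnotatedTable.
#' @param threshold Correlation threshold (default 0.70).
#' @param categorical Names of categorical predictor columns (defaulted from
#'   the table's schema when present).
#' @return List: `table` (reduced), `report` (`cor_matrix`, `dropped`
#'   data.frame with the partner that triggered each drop, `threshold`).
#' @export
correlation_screen <- function(table, threshold = 0.70, categorical = NULL) {
  schema <- attr(table, "schema")
  if (is.null(categorical) && !is.null(schema)) {
    categorical <- schema$column[schema$type == "categorical"]
  }
  meta <- c("label", "animal_id", "segment_id", "timestamp", "x", "y",
            "sim_id", "missing_any")
  cand <- setdiff(names(table), c(meta, categorical))
  cand <- cand[vapply(table[cand], is.numeric, logical(1))]
  if (length(cand) < 2) stop("need at least 2 continuous predictors")
  dropped <- data.frame(predictor = character(0), partner = character(0),
                        r = numeric(0))
  zv <- cand[vapply(cand, function(p) {
    v <- table[[p]][is.finite(table[[p]])]
    length(v) < 2 || stats::sd(v) == 0
  }, logical(1))]
  if (length(zv)) {
    warning("zero-variance predictors dropped: ", paste(zv, collapse = ", "))
    dropped <- rbind(dropped, data.frame(predictor = zv, partner = NA,
                                         r = NA_real_))
    cand <- setdiff(cand, zv)
  }
  cm <- suppressWarnings(
    stats::cor(table[cand], use = "pairwise.complete.obs"))
  full_cm <- cm
  repeat {
    a <- abs(cm); diag(a) <- 0
    if (all(a <= threshold | is.na(a))) break
    worst <- which(a == max(a, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- colnames(cm)[worst]
    mean_abs <- rowMeans(a, na.rm = TRUE)[pair]
    # drop the more globally collinear member; ties go to later column order
    victim <- if (mean_abs[1] > mean_abs[2]) pair[1]
      else if (mean_abs[2] > mean_abs[1]) pair[2]
      else pair[which.max(match(pair, cand))]
    partner <- setdiff(pair, victim)
    dropped <- rbind(dropped, data.frame(predictor = victim, partner = partner,
                                         r = cm[pair[1], pair[2]]))
    keep <- setdiff(colnames(cm), victim)
    cm <- cm[keep, keep, drop = FALSE]
  }
  out <- table[, setdiff(names(table), dropped$predictor), drop = FALSE]
  attr(out, "schema") <- schema[schema$column %in% names(out), , drop = FALSE]
  list(table = out,
       report = list(cor_matrix = full_cm, dropped = dropped,
                     retained = colnames(cm), threshold = threshold))
}

#' Bhattacharyya coefficient between two samples
#'
#' Overlap of two empirical distributions on shared equal-width bins
#' spanning the pooled range: `BC = sum_i sqrt(p_i q_i)`, 0 for entirely
#' dissimilar and 1 for identical.
#'
#' @param presence,absence Non-empty finite numeric samples.
#' @param n_bins Number of equal-width bins (default 100).
#' @return Coefficient in `[0, 1]`.
#' @export
bhattacharyya <- function(presence, absence, n_bins = 100) {
  presence <- presence[is.finite(presence)]
  absence <- absence[is.finite(absence)]
  if (!length(presence) || !length(absence)) stop("both samples must be non-empty")
  pooled <- range(c(presence, absence))
  if (pooled[1] == pooled[2]) {
    warning("single distinct pooled value; coefficient is 1")
    return(1)
  }
  brk <- seq(pooled[1], pooled[2], length.out = n_bins + 1)
  p <- tabulate(findInterval(presence, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(presence)
  q <- tabulate(findInterval(absence, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(absence)
  sum(sqrt(p * q))
}

#' Environmental-separation report over all continuous predictors
#' @param table AnnotatedTable with `label`.
#' @param n_bins Bins for [bhattacharyya()].
#' @return data.frame (`predictor`, `bc`).
#' @export
separation_report <- function(table, n_bins = 100) {
  schema <- attr(table, "schema")
  preds <- if (!is.null(schema)) {
    schema$column[schema$type == "continuous"]
  } else {
    setdiff(names(table), c("label", "animal_id", "segment_id", "timestamp",
                            "x", "y", "sim_id", "missing_any"))
  }
  preds <- intersect(preds, names(table))
  data.frame(
    predictor = preds,
    bc = vapply(preds, function(p) {
      bhattacharyya(table[[p]][table$label == 1],
                    table[[p]][table$label == 0], n_bins)
    }, numeric(1)),
    row.names = NULL
  )
}
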