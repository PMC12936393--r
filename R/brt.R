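#' Boosted-regression-tree configuration
#'
#' Defaults follow the standard telemetry-habitat setup: tree complexity 5
#' (each tree grown best-first to at most 5 splits), learning rate 0.005,
#' at most 10,000 trees, bag fraction 0.75, five-fold cross-validation.
#' `monotone` maps predictor names to -1/0/+1; constrained splits are
#' rejected when their child Newton values violate the sign, and leaf
#' values are clipped to bounds propagated from every constrained split, so
#' ensemble predictions are globally monotone in each constrained
#' predictor. Class imbalance is left unweighted.
#'
#' @param tree_complexity Maximum splits per tree (>= 1).
#' @param learning_rate Shrinkage in (0, 1].
#' @param max_trees Maximum boosting iterations.
#' @param bag_fraction Row fraction drawn (without replacement) per
#'   iteration, in (0, 1].
#' @param n_folds Cross-validation folds.
#' @param monotone Named integer vector (predictor -> -1, 0, +1), or NULL.
#' @param min_obs Minimum rows per terminal node.
#' @param oob_window Moving-average window (iterations) used to smooth OOB
#'   improvements before locating the best iteration.
#' @param seed Integer seed driving bagging and fold assignment.
#' @return A `brt_config` list.
#' @export
brt_config <- function(tree_complexity = 5, learning_rate = 0.005,
                       max_trees = 10000, bag_fraction = 0.75, n_folds = 5,
                       monotone = NULL, min_obs = 10, oob_window = 50,
                       seed = 1) {
  stopifnot(learning_rate > 0, learning_rate <= 1,
            bag_fraction > 0, bag_fraction <= 1, tree_complexity >= 1)
  structure(list(tree_complexity = as.integer(tree_complexity),
                 learning_rate = learning_rate,
                 max_trees = as.integer(max_trees),
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 monotone = monotone, min_obs = as.integer(min_obs),
                 oob_window = as.integer(oob_window),
                 seed = as.integer(seed)),
            class = "brt_config")
}

# Build the numeric design matrix: categorical columns are recoded to
# contiguous integer codes 0..L-1 with the level tables kept for prediction.
.brt_design <- function(data, predictors, categorical, levels = NULL) {
  X <- matrix(0, nrow(data), length(predictors),
              dimnames = list(NULL, predictors))
  lev <- levels %||% list()
  for (j in seq_along(predictors)) {
    p <- predictors[j]
    v <- data[[p]]
    if (p %in% categorical) {
      if (is.null(lev[[p]])) lev[[p]] <- sort(unique(v[!is.na(v)]))
      X[, j] <- match(v, lev[[p]]) - 1
      if (!is.null(levels) && anyNA(X[, j])) {
        warning("unseen categorical codes in '", p,
                "' routed by majority branch")
      }
      X[is.na(X[, j]), j] <- -1  # unseen code: routed by majority branch
    } else {
      X[, j] <- as.numeric(v)
    }
  }
  list(X = X, levels = lev)
}

#' Fit a boosted regression tree ensemble
#'
#' Stagewise gradient boosting on the Bernoulli deviance: trees are fit
#' best-first to the gradient residuals of a bagged row subset, terminal
#' nodes take one-step Newton values shrunk by the learning rate, and
#' monotone constraints are enforced by split rejection plus propagated
#' value bounds. Deterministic given `cfg$seed`.
#'
#' @param table AnnotatedTable (or any data.frame) with a 0/1 `label`
#'   column and predictor columns.
#' @param cfg A [brt_config()].
#' @param predictors Predictor column names (default: schema columns, or
#'   all non-metadata numeric columns).
#' @param categorical Names of categorical predictors (default from schema).
#' @return A `brt` model: trees, intercept, influence, OOB improvement
#'   series, training design and metadata.
#' @export
brt_fit <- function(table, cfg = brt_config(), predictors = NULL,
                    categorical = NULL) {
  schema <- attr(table, "schema")
  if (is.null(predictors)) {
    predictors <- if (!is.null(schema)) {
      intersect(schema$column, names(table))
    } else {
      setdiff(names(table), c("label", "animal_id", "segment_id", "timestamp",
                              "x", "y", "sim_id", "missing_any"))
    }
  }
  if (is.null(categorical)) {
    categorical <- if (!is.null(schema)) {
      intersect(schema$column[schema$type == "categorical"], predictors)
    } else character(0)
  }
  y <- table$label
  if (any(is.na(y)) || !all(y %in% c(0, 1))) stop("label must be 0/1")
  if (length(unique(y)) < 2) stop("need both classes present")
  cc <- stats::complete.cases(table[predictors])
  if (!all(cc)) {
    message(sum(!cc), " rows with missing predictors dropped before fitting")
    table <- table[cc, , drop = FALSE]
    y <- y[cc]
  }
  # constant predictors carry no splits; skip them up front
  keep <- vapply(predictors, function(p) {
    v <- table[[p]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  predictors <- predictors[keep]
  des <- .brt_design(table, predictors, categorical)
  mono <- integer(length(predictors))
  if (!is.null(cfg$monotone)) {
    m <- cfg$monotone[predictors]
    m[is.na(m)] <- 0L
    mono <- as.integer(m)
    mono[predictors %in% categorical] <- 0L
  }
  n_levels <- vapply(predictors, function(p) {
    if (p %in% categorical) length(des$levels[[p]]) else 0L
  }, integer(1))
  fit <- .brt_fit_cpp(des$X, as.numeric(y), mono, as.integer(n_levels),
                      cfg$max_trees, cfg$learning_rate, cfg$tree_complexity,
                      cfg$bag_fraction, cfg$min_obs, as.double(cfg$seed))
  structure(list(trees = fit$trees, init = fit$init,
                 influence_raw = stats::setNames(fit$influence, predictors),
                 oob_improve = fit$oob_improve,
                 train_deviance = fit$train_deviance,
                 predictors = predictors, categorical = categorical,
                 levels = des$levels, monotone = stats::setNames(mono, predictors),
                 config = cfg, n_trees = cfg$max_trees,
                 X = des$X, y = as.numeric(y)),
            class = "brt")
}

#' @export
print.brt <- function(x, ...) {
  cat(sprintf("<brt> %d trees (lr %.4g, tc %d), %d predictors; top influence: %s\n",
              x$n_trees, x$config$learning_rate, x$config$tree_complexity,
              length(x$predictors),
              paste(utils::head(names(sort(relative_influence(x),
                                           decreasing = TRUE)), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Predict presence probabilities from a fitted BRT
#' @param object A `brt` model.
#' @param newdata data.frame with the model's predictor columns, or a
#'   pre-built design matrix.
#' @param n_trees Number of leading trees to use (default: the model's
#'   selected count).
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.brt <- function(object, newdata, n_trees = NULL,
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  n_trees <- n_trees %||% object$n_trees
  stopifnot(n_trees >= 0, n_trees <= length(object$trees))
  X <- if (is.matrix(newdata)) newdata else {
    miss <- setdiff(object$predictors, names(newdata))
    if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
    .brt_design(newdata, object$predictors, object$categorical,
                object$levels)$X
  }
  F <- .brt_predict_cpp(object$trees, object$init, X,
                        object$config$learning_rate, as.integer(n_trees))
  if (type == "link") F else stats::plogis(F)
}

#' Relative influence of each predictor
#'
#' Each split's squared-error improvement is credited to its predictor and
#' summed over the first `n_trees` trees, then normalised to total 100.
#'
#' @param model A `brt` model.
#' @param n_trees Trees to include (default: the model's selected count).
#' @return Named percentages summing to 100.
#' @export
relative_influence <- function(model, n_trees = NULL) {
  n_trees <- n_trees %||% model$n_trees
  inf <- stats::setNames(numeric(length(model$predictors)), model$predictors)
  for (t in seq_len(n_trees)) {
    tm <- model$trees[[t]]
    sp <- tm[, 1] >= 0
    if (any(sp)) {
      v <- model$predictors[tm[sp, 1] + 1]
      g <- tm[sp, 9]
      for (k in seq_along(v)) inf[v[k]] <- inf[v[k]] + g[k]
    }
  }
  if (sum(inf) <= 0) return(inf)
  100 * inf / sum(inf)
}

#' Predictors exceeding the null-influence threshold
#'
#' Flags predictors whose relative influence exceeds `100 / p`, the
#' influence a predictor would have if all contributed equally.
#' @param model A `brt` model.
#' @param n_trees Trees to include.
#' @return Named logical vector.
#' @export
influential_predictors <- function(model, n_trees = NULL) {
  ri <- relative_influence(model, n_trees)
  ri > 100 / length(ri)
}

#' Partial dependence of the model on one predictor
#'
#' For every grid value, the mean link-scale prediction over the evaluation
#' rows (training rows by default) with that predictor overridden — the
#' brute-force definition, computed in a batched pass.
#'
#' @param model A `brt` model.
#' @param predictor Predictor name.
#' @param grid Override values (default: 100 quantile knots of the training
#'   values; the observed levels for a categorical predictor).
#' @param rows Evaluation design matrix rows (default: all training rows).
#' @param n_trees Trees to include.
#' @return data.frame (`value`, `yhat` on the logit scale).
#' @export
partial_dependence <- function(model, predictor, grid = NULL, rows = NULL,
                               n_trees = NULL) {
  j <- match(predictor, model$predictors)
  if (is.na(j)) stop("unknown predictor: ", predictor)
  n_trees <- n_trees %||% model$n_trees
  X <- rows %||% model$X
  if (is.null(grid)) {
    grid <- if (predictor %in% model$categorical) {
      seq_along(model$levels[[predictor]]) - 1
    } else {
      unique(stats::quantile(model$X[, j], probs = seq(0.005, 0.995,
                                                       length.out = 100),
                             names = FALSE))
    }
  }
  yhat <- .brt_pd_cpp(model$trees, model$init, X, j - 1L, as.numeric(grid),
                      model$config$learning_rate, as.integer(n_trees))
  data.frame(value = grid, yhat = yhat)
}

#' Two-way interaction strength of a predictor pair
#'
#' Builds the two-way partial-dependence surface on quantile knots, removes
#' the best additive (row + column means) approximation, and returns the
#' residual variance scaled by the surface variance: 0 for a perfectly
#' additive pair.
#'
#' @param model A `brt` model.
#' @param pair Character vector of two predictor names.
#' @param knots Knots per axis (default 20).
#' @param rows Evaluation rows (default: all training rows).
#' @param n_trees Trees to include.
#' @return Non-negative score.
#' @export
interaction_strength <- function(model, pair, knots = 20, rows = NULL,
                                 n_trees = NULL) {
  j <- match(pair, model$predictors)
  if (any(is.na(j))) stop("unknown predictor in pair")
  n_trees <- n_trees %||% model$n_trees
  X <- rows %||% model$X
  gr <- lapply(seq_len(2), function(k) {
    p <- pair[k]
    if (p %in% model$categorical) {
      seq_along(model$levels[[p]]) - 1
    } else {
      unique(stats::quantile(model$X[, j[k]],
                             probs = seq(0.02, 0.98, length.out = knots),
                             names = FALSE))
    }
  })
  s <- .brt_pd2_cpp(model$trees, model$init, X, j[1] - 1L, j[2] - 1L,
                    as.numeric(gr[[1]]), as.numeric(gr[[2]]),
                    model$config$learning_rate, as.integer(n_trees))
  resid <- s - outer(rowMeans(s), colMeans(s), `+`) + mean(s)
  vs <- stats::var(as.vector(s))
  if (!is.finite(vs) || vs < 1e-18) return(0)
  stats::var(as.vector(resid)) / vs
}

#' Rank all predictor pairs by interaction strength
#' @param model A `brt` model.
#' @param top Number of pairs to report (default 5).
#' @param ... Passed to [interaction_strength()].
#' @return data.frame (`var1`, `var2`, `score`), strongest first.
#' @export
rank_interactions <- function(model, top = 5, ...) {
  prs <- utils::combn(model$predictors, 2)
  sc <- apply(prs, 2, function(pp) interaction_strength(model, pp, ...))
  ord <- order(sc, decreasing = TRUE)
  utils::head(data.frame(var1 = prs[1, ord], var2 = prs[2, ord],
                         score = sc[ord], row.names = NULL), top)
}

# Seeded stratified fold assignment; re-drawn (up to 10 times) if any fold
# lacks a class.
.make_folds <- function(y, n_folds, seed) {
  for (attempt in 1:10) {
    f <- withr::with_seed(seed + attempt - 1L, {
      fold <- integer(length(y))
      for (cl in unique(y)) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      fold
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(y[f == k])) == 2
    }, logical(1)))
    if (ok) return(f)
  }
  stop("could not build folds with both classes present")
}

#' Five-fold cross-validation of a BRT formulation
#'
#' Rows are partitioned into `cfg$n_folds` seeded folds stratified by
#' label; each fold is held out once and scored with AUC, TSS, TPR and
#' percent deviance explained. Fold means are the headline metrics.
#'
#' @param table Labelled table as for [brt_fit()].
#' @param cfg A [brt_config()].
#' @param predictors,categorical As for [brt_fit()].
#' @return A `brt_cv` list: `models`, per-fold `metrics` data.frame,
#'   `means`, `fold` assignment, `influence` (per-fold matrix).
#' @export
cross_validate <- function(table, cfg = brt_config(), predictors = NULL,
                           categorical = NULL) {
  cc <- stats::complete.cases(
    if (is.null(predictors)) table else table[predictors])
  table <- table[cc, , drop = FALSE]
  fold <- .make_folds(table$label, cfg$n_folds, cfg$seed)
  models <- vector("list", cfg$n_folds)
  mets <- vector("list", cfg$n_folds)
  for (k in seq_len(cfg$n_folds)) {
    tr <- table[fold != k, , drop = FALSE]
    te <- table[fold == k, , drop = FALSE]
    attr(tr, "schema") <- attr(table, "schema")
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + 1000L * k
    m <- brt_fit(tr, cfg_k, predictors, categorical)
    p <- predict(m, te)
    mr <- metric_report(te$label, p)
    models[[k]] <- m
    mets[[k]] <- data.frame(fold = k, auc = mr$auc, tss = mr$tss,
                            tpr = mr$tpr,
                            deviance_explained = mr$deviance_explained)
  }
  metrics <- do.call(rbind, mets)
  infl <- do.call(rbind, lapply(models, relative_influence))
  structure(list(models = models, metrics = metrics,
                 means = colMeans(metrics[, -1]), fold = fold,
                 influence = infl, table = table, cfg = cfg,
                 predictors = models[[1]]$predictors,
                 categorical = models[[1]]$categorical),
            class = "brt_cv")
}

#' Prune predictors that are relatively unimportant in every fold
#'
#' Computes each fold's 10th-percentile influence cutoff and drops a
#' predictor only if its influence falls at or below that cutoff in all
#' folds; a predictor in the lowest 10% in merely most folds is retained.
#' If pruning would empty the list, nothing is dropped.
#'
#' @param cv A `brt_cv` result.
#' @param quantile_cut Per-fold cutoff quantile (default 0.10).
#' @return Character vector of surviving predictors, with attribute
#'   `dropped`.
#' @export
prune_predictors <- function(cv, quantile_cut = 0.10) {
  infl <- cv$influence
  cuts <- apply(infl, 1, stats::quantile, probs = quantile_cut, names = FALSE)
  low_all <- vapply(colnames(infl), function(p) {
    all(infl[, p] <= cuts)
  }, logical(1))
  survivors <- colnames(infl)[!low_all]
  if (length(survivors) == 0) {
    warning("pruning would remove every predictor; keeping all")
    survivors <- colnames(infl)
    low_all[] <- FALSE
  }
  attr(survivors, "dropped") <- colnames(infl)[low_all]
  survivors
}

#' Select the ensemble size from out-of-bag improvements
#'
#' Per fold, the best iteration is the argmax of the cumulative sum of
#' OOB deviance improvements smoothed by a moving average; the returned
#' tree count is the maximum over folds, so it encompasses every fold's
#' best iteration.
#'
#' @param cv A `brt_cv` result (or list of models with `oob_improve`).
#' @param window Moving-average window (default: config's `oob_window`).
#' @return Integer tree count with attribute `per_fold`.
#' @export
select_n_trees_oob <- function(cv, window = NULL) {
  models <- if (inherits(cv, "brt_cv")) cv$models else cv
  window <- window %||% models[[1]]$config$oob_window
  per_fold <- vapply(models, function(m) {
    imp <- m$oob_improve
    n <- length(imp)
    w <- min(window, n)
    sm <- as.numeric(stats::filter(imp, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- imp[is.na(sm)]
    which.max(cumsum(sm))
  }, numeric(1))
  out <- as.integer(max(per_fold))
  attr(out, "per_fold") <- as.integer(per_fold)
  out
}

#' Suggest monotone-constraint signs from empirical-logit trends
#'
#' For each continuous predictor, bins the values into deciles, computes the
#' empirical logit of the label per bin, and reports the sign of the fitted
#' linear trend when the correlation is decisive (|r| > 0.5); weak or
#' categorical predictors get 0. A helper standing in for choosing signs by
#' eye from input-data plots.
#'
#' @param table Labelled table.
#' @param predictors,categorical As for [brt_fit()].
#' @return Named integer vector in {-1, 0, 1}.
#' @export
suggest_monotone <- function(table, predictors = NULL, categorical = NULL) {
  schema <- attr(table, "schema")
  if (is.null(predictors)) {
    predictors <- if (!is.null(schema)) intersect(schema$column, names(table))
      else setdiff(names(table), c("label", "animal_id", "segment_id",
                                   "timestamp", "x", "y", "sim_id",
                                   "missing_any"))
  }
  if (is.null(categorical) && !is.null(schema)) {
    categorical <- schema$column[schema$type == "categorical"]
  }
  out <- stats::setNames(integer(length(predictors)), predictors)
  for (p in setdiff(predictors, categorical)) {
    v <- table[[p]]; y <- table$label
    ok <- is.finite(v) & !is.na(y)
    v <- v[ok]; y <- y[ok]
    if (length(unique(v)) < 10) next
    br <- unique(stats::quantile(v, seq(0, 1, 0.1), names = FALSE))
    if (length(br) < 4) next
    bin <- cut(v, br, include.lowest = TRUE)
    pm <- tapply(y, bin, mean)
    el <- stats::qlogis(pmin(pmax(pm, 1e-4), 1 - 1e-4))
    mid <- tapply(v, bin, mean)
    r <- stats::cor(mid, el, use = "complete.obs")
    if (is.finite(r) && abs(r) > 0.5) out[p] <- as.integer(sign(r))
  }
  out
}

#' Full BRT modelling pipeline: CV, prune, re-CV, OOB size, final fit
#'
#' Runs the initial cross-validation with all predictors and the maximum
#' tree count, prunes predictors unimportant in every fold (single pass),
#' re-runs the cross-validation on the survivors, selects the ensemble size
#' that encompasses every fold's best OOB iteration, and refits the final
#' model on 100% of the rows with that tree count.
#'
#' @param table Labelled table.
#' @param cfg A [brt_config()].
#' @param predictors,categorical As for [brt_fit()].
#' @return List: `model` (final `brt`), `cv` (post-prune `brt_cv`),
#'   `cv_initial`, `survivors`, `n_trees`.
#' @export
brt_pipeline <- function(table, cfg = brt_config(), predictors = NULL,
                         categorical = NULL) {
  cv0 <- cross_validate(table, cfg, predictors, categorical)
  survivors <- prune_predictors(cv0)
  cv1 <- if (length(attr(survivors, "dropped"))) {
    cross_validate(table, cfg, as.character(survivors), cv0$categorical)
  } else cv0
  n_trees <- select_n_trees_oob(cv1)
  final <- brt_fit(table, cfg, as.character(survivors), cv1$categorical)
  final$n_trees <- as.integer(n_trees)
  list(model = final, cv = cv1, cv_initial = cv0,
       survivors = as.character(survivors),
       dropped = attr(survivors, "dropped"), n_trees = n_trees)
}
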