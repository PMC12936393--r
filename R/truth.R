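#' Ground-truth suitability model for synthetic scenes
#'
#' A truth model maps a predictor vector to a suitability probability through
#' a logistic link: `suitability = plogis(intercept + sum_k f_k(x_k))`, where
#' each `f_k` is a closed-form monotone or unimodal effect function and all
#' predictors without an entry in `effects` have exactly zero effect. It is
#' the generating process for the biased movement simulation and the
#' reference for parameter-recovery checks.
#'
#' @param effects Named list of single-argument functions, one per predictor
#'   with nonzero effect; names must be predictor names.
#' @param intercept Intercept on the logit scale.
#' @return A `truth_model` object.
#' @export
truth_model <- function(effects = list(), intercept = 0) {
  stopifnot(is.list(effects),
            all(vapply(effects, is.function, logical(1))))
  structure(list(effects = effects, intercept = intercept,
                 predictors = names(effects)),
            class = "truth_model")
}

#' Default truth: reef-distance and salinity drive suitability
#'
#' Strong monotone preference for water close to reefs (logit effect
#' `-1.6 per km` of reef distance) and a comparably strong unimodal
#' salinity preference centred on the scene's typical offshore salinity
#' (33.5 PSU, 1 PSU tolerance). All other predictors have zero effect.
#' @return A [truth_model()].
#' @export
default_truth <- function() {
  truth_model(
    effects = list(
      distance_to_reef = function(d) -1.6 * d / 1000,
      salinity = function(s) -1.4 * ((s - 33.5) / 1.0)^2
    ),
    intercept = 3.0
  )
}

#' Flat truth (all effects zero)
#' @param p Constant suitability value in (0,1).
#' @return A [truth_model()] with no effects and `intercept = qlogis(p)`.
#' @export
flat_truth <- function(p = 0.5) truth_model(list(), stats::qlogis(p))

#' Evaluate truth suitability for rows of predictors
#' @param truth A [truth_model()].
#' @param predictors data.frame of predictor values (columns named).
#' @return Numeric vector of suitabilities in (0,1); `NA` where a needed
#'   predictor is missing.
#' @export
truth_suitability <- function(truth, predictors) {
  eta <- rep(truth$intercept, nrow(predictors))
  for (nm in names(truth$effects)) {
    if (!nm %in% names(predictors)) {
      stop("truth predictor not in table: ", nm)
    }
    eta <- eta + truth$effects[[nm]](predictors[[nm]])
  }
  stats::plogis(eta)
}

#' Truth suitability over every scene pixel at one date
#' @param truth A [truth_model()].
#' @param scene A scene.
#' @param when Date (defaults to the scene's first date).
#' @return Matrix of suitabilities; `NA` on land.
#' @export
truth_surface <- function(truth, scene, when = scene$dates[1]) {
  g <- scene$grid
  idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  ctr <- cell_xy(g, idx$row, idx$col)
  tab <- sample_scene(scene, ctr$x, ctr$y, when)
  s <- truth_suitability(truth, tab)
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[cbind(idx$row, idx$col)] <- s
  m[scene$land == 1L] <- NA_real_
  m
}
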