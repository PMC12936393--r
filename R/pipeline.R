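#' Example zoning for a synthetic scene
#'
#' Two rectangular zones standing in for a habitat-protection zone (the
#' northern half of the seaward domain) and a port area (a small box around
#' the first facility), in scene coordinates.
#'
#' @param scene A scene.
#' @return List of [zone_polygon()]s.
#' @export
example_zones <- function(scene) {
  g <- scene$grid
  W <- g$n_cols * g$px; H <- g$n_rows * g$px
  fac <- which(scene$features$facility == 1L, arr.ind = TRUE)
  fx <- cell_xy(g, fac[1, 1], fac[1, 2])
  r <- 6 * g$px
  list(
    zone_polygon("protection_zone",
                 x = c(0, W, W, 0), y = c(H / 2, H / 2, H, H)),
    zone_polygon("port_area",
                 x = fx$x + c(-r, r, r, -r), y = fx$y + c(-r, -r, r, r))
  )
}

#' Run the full telemetry-to-habitat-model pipeline on a synthetic scene
#'
#' End-to-end: build a seeded scene, simulate suitability-biased tracks
#' under a known truth, degrade them to raw telemetry, apply QC, regularize
#' with the movement model, generate CRW pseudo-absences, annotate in space
#' and time, clip to coverage, screen collinearity, fit the
#' cross-validated monotone BRT (prune, OOB tree selection, final 100% fit),
#' and map suitability at the first and last scene dates with area, change
#' and zone accounting.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_rows,n_cols,n_dates Scene size.
#' @param n_animals,steps_per_animal Track simulation size.
#' @param n_sims Pseudo-absence simulations per track.
#' @param max_trees BRT iteration cap.
#' @param truth Truth model (default [default_truth()]).
#' @param n_migrants Animals given an injected migration departure.
#' @param map If `TRUE`, also predict surfaces and zone/area accounting.
#' @return List with every stage's outputs (see components).
#' @export
run_habitat_pipeline <- function(seed, n_rows = 128, n_cols = 128,
                                 n_dates = 24, n_animals = 15,
                                 steps_per_animal = 300, n_sims = 9,
                                 max_trees = 2000, truth = default_truth(),
                                 n_migrants = 2, map = TRUE) {
  seed <- as.integer(seed)
  scene <- build_scene(seed, n_rows, n_cols, n_dates)
  paths <- simulate_tracks(scene, truth, n_animals, steps_per_animal,
                           seed = seed + 101L)
  migrants <- if (n_migrants > 0) seq_len(min(n_migrants, n_animals)) else integer(0)
  raw <- degrade_telemetry(paths, seed = seed + 202L,
                           migrate_animals = migrants)
  qc <- qc_pipeline(raw, scene$land, scene$grid)
  reg <- regularize_tracks(qc$tracks)
  if (length(reg$tracks) == 0) stop("no track survived regularization")
  absets <- generate_absence_sets(reg$tracks, scene$land, scene$grid,
                                  n_sims = n_sims, seed = seed + 303L)
  pts <- bind_labelled_points(reg$tracks, absets)
  tab <- annotate(pts, scene)
  tab <- temporal_clip(tab, scene$coverage)
  scr <- correlation_screen(tab)
  sep <- separation_report(scr$table)
  mono <- suggest_monotone(scr$table)
  cfg <- brt_config(max_trees = max_trees, monotone = mono,
                    seed = seed + 404L)
  brt <- brt_pipeline(scr$table, cfg)
  infl <- sort(relative_influence(brt$model), decreasing = TRUE)
  out <- list(scene = scene, truth = truth, paths = paths, raw = raw,
              qc = qc, reg = reg, absence_sets = absets, table = scr$table,
              screen = scr$report, separation = sep, monotone = mono,
              brt = brt, influence = infl,
              metrics = brt$cv$means,
              truth_ranks = match(truth$predictors, names(infl)))
  if (map) {
    d1 <- scene$dates[1]; d2 <- scene$dates[length(scene$dates)]
    s1 <- predict_surface(brt$model, scene, d1)
    s2 <- predict_surface(brt$model, scene, d2)
    zones <- example_zones(scene)
    out$surface_first <- s1
    out$surface_last <- s2
    out$area_first <- suitable_area(s1)
    out$area_last <- suitable_area(s2)
    out$change <- temporal_change(s1, s2)
    out$zones <- zone_overlap(s2, zones)
  }
  out
}
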