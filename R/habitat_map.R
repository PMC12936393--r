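#' Predict a suitability surface over a scene at a date
#'
#' Assembles the per-pixel predictor vectors from the scene (dynamic layers
#' at the nearest date not after `date`), scores them with the fitted model,
#' and masks land pixels and pixels with missing predictors.
#'
#' @param model A `brt` model.
#' @param scene A scene.
#' @param date Prediction date.
#' @param n_trees Trees to use (default: the model's selected count).
#' @return A `suitability_surface`: list with `prob` (matrix in `[0, 1]`,
#'   `NA` on masked pixels), `grid`, `date`, `n_masked`.
#' @export
predict_surface <- function(model, scene, date, n_trees = NULL) {
  g <- scene$grid
  avail <- c(setdiff(names(scene$static), "mangrove_canopy"),
             names(scene$dynamic))
  miss <- setdiff(model$predictors, avail)
  if (length(miss)) stop("predictor layer missing from scene: ",
                         paste(miss, collapse = ", "))
  idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  ctr <- cell_xy(g, idx$row, idx$col)
  tab <- sample_scene(scene, ctr$x, ctr$y, as.Date(date))
  pr <- rep(NA_real_, nrow(tab))
  ok <- stats::complete.cases(tab[model$predictors]) &
    scene$land[cbind(idx$row, idx$col)] == 0L
  if (any(ok)) {
    pr[ok] <- predict(model, tab[ok, , drop = FALSE], n_trees = n_trees)
  }
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[cbind(idx$row, idx$col)] <- pr
  structure(list(prob = m, grid = g, date = as.Date(date),
                 n_masked = sum(!ok)),
            class = "suitability_surface")
}

#' Suitable area above a probability threshold
#'
#' Counts pixels strictly above the threshold (a pixel at exactly 0.5 is
#' not suitable: "more likely than not") times the pixel area; the percent
#' uses the unmasked-pixel total as denominator.
#'
#' @param surface A `suitability_surface`.
#' @param threshold Probability cutoff (default 0.5).
#' @return List: `area_km2`, `percent_of_modelled_area`, `n_suitable`,
#'   `n_valid`.
#' @export
suitable_area <- function(surface, threshold = 0.5) {
  pxkm2 <- (surface$grid$px / 1000)^2
  valid <- !is.na(surface$prob)
  suit <- valid & surface$prob > threshold
  list(area_km2 = sum(suit) * pxkm2,
       percent_of_modelled_area = 100 * sum(suit) / max(1, sum(valid)),
       n_suitable = sum(suit), n_valid = sum(valid))
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorised over points; a point exactly on an edge follows the ray-cast
#' parity convention (half-open edges), so every point gets a deterministic
#' answer.
#'
#' @param px,py Point coordinates.
#' @param vx,vy Polygon vertex coordinates (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Make a named zone polygon
#' @param name Zone name.
#' @param x,y Vertex coordinates (metres, scene CRS).
#' @return A `zone` list.
#' @export
zone_polygon <- function(name, x, y) {
  if (length(x) < 3 || length(x) != length(y) || any(!is.finite(c(x, y)))) {
    stop("invalid polygon for zone '", name, "'")
  }
  structure(list(name = name, x = x, y = y), class = "zone")
}

#' Zone overlap of suitable habitat
#'
#' Assigns each suitable pixel (strictly above the threshold) to the first
#' listed zone whose polygon contains the pixel centre; pixels in no zone
#' are reported as `outside`. Per-zone areas and percentages of the total
#' suitable area sum to 100.
#'
#' @param surface A `suitability_surface`.
#' @param zones List of [zone_polygon()]s (assignment order = list order).
#' @param threshold Probability cutoff (default 0.5).
#' @return data.frame (`zone`, `area_km2`, `percent_of_suitable`).
#' @export
zone_overlap <- function(surface, zones, threshold = 0.5) {
  for (k in seq_along(zones)) {
    z <- zones[[k]]
    if (!inherits(z, "zone")) stop("invalid zone geometry at index ", k)
  }
  g <- surface$grid
  suit <- which(!is.na(surface$prob) & surface$prob > threshold,
                arr.ind = TRUE)
  pxkm2 <- (g$px / 1000)^2
  n_suit <- nrow(suit)
  assigned <- rep(NA_integer_, n_suit)
  if (n_suit > 0) {
    ctr <- cell_xy(g, suit[, 1], suit[, 2])
    for (k in seq_along(zones)) {
      z <- zones[[k]]
      hit <- is.na(assigned) & point_in_polygon(ctr$x, ctr$y, z$x, z$y)
      assigned[hit] <- k
    }
  }
  nm <- c(vapply(zones, `[[`, character(1), "name"), "outside")
  counts <- c(tabulate(assigned, length(zones)), sum(is.na(assigned)))
  data.frame(zone = nm, area_km2 = counts * pxkm2,
             percent_of_suitable = if (n_suit > 0) 100 * counts / n_suit
                                   else rep(0, length(nm)))
}

#' Compare suitable habitat between two dates
#'
#' Reports the suitable areas of both surfaces, the percent change
#' `100 * (b - a) / a` (undefined and reported `NA` when the first area is
#' zero), and a per-pixel classification over the suitable union: `1` for
#' gained (suitable only in `b`), `-1` for lost (only in `a`), `0` for
#' stable (both).
#'
#' @param surface_a,surface_b Surfaces on the same grid.
#' @param threshold Probability cutoff (default 0.5).
#' @return List: `area_a_km2`, `area_b_km2`, `percent_change`,
#'   `classification` (matrix, `NA` outside the suitable union),
#'   `n_gained`, `n_lost`, `n_stable`.
#' @export
temporal_change <- function(surface_a, surface_b, threshold = 0.5) {
  ga <- surface_a$grid; gb <- surface_b$grid
  if (!identical(unclass(ga), unclass(gb))) stop("surfaces on different grids")
  sa <- !is.na(surface_a$prob) & surface_a$prob > threshold
  sb <- !is.na(surface_b$prob) & surface_b$prob > threshold
  pxkm2 <- (ga$px / 1000)^2
  area_a <- sum(sa) * pxkm2
  area_b <- sum(sb) * pxkm2
  cls <- matrix(NA_real_, nrow(sa), ncol(sa))
  cls[sb & !sa] <- 1
  cls[sa & !sb] <- -1
  cls[sa & sb] <- 0
  list(area_a_km2 = area_a, area_b_km2 = area_b,
       percent_change = if (area_a > 0) 100 * (area_b - area_a) / area_a
                        else NA_real_,
       classification = cls,
       n_gained = sum(sb & !sa), n_lost = sum(sa & !sb),
       n_stable = sum(sa & sb))
}
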