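#' Build a seeded synthetic coastal scene
#'
#' Generates the full predictor stack the downstream habitat model consumes:
#' a connected landmass along the western edge with a smoothly varying
#' coastline, offshore reef patches, coastal point facilities (boat-ramp
#' analogues), river mouths, a mangrove canopy-cover fringe, a seagrass
#' probability field, a categorical geohabitat layer, Euclidean
#' distance-to-feature grids derived from the features, and smooth dynamic
#' fields (temperature, salinity, current speed) on a date axis. All layers
#' share one planar metric grid; the generation is bit-reproducible given
#' `seed`.
#'
#' @param seed Integer seed.
#' @param n_rows,n_cols Grid dimensions (>= 32).
#' @param n_dates Number of dates in the dynamic stacks (>= 2); dates are
#'   monthly starting 2018-01-15.
#' @param px Pixel size in metres (default 500, the prediction resolution).
#' @return A `scene` list: `grid`, `land` (0/1 matrix), `static` (named list
#'   of matrices), `dynamic` (named list of `n_rows x n_cols x n_dates`
#'   arrays), `dates` (Date vector), `coverage` (first/last date), and
#'   feature index lists.
#' @export
build_scene <- function(seed, n_rows, n_cols, n_dates, px = 500) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (n_rows < 32 || n_cols < 32) stop("n_rows and n_cols must be >= 32")
  if (n_dates < 2) stop("n_dates must be >= 2")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_dates <- as.integer(n_dates)
  grid <- grid_spec(0, 0, px, n_rows, n_cols, crs = "planar")
  withr::with_seed(as.integer(seed), {
    # --- coastline: land fills the west edge up to a smooth column bound ---
    base_w <- max(3L, round(n_cols * 0.12))
    wig <- stats::filter(stats::rnorm(n_rows), rep(1 / 9, 9), circular = TRUE)
    wig <- as.numeric(wig) / stats::sd(as.numeric(wig))
    coast_col <- pmax(2L, pmin(n_cols %/% 3L,
                               round(base_w + wig * n_cols * 0.03)))
    land <- matrix(0L, n_rows, n_cols)
    for (i in seq_len(n_rows)) land[i, seq_len(coast_col[i])] <- 1L

    # --- reefs: >= 3 elliptical patches offshore, away from the coast ---
    n_reef <- 6L + sample.int(3L, 1L) - 1L
    reef <- matrix(0L, n_rows, n_cols)
    cc <- col(reef); rr <- row(reef)
    reef_ctr <- vector("list", n_reef)
    for (k in seq_len(n_reef)) {
      rc <- sample(seq(round(n_rows * 0.1), round(n_rows * 0.9)), 1L)
      # stagger reef distance from shore so distance_to_reef and
      # distance_to_coast decorrelate
      off <- coast_col[rc] + round(n_cols * (0.12 + 0.55 * (k - 1) / n_reef)) +
        sample(-2:2, 1L)
      kc <- min(n_cols - 2L, off)
      a <- 1.5 + stats::runif(1, 0, n_cols * 0.03)
      b <- 1.5 + stats::runif(1, 0, n_rows * 0.03)
      patch <- ((cc - kc)^2 / a^2 + (rr - rc)^2 / b^2) <= 1
      reef[patch & land == 0L] <- 1L
      reef[rc, kc] <- if (land[rc, kc] == 0L) 1L else reef[rc, kc]
      reef_ctr[[k]] <- c(row = rc, col = kc)
    }

    # --- facilities: >= 2 sea pixels adjacent to land (coastal) ---
    n_fac <- 2L + sample.int(2L, 1L) - 1L
    fac <- matrix(0L, n_rows, n_cols)
    fac_rows <- round(seq(n_rows * 0.2, n_rows * 0.8, length.out = n_fac))
    for (r in fac_rows) fac[r, coast_col[r] + 1L] <- 1L

    # --- rivers: mouths on the coastline ---
    n_riv <- 2L
    riv <- matrix(0L, n_rows, n_cols)
    riv_rows <- round(seq(n_rows * 0.3, n_rows * 0.7, length.out = n_riv))
    for (r in riv_rows) riv[r, coast_col[r]] <- 1L

    # --- mangrove canopy cover (%): fringe near the coast, patchy ---
    d_land <- distance_transform(land == 1L, px)
    mg_noise <- gaussian_field(n_rows, n_cols, range_px = 4)
    canopy <- matrix(pmax(0, pmin(100,
      70 * exp(-d_land / (3 * px)) + 18 * mg_noise)), n_rows, n_cols)
    canopy[land == 1L & d_land == 0 & cc > 1] <- 0  # interior land bare
    canopy[cc > coast_col + 4L] <- pmax(0, canopy[cc > coast_col + 4L] - 40)

    # --- distance grids (metres, exact EDT) ---
    d_reef <- distance_transform(reef == 1L, px)
    d_fac <- distance_transform(fac == 1L, px)
    d_riv <- distance_transform(riv == 1L, px)

    # --- seagrass probability: shallow nearshore bias + own field ---
    sg_f <- gaussian_field(n_rows, n_cols, range_px = 6)
    seagrass <- stats::plogis(1.2 * sg_f + 1.5 * exp(-d_land / (6 * px)) - 1)
    seagrass[land == 1L] <- 0

    # --- geohabitat codes: 1 sand, 2 mud, 3 reef slope, 4 channel, 5 rocky ---
    gh_f <- gaussian_field(n_rows, n_cols, range_px = 5)
    geo <- matrix(1L, n_rows, n_cols)
    geo[gh_f > 0.6] <- 2L
    geo[gh_f < -0.8] <- 4L
    geo[d_reef <= 2 * px] <- 3L
    geo[gh_f > 1.4] <- 5L

    # --- dynamic stacks: AR(1) in time over spatial fields ---
    dates <- seq(as.Date("2018-01-15"), by = "month", length.out = n_dates)
    phi <- 0.7
    mk_stack <- function(range_px) {
      a <- array(0, dim = c(n_rows, n_cols, n_dates))
      f <- gaussian_field(n_rows, n_cols, range_px)
      a[, , 1] <- f
      for (t in 2:n_dates) {
        f <- phi * f + sqrt(1 - phi^2) * gaussian_field(n_rows, n_cols, range_px)
        a[, , t] <- f
      }
      a
    }
    # austral seasonality: warm and wet (flood plumes) in Dec-Mar
    season <- sin(2 * pi * (as.integer(format(dates, "%j")) / 365.25 - 0.25))
    wet <- pmax(0, -season)
    tmp <- mk_stack(20)  # SST varies over tens of km: very smooth in space
    temperature <- array(0, dim = dim(tmp))
    for (t in seq_len(n_dates)) {
      temperature[, , t] <- 25 - 4.5 * season[t] + 0.6 * tmp[, , t]
    }
    temperature <- array(pmin(32, pmax(18, temperature)), dim(temperature))
    sal <- mk_stack(4)
    salinity <- array(0, dim = dim(sal))
    plume <- exp(-d_riv / (8 * px))
    for (t in seq_len(n_dates)) {
      salinity[, , t] <- 33.5 + 1.2 * sal[, , t] - 6 * plume * wet[t]
    }
    salinity <- array(pmin(36, pmax(25, salinity)), dim(salinity))
    cur <- mk_stack(7)
    current_speed <- abs(cur) * 0.35 + 0.05

    scene <- list(
      grid = grid,
      land = land,
      static = list(
        distance_to_reef = d_reef,
        distance_to_coast = d_land,
        distance_to_facility = d_fac,
        distance_to_river = d_riv,
        seagrass_probability = seagrass,
        geohabitat = geo,
        mangrove_canopy = canopy
      ),
      dynamic = list(
        temperature = temperature,
        salinity = salinity,
        current_speed = current_speed
      ),
      dates = dates,
      coverage = c(dates[1], dates[n_dates]),
      features = list(reef = reef, facility = fac, river = riv),
      seed = as.integer(seed)
    )
    class(scene) <- "scene"
    scene
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d x %d @ %gm, %d dates (%s..%s), %d static, %d dynamic layers\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$px, length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)]),
              length(x$static), length(x$dynamic)))
  invisible(x)
}

#' Names of scene predictor layers
#' @param scene A scene.
#' @param categorical If `TRUE`, return only categorical layer names.
#' @return Character vector of predictor names (static + dynamic),
#'   excluding the mangrove canopy source layer (a feature layer from which
#'   distance grids are derived, not a direct predictor).
#' @export
scene_predictors <- function(scene, categorical = FALSE) {
  cats <- "geohabitat"
  if (categorical) return(cats)
  c(setdiff(names(scene$static), "mangrove_canopy"), names(scene$dynamic))
}

# Index of the dynamic date that applies at `when`: nearest date not after.
# Returns 0 if `when` precedes the first date.
.dynamic_index <- function(dates, when) {
  findInterval(as.numeric(as.Date(when)), as.numeric(dates))
}

#' Sample all scene predictors at points in space and time
#'
#' Static layers are sampled by pixel containment; dynamic layers use the
#' stack slice at the nearest date not after each point's date (model output
#' treated as step-valid in time). Points outside the grid, or dated before
#' the first dynamic date, get `NA` in the affected columns.
#'
#' @param scene A scene.
#' @param x,y Point coordinates (metres).
#' @param when Dates or POSIXct timestamps (vectorised or length 1).
#' @return data.frame with one column per predictor.
#' @export
sample_scene <- function(scene, x, y, when) {
  n <- length(x)
  when <- as.Date(rep_len(as.Date(when), n))
  out <- list()
  for (nm in setdiff(names(scene$static), "mangrove_canopy")) {
    out[[nm]] <- sample_layer(scene$static[[nm]], scene$grid, x, y)
  }
  rc <- xy_cell(scene$grid, x, y)
  di <- .dynamic_index(scene$dates, when)
  for (nm in names(scene$dynamic)) {
    v <- rep(NA_real_, n)
    ok <- !is.na(rc$row) & di >= 1L
    if (any(ok)) {
      v[ok] <- scene$dynamic[[nm]][cbind(rc$row[ok], rc$col[ok], di[ok])]
    }
    out[[nm]] <- v
  }
  as.data.frame(out)
}

#' Test whether points fall on land
#' @param scene A scene (or pass `land` + `grid`).
#' @param x,y Coordinates.
#' @return Logical; `NA` outside the grid.
#' @export
on_land <- function(scene, x, y) {
  v <- sample_layer(scene$land, scene$grid, x, y)
  v == 1
}
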