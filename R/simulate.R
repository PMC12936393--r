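#' Draw wrapped-Cauchy turning angles
#'
#' Inversion sampler for the wrapped Cauchy distribution with mean direction
#' `mu` and concentration `rho` in `[0, 1)`; `rho = 0` is circular uniform.
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param rho Concentration.
#' @return Angles wrapped to `(-pi, pi]`.
#' @export
rwrapped_cauchy <- function(n, mu = 0, rho = 0.7) {
  stopifnot(rho >= 0, rho < 1)
  u <- stats::runif(n)
  th <- mu + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
  wrap_angle(th)
}

#' Wrap angles to (-pi, pi]
#' @param theta Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

#' Wrapped-Cauchy CDF on (-pi, pi] (mu = 0)
#' @param q Angles.
#' @param rho Concentration.
#' @return CDF values.
#' @export
pwrapped_cauchy <- function(q, rho = 0.7) {
  0.5 + atan(((1 + rho) / (1 - rho)) * tan(q / 2)) / pi
}

#' Simulate true foraging paths as suitability-biased correlated random walks
#'
#' Each animal takes steps at a fixed interval (default 2 h): step lengths
#' are gamma-distributed, turning angles wrapped Cauchy. A candidate step is
#' accepted with probability equal to the truth suitability at the candidate
#' position; rejected candidates are redrawn, so under a flat truth the
#' realised kernel equals the proposal kernel. Candidates on land or outside
#' the grid are always redrawn: no true position is ever on land. Start
#' positions are sea pixels sampled with probability proportional to truth
#' suitability at the animal's start date.
#'
#' @param scene A scene.
#' @param truth A [truth_model()].
#' @param n_animals Number of animals (>= 1).
#' @param steps_per_animal Steps per path (>= 50).
#' @param seed Integer seed.
#' @param dt_hours True-position interval in hours (default 2, emulating tag
#'   duty cycling ahead of 12-h regularization).
#' @param step_shape,step_scale Gamma step-length kernel (metres); defaults
#'   give a 600 m mean per 2-h step.
#' @param rho Turning-angle concentration (wrapped Cauchy).
#' @param max_tries Candidate redraws before the heading is reflected.
#' @return data.frame (`animal_id`, `timestamp` POSIXct UTC, `x`, `y`) of
#'   true positions, `dt_hours` etc. as attributes.
#' @export
simulate_tracks <- function(scene, truth, n_animals, steps_per_animal, seed,
                            dt_hours = 2, step_shape = 2, step_scale = 300,
                            rho = 0.7, max_tries = 100) {
  stopifnot(n_animals >= 1)
  if (steps_per_animal < 50) stop("steps_per_animal must be >= 50")
  g <- scene$grid
  # truth suitability is a pure function of (pixel, date): precompute one
  # surface per scene date so candidate evaluation is a lookup
  suit_stack <- array(NA_real_, c(g$n_rows, g$n_cols, length(scene$dates)))
  for (t in seq_along(scene$dates)) {
    suit_stack[, , t] <- truth_surface(truth, scene, scene$dates[t])
  }
  withr::with_seed(as.integer(seed), {
    # start weights: suitability at the scene mid-date over sea pixels
    mid <- ceiling(length(scene$dates) / 2)
    suit0 <- suit_stack[, , mid]
    sea <- which(scene$land == 0L & !is.na(suit0))
    if (length(sea) == 0) stop("no sea pixel available for track starts")
    w <- suit0[sea]
    # span the coverage window so annotation exercises the date axis
    span_days <- as.numeric(scene$coverage[2] - scene$coverage[1])
    need_days <- steps_per_animal * dt_hours / 24
    out <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      start_off <- stats::runif(1, 0, max(0, span_days - need_days))
      t0 <- as.POSIXct(scene$coverage[1], tz = "UTC") + start_off * 86400
      cell <- sea[sample.int(length(sea), 1, prob = w)]
      rc <- arrayInd(cell, dim(scene$land))
      ctr <- cell_xy(g, rc[1], rc[2])
      x <- numeric(steps_per_animal); y <- numeric(steps_per_animal)
      x[1] <- ctr$x; y[1] <- ctr$y
      heading <- stats::runif(1, -pi, pi)
      times <- t0 + (seq_len(steps_per_animal) - 1) * dt_hours * 3600
      dix <- .dynamic_index(scene$dates, as.Date(times))
      for (i in 2:steps_per_animal) {
        placed <- FALSE
        tries <- 0L
        h <- heading
        di <- max(dix[i], 1L)
        while (!placed) {
          tries <- tries + 1L
          if (tries > max_tries) {
            h <- wrap_angle(h + pi)
            tries <- 1L
          }
          len <- stats::rgamma(1, shape = step_shape, scale = step_scale)
          turn <- rwrapped_cauchy(1, 0, rho)
          cand_h <- wrap_angle(h + turn)
          cx <- x[i - 1] + len * cos(cand_h)
          cy <- y[i - 1] + len * sin(cand_h)
          cc <- floor(cx / g$px - g$x0 / g$px) + 1L
          cr <- floor(cy / g$px - g$y0 / g$px) + 1L
          if (cr < 1L || cr > g$n_rows || cc < 1L || cc > g$n_cols) next
          s <- suit_stack[cr, cc, di]
          if (is.na(s)) next  # land or missing predictors
          if (stats::runif(1) < s) {
            x[i] <- cx; y[i] <- cy; heading <- cand_h
            placed <- TRUE
          }
        }
      }
      out[[a]] <- data.frame(animal_id = a, timestamp = times, x = x, y = y)
    }
    paths <- do.call(rbind, out)
    attr(paths, "dt_hours") <- dt_hours
    attr(paths, "kernel") <- list(step_shape = step_shape,
                                  step_scale = step_scale, rho = rho)
    paths
  })
}
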