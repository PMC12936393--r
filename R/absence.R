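#' Empirical movement statistics of a regularized track
#'
#' Step lengths are the norms of successive displacements (metres per
#' timestep); turning angles are the signed changes in heading between
#' successive steps, wrapped to `(-pi, pi]`. Zero-length steps have
#' undefined headings: the affected angles are skipped and counted.
#'
#' @param rt A RegularizedTrack (>= 4 estimates).
#' @return A `move_stats` list: `steps` (length n-1), `angles`
#'   (length n-2 minus skipped), `n_skipped_angles`.
#' @export
extract_move_stats <- function(rt) {
  n <- nrow(rt)
  if (n < 4) stop("need at least 4 estimates")
  dx <- diff(rt$x); dy <- diff(rt$y)
  steps <- sqrt(dx^2 + dy^2)
  ok <- steps > 1e-9
  head <- atan2(dy, dx)
  angles <- numeric(0)
  skipped <- 0L
  for (i in 2:length(steps)) {
    if (ok[i] && ok[i - 1]) {
      angles <- c(angles, wrap_angle(head[i] - head[i - 1]))
    } else {
      skipped <- skipped + 1L
    }
  }
  structure(list(steps = steps, angles = angles, n_skipped_angles = skipped),
            class = "move_stats")
}

#' Simulate one correlated-random-walk pseudo-absence track
#'
#' Starting from the source track's first estimated position with a uniform
#' initial heading, each subsequent point is placed by independently
#' resampling (with replacement) one empirical step length and one empirical
#' turning angle. A candidate on a land pixel is redrawn (both step and
#' angle) up to `max_tries` times; if exhausted, the heading is reflected by
#' pi and drawing continues. As a last resort the walker stays in place for
#' that timestep (the current position is at sea), so no simulated point is
#' ever on land.
#'
#' @param ms A [extract_move_stats()] result.
#' @param start Numeric `c(x, y)` at sea.
#' @param timestamps Timestamps to copy onto the simulated points.
#' @param land 0/1 land matrix.
#' @param grid The mask [grid_spec()].
#' @param seed Integer seed.
#' @param max_tries Redraws before reflection (default 100).
#' @return data.frame (`timestamp`, `x`, `y`).
#' @export
simulate_crw <- function(ms, start, timestamps, land, grid, seed,
                         max_tries = 100) {
  stopifnot(max_tries >= 1)
  sl <- sample_layer(land, grid, start[1], start[2])
  if (!is.na(sl) && sl == 1) stop("start position is on land")
  n <- length(timestamps)
  withr::with_seed(as.integer(seed), {
    x <- numeric(n); y <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]
    heading <- stats::runif(1, -pi, pi)
    for (i in seq_len(n)[-1]) {
      placed <- FALSE
      tries <- 0L
      reflections <- 0L
      while (!placed) {
        tries <- tries + 1L
        if (tries > max_tries) {
          heading <- wrap_angle(heading + pi)
          tries <- 0L
          reflections <- reflections + 1L
          if (reflections > 4L) {  # stay put: current position is at sea
            x[i] <- x[i - 1]; y[i] <- y[i - 1]
            break
          }
          next
        }
        st <- ms$steps[sample.int(length(ms$steps), 1)]
        tu <- if (length(ms$angles)) {
          ms$angles[sample.int(length(ms$angles), 1)]
        } else 0
        h <- wrap_angle(heading + tu)
        cx <- x[i - 1] + st * cos(h)
        cy <- y[i - 1] + st * sin(h)
        lv <- sample_layer(land, grid, cx, cy)
        if (is.na(lv) || lv == 1) next
        x[i] <- cx; y[i] <- cy; heading <- h
        placed <- TRUE
      }
    }
    data.frame(timestamp = timestamps, x = x, y = y)
  })
}

#' Generate pseudo-absence sets for a list of regularized tracks
#'
#' Simulates `n_sims` independent CRWs per source track (default 9; the
#' pooled absence:presence ratio this yields matches the roughly 9:1 ratio
#' implied by pooled presence/pseudo-absence totals in comparable studies).
#' Per-simulation seeds are derived deterministically from
#' `(seed, track index, sim index)`.
#'
#' @param rts List of RegularizedTracks.
#' @param land 0/1 land matrix.
#' @param grid The mask [grid_spec()].
#' @param n_sims Simulations per track (>= 1).
#' @param seed Integer master seed.
#' @return List of `absence_set` objects: each carries `animal_id`,
#'   `segment_id`, `n_sims` and `points` (`sim_id`, `timestamp`, `x`, `y`),
#'   with exactly `n_sims * n_estimates` points.
#' @export
generate_absence_sets <- function(rts, land, grid, n_sims = 9, seed = 1) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  out <- vector("list", length(rts))
  for (k in seq_along(rts)) {
    rt <- rts[[k]]
    ms <- extract_move_stats(rt)
    pts <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      sd_ks <- (as.integer(seed) %% 1000000L) * 2011L + k * 131L + s * 7L
      sim <- simulate_crw(ms, c(rt$x[1], rt$y[1]), rt$timestamp,
                          land, grid, seed = sd_ks %% .Machine$integer.max)
      sim$sim_id <- s
      pts[[s]] <- sim
    }
    pts <- do.call(rbind, pts)
    out[[k]] <- structure(
      list(animal_id = rt$animal_id[1], segment_id = rt$segment_id[1],
           n_sims = n_sims,
           points = pts[, c("sim_id", "timestamp", "x", "y")]),
      class = "absence_set")
  }
  out
}

#' Bind presences and pseudo-absences into one labelled point table
#' @param rts List of RegularizedTracks (label 1).
#' @param absence_sets List from [generate_absence_sets()] (label 0).
#' @return data.frame (`label`, `animal_id`, `segment_id`, `timestamp`,
#'   `x`, `y`).
#' @export
bind_labelled_points <- function(rts, absence_sets) {
  pres <- do.call(rbind, lapply(rts, function(rt) {
    data.frame(label = 1L, animal_id = rt$animal_id, segment_id = rt$segment_id,
               timestamp = rt$timestamp, x = rt$x, y = rt$y)
  }))
  abs <- do.call(rbind, lapply(absence_sets, function(as_) {
    data.frame(label = 0L, animal_id = as_$animal_id,
               segment_id = as_$segment_id,
               timestamp = as_$points$timestamp,
               x = as_$points$x, y = as_$points$y)
  }))
  rbind(pres, abs)
}
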