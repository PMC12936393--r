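# Small fixture builders shared by the suite. Everything is generated in
# code; no data files.

# A minimal hand-built scene: all-sea except a western land strip, constant
# and patterned layers chosen for exact lookups.
tiny_scene <- function(n_rows = 32, n_cols = 32, px = 500,
                       dates = as.Date(c("2020-01-10", "2020-01-20"))) {
  g <- grid_spec(0, 0, px, n_rows, n_cols)
  land <- matrix(0L, n_rows, n_cols)
  land[, 1:2] <- 1L
  reef <- matrix(0L, n_rows, n_cols)
  reef[n_rows %/% 2, n_cols %/% 2] <- 1L
  dyn <- array(0, c(n_rows, n_cols, length(dates)))
  for (t in seq_along(dates)) dyn[, , t] <- t * 10
  sc <- list(
    grid = g, land = land,
    static = list(
      distance_to_reef = distance_transform(reef == 1L, px),
      distance_to_coast = distance_transform(land == 1L, px),
      distance_to_facility = matrix(7, n_rows, n_cols),
      distance_to_river = matrix(3, n_rows, n_cols),
      seagrass_probability = matrix(0.5, n_rows, n_cols),
      geohabitat = matrix(1L, n_rows, n_cols),
      mangrove_canopy = matrix(0, n_rows, n_cols)
    ),
    dynamic = list(temperature = dyn, salinity = dyn + 100,
                   current_speed = dyn / 100),
    dates = dates, coverage = range(dates),
    features = list(reef = reef, facility = reef, river = reef),
    seed = 0L
  )
  class(sc) <- "scene"
  sc
}

# Straight-line GPS track: one animal, hourly fixes, planar metres.
straight_track <- function(n = 50, speed_kmh = 1, t0 = as.POSIXct("2020-01-01", tz = "UTC")) {
  data.frame(
    animal_id = 1,
    timestamp = t0 + (seq_len(n) - 1) * 3600,
    x = (seq_len(n) - 1) * speed_kmh * 1000,
    y = 0,
    lc = "G", tag_type = "GPS"
  )
}

# A labelled table with a separable signal in x1 among noise predictors.
separable_table <- function(n = 2000, p_noise = 4, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * p_noise), n)
    colnames(noise) <- paste0("noise", seq_len(p_noise))
    data.frame(label = as.integer(x1 > 0), x1 = x1, noise)
  })
}

# Logistic-truth table: y ~ Bernoulli(plogis(b1*x1 + b2*x2)).
logistic_table <- function(n, b1 = 1.2, b2 = -0.8, p_noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    pr <- stats::plogis(b1 * x1 + b2 * x2)
    out <- data.frame(label = stats::rbinom(n, 1, pr), x1 = x1, x2 = x2)
    if (p_noise > 0) {
      noise <- matrix(stats::rnorm(n * p_noise), n)
      colnames(noise) <- paste0("noise", seq_len(p_noise))
      out <- cbind(out, noise)
    }
    attr(out, "true_p") <- pr
    out
  })
}

# Fabricated suitability surface on a given grid.
fake_surface <- function(prob, px = 500) {
  structure(list(prob = prob,
                 grid = grid_spec(0, 0, px, nrow(prob), ncol(prob)),
                 date = as.Date("2020-01-01"), n_masked = sum(is.na(prob))),
            class = "suitability_surface")
}
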