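#' Per-class positional error model
#'
#' Isotropic (circular normal) positional error per location quality class,
#' parameterised by the mean radial error in metres. For a circular normal
#' the radial error is Rayleigh, so the per-axis standard deviation is
#' `mean_radial / sqrt(pi / 2)`; the GPS class uses a 40 m mean radial error
#' and ARGOS classes 3/2/1 use 250/500/1500 m, with the low-quality classes
#' 0/A/B (destined for removal during QC) at 3/5/10 km.
#'
#' @param mean_radial Named numeric vector of mean radial errors (m) by class.
#' @return An `error_model` list with per-class per-axis sigmas.
#' @export
error_model <- function(mean_radial = c(G = 40, `3` = 250, `2` = 500,
                                        `1` = 1500, `0` = 3000, A = 5000,
                                        B = 10000)) {
  stopifnot(all(mean_radial > 0))
  structure(list(mean_radial = mean_radial,
                 sigma = mean_radial / sqrt(pi / 2)),
            class = "error_model")
}

#' Degrade true paths into raw telemetry
#'
#' Emulates tag realities: irregular sampling (independent per-fix
#' retention), class-dependent positional noise, exact duplicate rows, empty
#' rows, shuffled row order, and — for flagged animals — a long directed
#' departure segment (> 150 km) appended to the end of the path, standing in
#' for a breeding migration. True coordinates are carried in `true_x`,
#' `true_y` for validation only; downstream QC ignores them.
#'
#' @param paths True paths from [simulate_tracks()].
#' @param err An [error_model()].
#' @param seed Integer seed.
#' @param retention Per-fix retention probability in (0, 1].
#' @param gps_prob Probability a retained fix is Fastloc GPS (class `G`);
#'   otherwise an ARGOS class is drawn from `argos_probs`.
#' @param argos_probs Named probabilities over ARGOS classes 3,2,1,0,A,B.
#' @param dup_frac Fraction of rows duplicated exactly (count is
#'   `ceiling(dup_frac * n)`).
#' @param empty_frac Fraction of empty (NA-coordinate) rows injected.
#' @param migrate_animals Integer ids of animals given a departure segment.
#' @param migration_km Total departure length (km), > 150 by construction.
#' @return data.frame `RawTelemetry`: `animal_id`, `timestamp`, `lon`, `lat`
#'   (planar metres relabelled; attribute `crs = "planar"`), `lc`,
#'   `tag_type`, `true_x`, `true_y`.
#' @export
degrade_telemetry <- function(paths, err = error_model(), seed,
                              retention = 0.45, gps_prob = 0.7,
                              argos_probs = c(`3` = 0.3, `2` = 0.3, `1` = 0.2,
                                              `0` = 0.08, A = 0.07, B = 0.05),
                              dup_frac = 0.02, empty_frac = 0.01,
                              migrate_animals = integer(0),
                              migration_km = 250) {
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  dt_hours <- attr(paths, "dt_hours")
  if (is.null(dt_hours)) dt_hours <- 2
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (a in unique(paths$animal_id)) {
      p <- paths[paths$animal_id == a, , drop = FALSE]
      if (a %in% migrate_animals) {
        # directed departure: constant heading, brisk steps, same cadence
        n_mig <- max(30L, ceiling(migration_km * 1000 / 7000))
        h <- stats::runif(1, -pi, pi)
        step <- migration_km * 1000 / n_mig
        lastx <- p$x[nrow(p)]; lasty <- p$y[nrow(p)]
        mt <- p$timestamp[nrow(p)] + seq_len(n_mig) * dt_hours * 3600
        mx <- lastx + cumsum(rep(step * cos(h), n_mig))
        my <- lasty + cumsum(rep(step * sin(h), n_mig))
        p <- rbind(p, data.frame(animal_id = a, timestamp = mt, x = mx, y = my))
      }
      keep <- stats::runif(nrow(p)) < retention
      keep[1] <- TRUE
      p <- p[keep, , drop = FALSE]
      n <- nrow(p)
      is_gps <- stats::runif(n) < gps_prob
      lc <- ifelse(is_gps, "G",
                   sample(names(argos_probs), n, TRUE, argos_probs))
      sg <- err$sigma[lc]
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = a,
        timestamp = p$timestamp,
        lon = p$x + stats::rnorm(n, 0, sg),
        lat = p$y + stats::rnorm(n, 0, sg),
        lc = lc,
        tag_type = ifelse(is_gps, "GPS", "ARGOS"),
        true_x = p$x, true_y = p$y
      )
    }
    raw <- do.call(rbind, rows)
    n <- nrow(raw)
    n_dup <- ceiling(dup_frac * n)
    if (n_dup > 0) {
      raw <- rbind(raw, raw[sample.int(n, n_dup, replace = FALSE), ,
                            drop = FALSE])
    }
    n_empty <- ceiling(empty_frac * n)
    if (n_empty > 0) {
      er <- raw[sample.int(n, n_empty, replace = FALSE), , drop = FALSE]
      er$lon <- NA_real_; er$lat <- NA_real_
      er$true_x <- NA_real_; er$true_y <- NA_real_
      raw <- rbind(raw, er)
    }
    raw <- raw[sample.int(nrow(raw)), , drop = FALSE]
    rownames(raw) <- NULL
    attr(raw, "crs") <- "planar"
    attr(raw, "n_duplicates") <- n_dup
    attr(raw, "n_empty") <- n_empty
    raw
  })
}
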