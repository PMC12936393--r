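test_that("basic cleaning: burn-in, class filter, dedup arithmetic", {
  t0 <- as.POSIXct("2020-01-01 00:00", tz = "UTC")
  # 10 rows, 3 within the first 24 h -> 7 remain
  d <- data.frame(animal_id = 1,
                  timestamp = t0 + c(0, 5, 23, 24, 30, 40, 50, 60, 70, 80) * 3600,
                  lon = 1:10 * 100, lat = 0, lc = "G", tag_type = "GPS")
  out <- basic_clean(d)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "qc_log")$burn_in, 3L)

  # one ARGOS row of each class: only 1, 2, 3 survive
  d2 <- data.frame(animal_id = 1,
                   timestamp = t0 + (26:31) * 3600,
                   lon = 1:6, lat = 0,
                   lc = c("3", "2", "1", "0", "A", "B"), tag_type = "ARGOS")
  cfg0 <- qc_config(burn_in_hours = 1e-9)
  out2 <- basic_clean(d2, cfg0, release = c(`1` = t0))
  expect_setequal(out2$lc, c("1", "2", "3"))
  expect_equal(nrow(out2), 3)

  # k exact duplicates -> k fewer rows
  d3 <- rbind(d, d[c(5, 6, 7), ])
  out3 <- basic_clean(d3)
  expect_equal(nrow(out3), nrow(out))
  expect_equal(attr(out3, "qc_log")$duplicates, 3L)

  # empty rows removed and counted
  d4 <- rbind(d, data.frame(animal_id = 1, timestamp = t0 + 100 * 3600,
                            lon = NA, lat = NA, lc = "G", tag_type = "GPS"))
  out4 <- basic_clean(d4)
  expect_equal(attr(out4, "qc_log")$empty_rows, 1L)
})

test_that("speed filter removes double-leg violations only", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  # three collinear fixes; middle displaced so both legs run at 12 km/h
  f <- data.frame(animal_id = 1, timestamp = t0 + (0:2) * 3600,
                  x = c(0, 12000, 2000), y = 0)
  out <- speed_angle_filter(f)
  expect_equal(nrow(out), 2)
  expect_equal(out$x, c(0, 2000))
  # uniform 5 km/h straight track untouched
  g <- straight_track(20, speed_kmh = 5)
  out2 <- speed_angle_filter(g)
  expect_equal(nrow(out2), 20)
  # fewer than 3 fixes returned unchanged with warning
  expect_warning(speed_angle_filter(g[1:2, ]), "fewer than 3")
})

test_that("injected spikes are removed with minimal collateral damage", {
  withr::with_seed(31, {
    n <- 200
    t0 <- as.POSIXct("2020-01-01", tz = "UTC")
    # slow meandering base track, ~0.7 km/h
    ang <- cumsum(stats::rnorm(n, 0, 0.4))
    f <- data.frame(animal_id = 1, timestamp = t0 + (0:(n - 1)) * 3600,
                    x = cumsum(700 * cos(ang)), y = cumsum(700 * sin(ang)))
    spikes <- sort(sample(seq(10, n - 10, by = 6), 20))
    f$y[spikes] <- f$y[spikes] + 35000  # both legs > 30 km/h
    out <- speed_angle_filter(f)
    kept_times <- out$timestamp
    spike_times <- f$timestamp[spikes]
    expect_equal(sum(spike_times %in% kept_times), 0)  # all spikes removed
    clean_times <- f$timestamp[-spikes]
    n_clean_removed <- sum(!clean_times %in% kept_times)
    expect_lte(n_clean_removed / length(clean_times), 0.01)
  })
})

test_that("terrestrial filter drops by pixel containment", {
  sc <- tiny_scene()
  withr::with_seed(5, {
    f <- data.frame(animal_id = 1,
                    timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                      (1:100) * 3600,
                    x = stats::runif(100, 2.5 * 500, 31 * 500),
                    y = stats::runif(100, 0.5 * 500, 31 * 500))
    # move 5 fixes onto the land strip (columns 1-2)
    f$x[1:5] <- 1.2 * 500
    out <- remove_terrestrial(f, sc$land, sc$grid)
    expect_equal(nrow(out), 95)
    expect_equal(attr(out, "n_on_land"), 5L)
    # all-sea track: identity
    out2 <- remove_terrestrial(f[6:100, ], sc$land, sc$grid)
    expect_equal(nrow(out2), 95)
  })
  # boundary point: containment by the half-open pixel rule
  b <- data.frame(animal_id = 1, timestamp = as.POSIXct("2020-01-01", tz = "UTC"),
                  x = 2 * 500, y = 5 * 500)  # exactly on the land/sea edge
  outb <- remove_terrestrial(b, sc$land, sc$grid)
  # x = 1000 m opens pixel column 3 (sea): the fix is retained
  expect_equal(nrow(outb), 1)
})

test_that("gap splitting and minimum-size trimming follow strict inequalities", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  ts <- t0 + c(0:29, 30:49 + 80) * 3600  # 80-h gap after fix 30
  f <- data.frame(animal_id = 1, timestamp = ts, x = seq_along(ts) * 100, y = 0)
  segs <- split_and_trim(f)
  expect_length(segs, 1)          # 20-fix tail discarded (needs > 20)
  expect_equal(nrow(segs[[1]]), 30)
  # no gap over 72 h: single track
  g <- straight_track(40)
  expect_length(split_and_trim(g), 1)
  # gap of exactly 72.0 h does not split
  ts2 <- t0 + c(0:29, 30:59 + 72 - 1) * 3600
  h <- data.frame(animal_id = 1, timestamp = ts2, x = seq_along(ts2), y = 0)
  expect_length(split_and_trim(h), 1)
})

test_that("migration removal truncates departures and keeps residents", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  # resident phase then a 300-km departure
  res_n <- 40
  dep_n <- 30
  f <- data.frame(animal_id = 1, segment_id = 1,
                  timestamp = t0 + seq_len(res_n + dep_n) * 3600,
                  x = c(stats::rnorm(res_n, 0, 800),
                        seq_len(dep_n) * 10000),
                  y = 0)
  out <- remove_migrations(list(f))
  expect_length(out, 1)
  d <- sqrt((out[[1]]$x - out[[1]]$x[1])^2 + (out[[1]]$y - out[[1]]$y[1])^2)
  expect_lt(max(d) / 1000, 150)
  # resident track (max displacement 20 km): identity
  g <- data.frame(animal_id = 2, segment_id = 1,
                  timestamp = t0 + (1:50) * 3600,
                  x = seq(0, 20000, length.out = 50), y = 0)
  out2 <- remove_migrations(list(g))
  expect_equal(nrow(out2[[1]]), 50)
  # drop_track mode discards the whole animal
  out3 <- remove_migrations(list(f), qc_config(migration_mode = "drop_track"))
  expect_length(out3, 0)
})

test_that("departure-and-return loops keep an adequate post-return segment", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  pre_n <- 30; loop_n <- 100; post_n <- 30
  x <- c(stats::rnorm(pre_n, 0, 500),
         c(seq(20000, 300000, length.out = loop_n / 2),
           seq(300000, 20000, length.out = loop_n / 2)),
         stats::rnorm(post_n, 0, 500))
  f <- data.frame(animal_id = 1, segment_id = 1,
                  timestamp = t0 + seq_along(x) * 3600, x = x, y = 0)
  out <- remove_migrations(list(f))
  # both the pre-departure and post-return phases have > 20 fixes
  expect_length(out, 2)
  for (tr in out) {
    d <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
    expect_lt(max(d) / 1000, 150)
    expect_gt(nrow(tr), 20)
  }
})

test_that("QC pipeline conserves counts and is idempotent on its own output", {
  sc <- build_scene(6, 48, 48, 4)
  p <- simulate_tracks(sc, default_truth(), 3, 120, seed = 4)
  raw <- degrade_telemetry(p, seed = 6)
  qc1 <- qc_pipeline(raw, sc$land, sc$grid)
  log <- qc1$log
  removed <- log$empty_rows + log$duplicates + log$argos_class + log$burn_in +
    log$speed_angle + log$terrestrial + log$segment_trim + log$migration
  expect_equal(log$n_input, log$n_output + removed)
  # recompose output as raw telemetry and re-run with the same release anchor
  back <- do.call(rbind, lapply(qc1$tracks, function(tr) {
    data.frame(animal_id = tr$animal_id, timestamp = tr$timestamp,
               lon = tr$lon, lat = tr$lat, lc = tr$lc, tag_type = tr$tag_type)
  }))
  qc2 <- qc_pipeline(back, sc$land, sc$grid, release = qc1$release)
  expect_equal(length(qc2$tracks), length(qc1$tracks))
  for (k in seq_along(qc1$tracks)) {
    expect_equal(qc2$tracks[[k]]$lon, qc1$tracks[[k]]$lon)
    expect_equal(qc2$tracks[[k]]$timestamp, qc1$tracks[[k]]$timestamp)
  }
})
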