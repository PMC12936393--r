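test_that("movement-model parameters are recovered from simulated tracks", {
  beta <- 0.5; sigma <- 1000  # 1 km h^-3/2
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  est <- t(vapply(1:20, function(s) {
    withr::with_seed(300 + s, {
      times <- cumsum(stats::rexp(500, 1 / 2))  # irregular, mean 2 h
      sx <- sim_iou_axis(beta, sigma, times)
      sy <- sim_iou_axis(beta, sigma, times)
      em <- error_model()
      noise <- em$sigma["G"]
      tr <- data.frame(animal_id = 1,
                       timestamp = t0 + times * 3600,
                       x = sx$p + stats::rnorm(500, 0, noise),
                       y = sy$p + stats::rnorm(500, 0, noise),
                       lc = "G")
      fit <- fit_movement_model(tr, em)
      c(fit$beta, fit$sigma, fit$converged)
    })
  }, numeric(3)))
  conv <- est[, 3] == 1
  expect_gt(mean(conv), 0.8)
  expect_lt(abs(stats::median(est[conv, 1]) - beta) / beta, 0.25)
  expect_lt(abs(stats::median(est[conv, 2]) - sigma) / sigma, 0.25)
})

test_that("identical data give identical fits", {
  withr::with_seed(12, {
    times <- cumsum(stats::rexp(60, 1 / 3))
    sx <- sim_iou_axis(0.4, 800, times)
    tr <- data.frame(animal_id = 1,
                     timestamp = as.POSIXct("2020-01-01", tz = "UTC") + times * 3600,
                     x = sx$p, y = rev(sx$p), lc = "G")
  })
  f1 <- fit_movement_model(tr)
  f2 <- fit_movement_model(tr)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$beta, f2$beta)
})

test_that("sparse tracks are flagged non-converged and excluded", {
  tr <- straight_track(5)
  fit <- fit_movement_model(tr)
  expect_false(fit$converged)
  expect_match(fit$reason, "10 usable")
  expect_error(interpolate(fit, 12), "not converged")
})

test_that("smoother pins noiseless straight-line motion", {
  # constant-velocity path observed with tiny error: smoothed positions at
  # observation times must sit on the line to within a metre
  n <- 30
  times <- seq(0, 58, by = 2)
  fit <- structure(list(
    n = n, times = times, x = 500 * times, y = 200 * times,
    tau2 = rep(1e-6, n), animal_id = 1, segment_id = 1,
    t0 = as.POSIXct("2020-01-01", tz = "UTC"),
    beta = 0.5, sigma = 500, converged = TRUE), class = "ctcrw_fit")
  rt <- interpolate(fit, 12)
  on_obs <- rt$timestamp %in% (fit$t0 + times * 3600)
  want_x <- 500 * as.numeric(difftime(rt$timestamp, fit$t0, units = "hours"))
  expect_lt(max(abs(rt$x[on_obs] - want_x[on_obs])), 1)
})

test_that("smoother equals the dense joint-Gaussian conditional oracle", {
  withr::with_seed(77, {
    times <- c(0, 5, 13, 26, 40)
    sx <- sim_iou_axis(0.3, 700, times)
    obs <- sx$p + stats::rnorm(5, 0, 30)
    fit <- structure(list(
      n = 5, times = times, x = obs, y = obs,
      tau2 = rep(30^2, 5), animal_id = 1, segment_id = 1,
      t0 = as.POSIXct("2020-01-01", tz = "UTC"),
      beta = 0.3, sigma = 700, converged = TRUE), class = "ctcrw_fit")
    rt <- interpolate(fit, 12)
    grid_t <- seq(0, 40, by = 12)
    all_t <- sort(unique(c(times, grid_t)))
    y_all <- rep(NA_real_, length(all_t))
    y_all[match(times, all_t)] <- obs
    tau_all <- rep(1, length(all_t))
    tau_all[match(times, all_t)] <- 30^2
    oracle <- dense_gaussian_smoother(0.3, 700, all_t, y_all, tau_all)
    gi <- match(grid_t, all_t)
    expect_equal(rt$x, oracle$mean[gi], tolerance = 1e-6)
    expect_equal(rt$x_se, oracle$sd[gi], tolerance = 1e-6)
  })
})

test_that("regular grid has floor(span/step)+1 estimates and sane SEs", {
  withr::with_seed(21, {
    times <- sort(c(cumsum(stats::rexp(40, 1 / 2)), 100))
    times <- c(0, times[times < 40], seq(100, 130, by = 2))  # 60-h data gap
    sx <- sim_iou_axis(0.5, 900, times)
    tr <- data.frame(animal_id = 1,
                     timestamp = as.POSIXct("2020-01-01", tz = "UTC") + times * 3600,
                     x = sx$p, y = sim_iou_axis(0.5, 900, times)$p, lc = "G")
    fit <- fit_movement_model(tr)
    expect_true(fit$converged)
    rt <- interpolate(fit, 12)
    span <- max(times) - min(times)
    expect_equal(nrow(rt), floor(span / 12) + 1)
    expect_true(all(diff(as.numeric(rt$timestamp)) == 12 * 3600))
    # SE mid-gap exceeds SE near an observation
    th <- as.numeric(difftime(rt$timestamp, tr$timestamp[1], units = "hours"))
    mid_gap <- which.min(abs(th - 70))
    near_obs <- which.min(abs(th - 12))
    expect_gt(rt$x_se[mid_gap], rt$x_se[near_obs])
  })
})

test_that("interpolation error shrinks as observation noise shrinks", {
  withr::with_seed(99, {
    times <- cumsum(stats::rexp(300, 1 / 2))
    sx <- sim_iou_axis(0.5, 1000, times)
    sy <- sim_iou_axis(0.5, 1000, times)
    rmse <- vapply(c(10, 500, 3000), function(noise) {
      em <- error_model(c(G = max(noise * sqrt(pi / 2), 1), `3` = 250,
                          `2` = 500, `1` = 1500, `0` = 3000, A = 5000,
                          B = 10000))
      tr <- data.frame(animal_id = 1,
                       timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                         times * 3600,
                       x = sx$p + stats::rnorm(300, 0, noise),
                       y = sy$p + stats::rnorm(300, 0, noise), lc = "G")
      fit <- fit_movement_model(tr, em)
      if (!fit$converged) return(NA_real_)
      kf <- habtrack:::.kalman_axis(fit$beta, fit$sigma, times, tr$x,
                                    rep(em$sigma["G"]^2, 300))
      sm <- habtrack:::.smooth_axis(kf)
      sqrt(mean((sm$a[, 1] - sx$p)^2))
    }, numeric(1))
    expect_false(anyNA(rmse))
    expect_true(all(diff(rmse) > 0))
  })
})

test_that("timestep selection prefers dense data and discards hopeless tracks", {
  withr::with_seed(55, {
    times <- cumsum(stats::rexp(200, 1 / 4))  # median interval ~ 2.8 h
    sx <- sim_iou_axis(0.5, 900, times)
    sy <- sim_iou_axis(0.5, 900, times)
    em <- error_model()
    tr <- data.frame(animal_id = 1, segment_id = 1,
                     timestamp = as.POSIXct("2020-01-01", tz = "UTC") + times * 3600,
                     x = sx$p + stats::rnorm(200, 0, em$sigma["G"]),
                     y = sy$p + stats::rnorm(200, 0, em$sigma["G"]), lc = "G")
    res <- select_timestep(tr, em)
    expect_false(is.null(res$rt))
    expect_equal(attr(res$rt, "timestep_hours"), 12)
    # hopeless: too few fixes
    res2 <- select_timestep(tr[1:6, ], em)
    expect_null(res2$rt)
    expect_match(res2$reason, "non-convergence")
    reg <- regularize_tracks(list(tr, tr[1:6, ]), em)
    expect_length(reg$tracks, 1)
    expect_equal(nrow(reg$discarded), 1)
  })
})

test_that("interpolate validates its timestep", {
  fit <- structure(list(converged = TRUE), class = "ctcrw_fit")
  expect_error(interpolate(fit, 6), "12, 24 or 48")
})
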