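fast_cfg <- function(max_trees = 200, tree_complexity = 2, ...) {
  brt_config(learning_rate = 0.1, max_trees = max_trees,
             tree_complexity = tree_complexity, min_obs = 5, ...)
}

test_that("a separable signal is learned and dominates the influence", {
  tab <- separable_table(5000, p_noise = 4, seed = 21)
  tr <- tab[1:4000, ]; te <- tab[4001:5000, ]
  m <- brt_fit(tr, fast_cfg(max_trees = 300))
  ri <- relative_influence(m)
  expect_gt(ri["x1"], 90)
  expect_gt(auc(te$label, predict(m, te)), 0.99)
  expect_equal(sum(ri), 100, tolerance = 1e-6)
})

test_that("fits are bit-identical under the same seed", {
  tab <- logistic_table(1500, p_noise = 2, seed = 22)
  m1 <- brt_fit(tab, fast_cfg(seed = 5))
  m2 <- brt_fit(tab, fast_cfg(seed = 5))
  expect_identical(m1$trees, m2$trees)
  expect_identical(predict(m1, tab), predict(m2, tab))
  m3 <- brt_fit(tab, fast_cfg(seed = 6))
  expect_false(identical(m1$trees, m3$trees))
})

test_that("prediction semantics: intercept-only, batching, link scale", {
  tab <- logistic_table(800, seed = 23)
  m <- brt_fit(tab, fast_cfg(max_trees = 50))
  expect_equal(unique(predict(m, tab, n_trees = 0)), mean(tab$label))
  # single-row vs batched agreement
  p_all <- predict(m, tab)
  p_one <- vapply(1:20, function(i) predict(m, tab[i, , drop = FALSE]),
                  numeric(1))
  expect_equal(p_one, p_all[1:20], tolerance = 1e-12)
  expect_equal(stats::plogis(predict(m, tab, type = "link")), p_all)
  expect_true(all(p_all > 0 & p_all < 1))
})

test_that("training deviance decreases and OOB bookkeeping is sane", {
  tab <- logistic_table(1200, seed = 24)
  m <- brt_fit(tab, fast_cfg(max_trees = 100))
  dd <- diff(m$train_deviance)
  expect_true(all(dd <= 1e-8))
  expect_length(m$oob_improve, 100)
})

test_that("monotone constraints hold everywhere on the PD grid", {
  withr::with_seed(25, {
    n <- 3000
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    pr <- stats::plogis(1.5 * x1 + 0.8 * sin(3 * x2))
    tab <- data.frame(label = stats::rbinom(n, 1, pr), x1 = x1, x2 = x2)
  })
  m <- brt_fit(tab, fast_cfg(monotone = c(x1 = 1)))
  grid <- seq(min(tab$x1), max(tab$x1), length.out = 100)
  pd <- partial_dependence(m, "x1", grid = grid)
  expect_true(all(diff(pd$yhat) >= -1e-12))
  m2 <- brt_fit(tab, fast_cfg(monotone = c(x1 = -1)))
  pd2 <- partial_dependence(m2, "x1", grid = grid)
  expect_true(all(diff(pd2$yhat) <= 1e-12))
})

test_that("partial dependence equals the brute-force override", {
  tab <- logistic_table(50, seed = 26)
  m <- brt_fit(tab, brt_config(learning_rate = 0.1, max_trees = 20,
                               tree_complexity = 3, min_obs = 2))
  grid <- stats::quantile(tab$x1, seq(0.1, 0.9, 0.1), names = FALSE)
  fast <- partial_dependence(m, "x1", grid = grid)
  brute <- vapply(grid, function(v) {
    d <- tab
    d$x1 <- v
    mean(predict(m, d, type = "link"))
  }, numeric(1))
  expect_equal(fast$yhat, brute, tolerance = 1e-9)
})

test_that("PD of an unused predictor is constant; single split is a step", {
  withr::with_seed(27, {
    tab <- data.frame(label = rep(0:1, each = 300),
                      x1 = c(stats::rnorm(300, -2), stats::rnorm(300, 2)),
                      dead = stats::rnorm(600))
  })
  m <- brt_fit(tab, brt_config(learning_rate = 0.5, max_trees = 1,
                               tree_complexity = 1, min_obs = 10,
                               bag_fraction = 1))
  pd_dead <- partial_dependence(m, "dead",
                                grid = seq(-2, 2, length.out = 20))
  expect_equal(stats::sd(pd_dead$yhat), 0)
  pd1 <- partial_dependence(m, "x1", grid = seq(-3, 3, length.out = 200))
  expect_equal(length(unique(round(pd1$yhat, 12))), 2)  # a single step
})

test_that("influence under pure noise stays diffuse", {
  maxes <- vapply(1:10, function(s) {
    withr::with_seed(400 + s, {
      tab <- data.frame(label = stats::rbinom(2000, 1, 0.5),
                        matrix(stats::rnorm(2000 * 5), 2000,
                               dimnames = list(NULL, paste0("p", 1:5))))
    })
    m <- brt_fit(tab, fast_cfg(max_trees = 100, seed = s))
    max(relative_influence(m))
  }, numeric(1))
  expect_lt(max(maxes), 40)
})

test_that("influential-predictor flag uses the 100/p threshold", {
  tab <- separable_table(2000, p_noise = 4, seed = 28)
  m <- brt_fit(tab, fast_cfg())
  fl <- influential_predictors(m)
  expect_true(fl["x1"])
  expect_equal(sum(fl), 1L)
})

test_that("interaction scores separate additive from XOR structure", {
  adds <- vapply(1:10, function(s) {
    withr::with_seed(600 + s, {
      n <- 4000
      x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
      pr <- stats::plogis(x1 + x2)
      tab <- data.frame(label = stats::rbinom(n, 1, pr), x1 = x1, x2 = x2)
    })
    m <- brt_fit(tab, fast_cfg(seed = s))
    interaction_strength(m, c("x1", "x2"))
  }, numeric(1))
  expect_lt(stats::median(adds), 0.05)
  # XOR: the constructed pair ranks first among all pairs
  withr::with_seed(29, {
    n <- 4000
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rnorm(n)
    tab <- data.frame(label = as.integer(xor(x1 > 0, x2 > 0)),
                      x1 = x1, x2 = x2, x3 = x3)
  })
  m <- brt_fit(tab, fast_cfg(tree_complexity = 3))
  rk <- rank_interactions(m, top = 3)
  expect_setequal(unlist(rk[1, c("var1", "var2")]), c("x1", "x2"))
  expect_equal(interaction_strength(m, c("x1", "x2")),
               interaction_strength(m, c("x2", "x1")))
})

test_that("cross-validation partitions evenly and recovers separable truth", {
  tab <- separable_table(1000, p_noise = 2, seed = 30)
  cv <- cross_validate(tab, fast_cfg())
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_true(all(abs(table(cv$fold) - 200) <= 1))
  expect_equal(unname(cv$means["auc"]), mean(cv$metrics$auc))
  expect_gt(cv$means["auc"], 0.95)
})

test_that("pruning requires unimportance in every fold", {
  fake_cv <- structure(list(influence = rbind(
    c(a = 40, b = 30, c = 25, d = 5, e = 0),
    c(a = 35, b = 35, c = 20, d = 10, e = 0),
    c(a = 45, b = 25, c = 20, d = 0, e = 10),
    c(a = 30, b = 40, c = 25, d = 5, e = 0),
    c(a = 50, b = 20, c = 25, d = 5, e = 0))), class = "brt_cv")
  colnames(fake_cv$influence) <- c("a", "b", "c", "d", "e")
  sv <- prune_predictors(fake_cv)
  # e is lowest-10% in 4 of 5 folds only -> retained; d dips but not always
  expect_true(all(c("a", "b", "c") %in% sv))
  drop <- attr(sv, "dropped")
  # a predictor at or below the fold cutoff in ALL folds is dropped
  low_all <- apply(fake_cv$influence, 2, function(col) {
    all(col <= apply(fake_cv$influence, 1, stats::quantile, probs = 0.1))
  })
  expect_setequal(drop, names(low_all)[low_all])
})

test_that("noise predictors are pruned while informative ones survive", {
  hits <- vapply(1:10, function(s) {
    tab <- logistic_table(2500, b1 = 1.5, b2 = -1.2, p_noise = 6,
                          seed = 700 + s)
    cv <- cross_validate(tab, fast_cfg(max_trees = 120, seed = s))
    sv <- prune_predictors(cv)
    keep_truth <- all(c("x1", "x2") %in% sv)
    noise_removed <- sum(grepl("^noise", attr(sv, "dropped")))
    c(keep_truth, noise_removed)
  }, numeric(2))
  expect_gte(sum(hits[1, ]), 9)
})

test_that("OOB tree selection encompasses every fold's best iteration", {
  mk <- function(imp) list(oob_improve = imp, config = list(oob_window = 5))
  # strictly positive improvements: use every tree
  ms <- list(mk(rep(0.5, 100)), mk(rep(0.2, 100)))
  expect_equal(as.integer(select_n_trees_oob(ms)), 100L)
  # improvements negative after iteration k in all folds -> about k
  drop_after <- function(k) c(rep(1, k), rep(-0.5, 100 - k))
  ms2 <- list(mk(drop_after(40)), mk(drop_after(60)))
  got <- select_n_trees_oob(ms2)
  expect_lt(abs(got - 60), 6)  # within the smoothing window
  expect_true(all(got >= attr(got, "per_fold")))
})

test_that("categorical predictors split by level subsets and route unseen codes", {
  withr::with_seed(31, {
    n <- 2000
    g <- sample(0:3, n, replace = TRUE)
    pr <- c(0.1, 0.8, 0.15, 0.9)[g + 1]
    tab <- data.frame(label = stats::rbinom(n, 1, pr), geo = g,
                      x = stats::rnorm(n))
  })
  attr(tab, "schema") <- data.frame(column = c("geo", "x"),
                                    type = c("categorical", "continuous"),
                                    source = "static")
  m <- brt_fit(tab, fast_cfg(max_trees = 60))
  p_lvl <- vapply(0:3, function(lv) {
    predict(m, data.frame(geo = lv, x = 0))
  }, numeric(1))
  expect_gt(min(p_lvl[c(2, 4)]), max(p_lvl[c(1, 3)]))
  expect_warning(predict(m, data.frame(geo = 7, x = 0)), "unseen")
})

test_that("degenerate inputs are rejected", {
  tab <- data.frame(label = rep(1L, 50), x1 = stats::rnorm(50))
  expect_error(brt_fit(tab, fast_cfg()), "both classes")
  tab2 <- data.frame(label = c(0, 1, 2), x1 = 1:3)
  expect_error(brt_fit(tab2, fast_cfg()), "0/1")
})

test_that("held-out ranking agrees with an independent boosting library", {
  skip_if_not_installed("xgboost")
  tab <- logistic_table(4000, p_noise = 2, seed = 33)
  tr <- tab[1:3000, ]; te <- tab[3001:4000, ]
  m <- brt_fit(tr, fast_cfg(max_trees = 600, tree_complexity = 3))
  a_own <- auc(te$label, predict(m, te))
  dtr <- xgboost::xgb.DMatrix(as.matrix(tr[, -1]), label = tr$label)
  xg <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = 3, eta = 0.1,
                                         subsample = 0.75),
                           data = dtr, nrounds = 300)
  a_ref <- auc(te$label,
               predict(xg, xgboost::xgb.DMatrix(as.matrix(te[, -1]))))
  expect_lt(abs(a_own - a_ref), 0.05)
})
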