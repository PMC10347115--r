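# Feature sets, the split plan, model training with Bayesian HPO, metrics.

scene_features <- function(fs = "FS1", seed = 11) {
  s <- small_scene(n_plots = 8, snx = 4, sny = 3, px = 16, seed = seed,
                   plots_per_row = 4)
  m <- gfkuts_segment(s$raster, gfkuts_params(), grid = s$grid, seed = 2)
  rec <- s$truth_records
  rec$height_cm <- rec$cover * 100
  list(scene = s, mask = m,
       fm = build_features(s$raster, m, s$grid, rec, fs))
}

test_that("feature sets carry exactly the specified columns", {
  sf <- scene_features("FS1")
  expect_equal(attr(sf$fm, "feature_cols"),
               c(paste0("vi_", vi_names()), "genotype"))
  rec <- sf$scene$truth_records
  rec$height_cm <- rec$cover * 100
  fs2 <- build_features(sf$scene$raster, sf$mask, sf$scene$grid, rec, "FS2")
  expect_equal(attr(fs2, "feature_cols"),
               c(paste0("ch_", sf$scene$raster$bands), "seg_mean", "genotype"))
  fs3 <- build_features(sf$scene$raster, sf$mask, sf$scene$grid, rec, "FS3")
  expect_equal(length(attr(fs3, "feature_cols")), 16)  # 10 VIs + 5 channels + height
  fs4 <- build_features(sf$scene$raster, sf$mask, sf$scene$grid, rec, "FS4")
  expect_equal(attr(fs4, "feature_cols"), c("seg_mean", "height"))
  expect_false(anyNA(fs4[, attr(fs4, "label_cols")]))
  # one-hot genotype option widens FS1
  fs1h <- build_features(sf$scene$raster, sf$mask, sf$scene$grid, rec, "FS1",
                         genotype_encoding = "onehot")
  expect_equal(length(attr(fs1h, "feature_cols")), 10 + nrow(rec))
})

test_that("channel-mean features of a constant tile equal the constant", {
  arr <- array(0, dim = c(16, 16, 5))
  for (b in 1:5) arr[, , b] <- b / 10
  r <- multiband_raster(arr, c("BLUE", "GREEN", "RED", "REG", "NIR"))
  grid <- data.frame(plot_id = 1, subplot_id = 1, x0 = 0, y0 = 0, x1 = 16,
                     y1 = 16)
  rec <- data.frame(plot_id = 1, genotype_id = "G01", height_cm = 100,
                    wet_g = 900, dry_g = 300, spad = 38)
  mask <- canopy_mask(matrix(1, 16, 16), binary = TRUE)
  fm <- build_features(r, mask, grid, rec, "FS2")
  expect_equal(unname(unlist(fm[1, paste0("ch_", r$bands)])),
               (1:5) / 10, tolerance = 1e-12)
  expect_equal(fm$seg_mean, 1)
  # tiles without a record are refused by name
  grid2 <- rbind(grid, data.frame(plot_id = 2, subplot_id = 1, x0 = 0,
                                  y0 = 0, x1 = 16, y1 = 16))
  expect_error(build_features(r, mask, grid2, rec, "FS2"), "plot 2")
})

test_that("the split plan reserves the right counts and is seed-deterministic", {
  fm <- data.frame(plot_id = rep(1:6, each = 12), subplot_id = rep(1:12, 6))
  attr(fm, "label_cols") <- character(0)
  p1 <- make_split(fm, seed = 4, n_test_per_plot = 8)
  expect_equal(length(p1$test_rows), 48)
  expect_equal(length(p1$cv_rows), 24)
  expect_equal(length(intersect(p1$test_rows, p1$cv_rows)), 0)
  # 8 test rows from every plot
  expect_true(all(table(fm$plot_id[p1$test_rows]) == 8))
  # folds are 70/30 partitions of the cv pool only
  for (f in p1$folds) {
    expect_equal(sort(c(f$train, f$val)), p1$cv_rows)
    expect_equal(length(f$train), round(0.7 * 24))
  }
  p2 <- make_split(fm, seed = 4, n_test_per_plot = 8)
  expect_identical(p1, p2)
  p3 <- make_split(fm, seed = 5, n_test_per_plot = 8)
  expect_false(identical(p1$test_rows, p3$test_rows))
  small <- data.frame(plot_id = rep(1, 5), subplot_id = 1:5)
  expect_error(make_split(small, n_test_per_plot = 8), "fewer than")
})

test_that("a noiseless linear target is recovered almost exactly by TR/ER/GPR", {
  set.seed(20)
  n <- 120
  fm <- data.frame(plot_id = rep(1:6, each = 20), subplot_id = rep(1:20, 6),
                   f1 = runif(n), f2 = runif(n))
  fm$y <- 2 * fm$f1 - 3 * fm$f2 + 1
  attr(fm, "feature_cols") <- c("f1", "f2")
  attr(fm, "label_cols") <- "y"
  attr(fm, "fs_id") <- "FS1"
  class(fm) <- c("feature_matrix", "data.frame")
  plan <- make_split(fm, seed = 2, n_test_per_plot = 4)
  for (kind in c("GPR", "ER")) {
    fit <- train_model(model_spec(kind, hpo_iterations = 5, seed = 1), fm,
                       plan, "y")
    rep <- evaluate_model(fit, fm, plan$test_rows)
    expect_gte(rep$R2, 0.95)
  }
  fit_tr <- train_model(model_spec("TR", hpo_iterations = 8, seed = 1), fm,
                        plan, "y")
  expect_gte(evaluate_model(fit_tr, fm, plan$test_rows)$R2, 0.8)
})

test_that("a pure-noise target yields no spurious skill", {
  set.seed(21)
  n <- 120
  fm <- data.frame(plot_id = rep(1:6, each = 20), subplot_id = rep(1:20, 6),
                   f1 = runif(n), f2 = runif(n), y = rnorm(n))
  attr(fm, "feature_cols") <- c("f1", "f2")
  attr(fm, "label_cols") <- "y"
  attr(fm, "fs_id") <- "FS1"
  class(fm) <- c("feature_matrix", "data.frame")
  plan <- make_split(fm, seed = 3, n_test_per_plot = 4)
  for (kind in c("GPR", "TR", "SVMR")) {
    fit <- train_model(model_spec(kind, hpo_iterations = 4, seed = 2), fm,
                       plan, "y")
    rep <- evaluate_model(fit, fm, plan$test_rows)
    expect_lte(rep$R2, 0.1)
  }
})

test_that("GPR on FS1 recovers the latent SPAD on a small synthetic scene", {
  sf <- scene_features("FS1", seed = 11)
  plan <- make_split(sf$fm, seed = 5, n_test_per_plot = 3)
  fit <- train_model(model_spec("GPR", seed = 3), sf$fm, plan, "spad")
  rep <- evaluate_model(fit, sf$fm, plan$test_rows)
  expect_gte(rep$R2, 0.9)
  expect_gte(rep$RMSE, rep$MAE)
})

test_that("training is deterministic for fixed seeds and rejects degenerate labels", {
  set.seed(22)
  fm <- data.frame(plot_id = rep(1:4, each = 10), subplot_id = rep(1:10, 4),
                   f1 = runif(40))
  fm$y <- fm$f1 + rnorm(40, 0, 0.05)
  attr(fm, "feature_cols") <- "f1"
  attr(fm, "label_cols") <- "y"
  attr(fm, "fs_id") <- "FS1"
  class(fm) <- c("feature_matrix", "data.frame")
  plan <- make_split(fm, seed = 1, n_test_per_plot = 3)
  f1 <- train_model(model_spec("TR", hpo_iterations = 6, seed = 9), fm, plan, "y")
  f2 <- train_model(model_spec("TR", hpo_iterations = 6, seed = 9), fm, plan, "y")
  expect_identical(f1$best_hyper, f2$best_hyper)
  expect_identical(f1$history$objective, f2$history$objective)
  expect_identical(predict(f1, fm), predict(f2, fm))
  fm$y <- 1
  expect_error(train_model(model_spec("TR", hpo_iterations = 2), fm, plan, "y"),
               "degenerate")
})

test_that("GPR with (near) zero noise interpolates its training points", {
  set.seed(23)
  X <- matrix(runif(30), 15, 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  fit <- ricecanopy:::gp_fit(X, y, kernel = "rbf", lengthscale = 1,
                             noise = 0, jitter = 1e-12)
  expect_lt(max(abs(ricecanopy:::gp_predict(fit, X) - y)), 1e-6)
  # independent reference on the same kernel family
  skip_if_not_installed("kernlab")
  gp_ref <- kernlab::gausspr(X, y, kernel = "rbfdot",
                             kpar = list(sigma = 1 / 2), var = 1e-3,
                             scaled = FALSE, variance.model = FALSE)
  ours <- ricecanopy:::gp_fit(X, y, "rbf", lengthscale = 1, noise = 1e-3)
  Xq <- matrix(runif(10), 5, 2)
  expect_equal(ricecanopy:::gp_predict(ours, Xq),
               as.numeric(kernlab::predict(gp_ref, Xq)), tolerance = 0.05)
})

test_that("ensemble predictions are the average of the base trees", {
  set.seed(24)
  X <- matrix(runif(200), 100, 2)
  colnames(X) <- c("f1", "f2")
  y <- X[, 1] + rnorm(100, 0, 0.1)
  m <- ricecanopy:::fit_one_model("ER",
                                  list(num_trees = 25, max_depth = 6,
                                       mtry_frac = 1), X, y, seed = 2)
  agg <- ricecanopy:::predict_one_model(m, X)
  per_tree <- predict(m$fit,
                      data = ricecanopy:::standardize_apply(X, m$st),
                      predict.all = TRUE)$predictions
  expect_equal(agg, rowMeans(per_tree), tolerance = 1e-10)
})

test_that("a single tree split reduces the node MSE on a two-cluster target", {
  X <- matrix(c(rep(0, 30), rep(1, 30)), ncol = 1)
  colnames(X) <- "f1"
  set.seed(25)
  y <- c(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1))
  m <- ricecanopy:::fit_one_model("TR",
                                  list(maxdepth = 1, minbucket = 5, cp = 1e-6),
                                  X, y, seed = 1)
  pred <- ricecanopy:::predict_one_model(m, X)
  mse_split <- mean((pred - y)^2)
  mse_root <- mean((mean(y) - y)^2)
  expect_lt(mse_split, mse_root)
})

test_that("metric identities hold: perfect, mean-constant and hand-set errors", {
  truth <- c(3, 1, 4, 1, 5, 9)
  perfect <- regression_metrics(truth, truth)
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$MAE, 0)
  expect_equal(perfect$RMSE, 0)
  mean_pred <- regression_metrics(truth, rep(mean(truth), 6))
  expect_equal(mean_pred$R2, 0)
  hand <- regression_metrics(c(0, 0, 0, 0), c(1, -1, 2, -2))
  expect_equal(hand$MAE, 1.5)
  expect_equal(hand$RMSE, sqrt(2.5))
  # RMSE >= MAE over random error vectors (Jensen)
  set.seed(26)
  for (rep in 1:10) {
    e <- rnorm(20)
    mt <- regression_metrics(rnorm(20), rnorm(20) + e)
    expect_gte(mt$RMSE, mt$MAE)
  }
})
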