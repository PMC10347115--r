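# Feature matrices FS1-FS4, the split/cross-validation scheme, the five
# regression model families with Bayesian hyperparameter optimization, and
# R2/MAE/RMSE evaluation.

#' Build a feature matrix for one feature set
#'
#' Per-subplot rows with the configured feature columns and the three trait
#' labels replicated from each tile's plot record:
#' \itemize{
#' \item FS1: ten mask-weighted vegetation-index means + genotype ID
#' \item FS2: five channel means + mean segmentation value + genotype ID
#' \item FS3: ten VI means + five channel means + plant height
#' \item FS4: mean segmentation value + plant height
#' }
#' VI means are weighted by the canopy mask; channel and segmentation means
#' are whole-tile. A tile with zero canopy coverage falls back to the
#' unmasked VI mean.
#'
#' @param scene a \code{multiband_raster} of the field.
#' @param mask \code{canopy_mask} aligned with the scene.
#' @param grid plot grid from [make_plot_grid()].
#' @param records per-plot data.frame with \code{plot_id},
#'   \code{genotype_id}, \code{height_cm} (or \code{cover} for synthetic
#'   truth), and labels \code{wet_g}, \code{dry_g}, \code{spad}.
#' @param fs_id one of \code{"FS1" .. "FS4"}.
#' @param params a [vi_params()].
#' @param genotype_encoding \code{"integer"} (ordinal codes) or
#'   \code{"onehot"}.
#' @param height_col column of \code{records} holding plant height.
#' @return data.frame of class \code{feature_matrix}: metadata columns
#'   \code{plot_id}, \code{subplot_id}; feature columns (attribute
#'   \code{feature_cols}); label columns \code{wet_g}, \code{dry_g},
#'   \code{spad} (attribute \code{label_cols}).
#' @export
build_features <- function(scene, mask, grid, records, fs_id = "FS1",
                           params = vi_params(),
                           genotype_encoding = c("integer", "onehot"),
                           height_col = "height_cm") {
  stopifnot(inherits(scene, "multiband_raster"), fs_id %in% paste0("FS", 1:4))
  genotype_encoding <- match.arg(genotype_encoding)
  missing_plots <- setdiff(grid$plot_id, records$plot_id)
  if (length(missing_plots))
    stop("tiles without a matching plot record: plot ",
         paste(missing_plots, collapse = ", "))
  m <- mask_matrix(mask)
  need_vi <- fs_id %in% c("FS1", "FS3")
  idx <- if (need_vi) compute_all_indices(scene, params) else NULL

  n <- nrow(grid)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- grid[i, ]
    mm <- crop_rect(m, g)
    row <- list(plot_id = g$plot_id, subplot_id = g$subplot_id,
                seg_mean = mean(mm))
    if (need_vi) {
      for (nm in vi_names()) {
        tile <- crop_rect(idx[[nm]], g)
        w <- mm > 0 & !is.na(tile)
        row[[paste0("vi_", nm)]] <- if (any(w)) mean(tile[w])
                                    else mean(tile, na.rm = TRUE)
      }
    }
    if (fs_id %in% c("FS2", "FS3")) {
      for (b in scene$bands)
        row[[paste0("ch_", b)]] <- mean(crop_rect(get_band(scene, b), g))
    }
    rows[[i]] <- as.data.frame(row)
  }
  fm <- do.call(rbind, rows)
  ri <- match(fm$plot_id, records$plot_id)
  fm$genotype_id <- records$genotype_id[ri]
  fm$height <- if (height_col %in% names(records)) records[[height_col]][ri] else NA
  fm$wet_g <- records$wet_g[ri]
  fm$dry_g <- records$dry_g[ri]
  fm$spad <- records$spad[ri]
  if (anyNA(fm[c("wet_g", "dry_g", "spad")])) stop("missing trait labels")

  geno_cols <- "genotype"
  if (genotype_encoding == "integer") {
    fm$genotype <- as.integer(factor(fm$genotype_id,
                                     levels = sort(unique(records$genotype_id))))
  } else {
    lv <- sort(unique(records$genotype_id))
    oh <- outer(fm$genotype_id, lv, "==") + 0
    colnames(oh) <- paste0("geno_", seq_along(lv))
    fm <- cbind(fm, oh)
    geno_cols <- colnames(oh)
  }
  feature_cols <- switch(fs_id,
    FS1 = c(paste0("vi_", vi_names()), geno_cols),
    FS2 = c(paste0("ch_", scene$bands), "seg_mean", geno_cols),
    FS3 = c(paste0("vi_", vi_names()), paste0("ch_", scene$bands), "height"),
    FS4 = c("seg_mean", "height"))
  structure(fm, feature_cols = feature_cols,
            label_cols = c("wet_g", "dry_g", "spad"), fs_id = fs_id,
            class = c("feature_matrix", "data.frame"))
}

#' Test / cross-validation split plan
#'
#' Randomly sets aside a fixed number of subplots per plot as the held-out
#' test set; the remainder forms the cross-validation pool, from which
#' \code{n_folds} independent random train/validation partitions are drawn.
#'
#' @param matrix a \code{feature_matrix} (needs \code{plot_id} per row).
#' @param seed integer seed.
#' @param n_test_per_plot subplots per plot held out for testing (default 8).
#' @param n_folds number of folds (default 5).
#' @param train_frac training fraction within each fold (default 0.7).
#' @return list of class \code{split_plan}: \code{test_rows},
#'   \code{cv_rows}, \code{folds} (each a list with \code{train},
#'   \code{val}), \code{seed}.
#' @export
make_split <- function(matrix, seed = 1, n_test_per_plot = 8, n_folds = 5,
                       train_frac = 0.7) {
  set.seed(seed)
  by_plot <- split(seq_len(nrow(matrix)), matrix$plot_id)
  short <- names(by_plot)[vapply(by_plot, length, 1L) < n_test_per_plot + 1]
  if (length(short))
    stop("plots with fewer than ", n_test_per_plot + 1, " subplots: ",
         paste(short, collapse = ", "))
  test_rows <- sort(unlist(lapply(by_plot, function(rr)
    sample(rr, n_test_per_plot)), use.names = FALSE))
  cv_rows <- setdiff(seq_len(nrow(matrix)), test_rows)
  folds <- lapply(seq_len(n_folds), function(k) {
    tr <- sample(cv_rows, round(train_frac * length(cv_rows)))
    list(train = sort(tr), val = sort(setdiff(cv_rows, tr)))
  })
  structure(list(test_rows = test_rows, cv_rows = cv_rows, folds = folds,
                 seed = seed), class = "split_plan")
}

# ---- Gaussian process regression (RBF / Matern-5/2, Cholesky solve) ---------

gp_kernel <- function(D, kernel, lengthscale) {
  if (kernel == "rbf") return(exp(-D^2 / (2 * lengthscale^2)))
  s <- sqrt(5) * D / lengthscale
  (1 + s + s^2 / 3) * exp(-s)
}

cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

gp_fit <- function(X, y, kernel = "rbf", lengthscale = 1, noise = 1e-3,
                   jitter = 1e-10) {
  ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yc <- (y - ym) / ys
  K <- gp_kernel(cross_dist(X, X), kernel, lengthscale)
  L <- NULL
  for (j in jitter * 10^(0:8)) {  # grow the jitter until K is factorizable
    L <- tryCatch(chol(K + diag(noise + j, nrow(X))), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) stop("GP covariance is not positive definite")
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  list(X = X, alpha = alpha, kernel = kernel, lengthscale = lengthscale,
       noise = noise, ym = ym, ys = ys, L = L)
}

gp_predict <- function(fit, Xnew, se = FALSE) {
  Ks <- gp_kernel(cross_dist(Xnew, fit$X), fit$kernel, fit$lengthscale)
  mu <- fit$ym + fit$ys * as.numeric(Ks %*% fit$alpha)
  if (!se) return(mu)
  v <- forwardsolve(t(fit$L), t(Ks))
  var_c <- pmax(1 - colSums(v^2), 0)
  list(mean = mu, sd = fit$ys * sqrt(var_c))
}

# ---- model family wrappers (standardize features inside) --------------------

standardize_fit <- function(X) {
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(ctr = ctr, scl = scl)
}
standardize_apply <- function(X, st) sweep(sweep(X, 2, st$ctr), 2, st$scl, "/")

fit_one_model <- function(kind, hyper, X, y, seed = 1) {
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  set.seed(seed)
  fit <- switch(kind,
    TR = {
      df <- data.frame(y = y, Xs)
      rpart::rpart(y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = hyper$maxdepth, minbucket = hyper$minbucket,
                     cp = hyper$cp, minsplit = max(2 * hyper$minbucket, 2),
                     xval = 0))
    },
    ER = ranger::ranger(x = Xs, y = y, num.trees = hyper$num_trees,
                        max.depth = hyper$max_depth,
                        mtry = max(1, round(hyper$mtry_frac * ncol(Xs))),
                        seed = seed, num.threads = 1),
    GPR = gp_fit(as.matrix(Xs), y, kernel = hyper$kernel,
                 lengthscale = hyper$lengthscale, noise = hyper$noise),
    SVMR = e1071::svm(x = as.matrix(Xs), y = y, type = "eps-regression",
                      kernel = "radial", cost = hyper$cost,
                      gamma = hyper$gamma, epsilon = hyper$epsilon),
    NNR = {
      ysc <- list(m = mean(y), s = max(stats::sd(y), 1e-12))
      nn <- nnet::nnet(x = as.matrix(Xs), y = (y - ysc$m) / ysc$s,
                       size = hyper$size, decay = hyper$decay, linout = TRUE,
                       maxit = 300, trace = FALSE, MaxNWts = 50000)
      list(nn = nn, ysc = ysc)
    },
    stop("unknown model kind: ", kind))
  list(kind = kind, fit = fit, st = st, hyper = hyper,
       feature_names = colnames(X))
}

predict_one_model <- function(model, X) {
  Xs <- standardize_apply(X, model$st)
  switch(model$kind,
    TR = as.numeric(stats::predict(model$fit, newdata = data.frame(Xs))),
    ER = as.numeric(stats::predict(model$fit, data = Xs)$predictions),
    GPR = gp_predict(model$fit, as.matrix(Xs)),
    SVMR = as.numeric(stats::predict(model$fit, as.matrix(Xs))),
    NNR = as.numeric(stats::predict(model$fit$nn, as.matrix(Xs))) *
      model$fit$ysc$s + model$fit$ysc$m)
}

# ---- hyperparameter search spaces -------------------------------------------

search_space <- function(kind) {
  switch(kind,
    TR = list(
      maxdepth = list(type = "int", lo = 1, hi = 30),
      minbucket = list(type = "int", lo = 1, hi = 50, log = TRUE),
      cp = list(type = "num", lo = 1e-6, hi = 0.1, log = TRUE)),
    ER = list(
      num_trees = list(type = "int", lo = 50, hi = 500),
      max_depth = list(type = "int", lo = 2, hi = 30),
      mtry_frac = list(type = "num", lo = 0.3, hi = 1)),
    GPR = list(
      kernel = list(type = "cat", values = c("rbf", "matern52")),
      lengthscale = list(type = "num", lo = 0.1, hi = 30, log = TRUE),
      noise = list(type = "num", lo = 1e-6, hi = 1, log = TRUE)),
    SVMR = list(
      cost = list(type = "num", lo = 1e-2, hi = 1e3, log = TRUE),
      gamma = list(type = "num", lo = 1e-4, hi = 10, log = TRUE),
      epsilon = list(type = "num", lo = 1e-3, hi = 1, log = TRUE)),
    NNR = list(
      size = list(type = "int", lo = 4, hi = 128, log = TRUE),
      decay = list(type = "num", lo = 1e-5, hi = 1, log = TRUE)),
    stop("unknown model kind: ", kind))
}

decode_unit <- function(u, space) {
  hyper <- list()
  for (i in seq_along(space)) {
    sp <- space[[i]]; ui <- u[i]
    hyper[[names(space)[i]]] <- switch(sp$type,
      num = if (isTRUE(sp$log)) exp(log(sp$lo) + ui * (log(sp$hi) - log(sp$lo)))
            else sp$lo + ui * (sp$hi - sp$lo),
      int = {
        v <- if (isTRUE(sp$log)) exp(log(sp$lo) + ui * (log(sp$hi) - log(sp$lo)))
             else sp$lo + ui * (sp$hi - sp$lo)
        as.integer(max(sp$lo, min(sp$hi, round(v))))
      },
      cat = sp$values[1 + pmin(floor(ui * length(sp$values)),
                               length(sp$values) - 1)])
  }
  hyper
}

#' Model specification
#'
#' One of the five model families with its Bayesian-optimization budget.
#' Default budgets per family: GPR 5, NNR 300, SVMR 600, ER 800, TR 900
#' hyperparameter evaluations.
#'
#' @param kind one of \code{"GPR"}, \code{"TR"}, \code{"ER"}, \code{"SVMR"},
#'   \code{"NNR"}.
#' @param hpo_iterations optimization budget (>= 1); \code{NULL} uses the
#'   family default.
#' @param seed integer seed.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(kind = c("GPR", "TR", "ER", "SVMR", "NNR"),
                       hpo_iterations = NULL, seed = 1) {
  kind <- match.arg(kind)
  defaults <- c(GPR = 5, NNR = 300, SVMR = 600, ER = 800, TR = 900)
  if (is.null(hpo_iterations)) hpo_iterations <- defaults[[kind]]
  stopifnot(hpo_iterations >= 1)
  structure(list(kind = kind, hpo_iterations = as.integer(hpo_iterations),
                 search_space = search_space(kind), seed = seed),
            class = "model_spec")
}

# mean validation MSE over the plan's folds for one hyperparameter setting
cv_objective <- function(kind, hyper, X, y, plan, seed) {
  mse <- vapply(plan$folds, function(f) {
    m <- fit_one_model(kind, hyper, X[f$train, , drop = FALSE], y[f$train],
                       seed = seed)
    pred <- predict_one_model(m, X[f$val, , drop = FALSE])
    mean((pred - y[f$val])^2)
  }, numeric(1))
  mean(mse)
}

# Expected improvement of candidate points under a GP surrogate
expected_improvement <- function(surrogate, U, best) {
  pr <- gp_predict(surrogate, U, se = TRUE)
  s <- pmax(pr$sd, 1e-12)
  z <- (best - pr$mean) / s
  (best - pr$mean) * stats::pnorm(z) + s * stats::dnorm(z)
}

#' Train one model with Bayesian hyperparameter optimization
#'
#' Minimizes the mean validation MSE across the plan's folds over the
#' family's search space: a Latin-hypercube initial design followed by
#' expected-improvement proposals from a Gaussian-process surrogate on the
#' unit cube (log objective). The best hyperparameters are refit on the full
#' cross-validation pool. Fully seeded.
#'
#' @param spec a [model_spec()].
#' @param matrix a \code{feature_matrix}.
#' @param plan a [make_split()] plan.
#' @param trait label column: \code{"wet_g"}, \code{"dry_g"} or \code{"spad"}.
#' @return object of class \code{canopy_model}: the refit model plus
#'   \code{best_hyper}, \code{history} (evaluated settings and objectives),
#'   \code{spec}, \code{trait}.
#' @export
train_model <- function(spec, matrix, plan, trait = "dry_g") {
  stopifnot(inherits(spec, "model_spec"), inherits(plan, "split_plan"),
            trait %in% attr(matrix, "label_cols"))
  fcols <- attr(matrix, "feature_cols")
  X <- as.matrix(matrix[, fcols, drop = FALSE])
  y <- matrix[[trait]]
  if (stats::sd(y[plan$cv_rows]) == 0)
    stop("degenerate labels: zero variance in the CV pool")
  d <- length(spec$search_space)
  budget <- spec$hpo_iterations
  set.seed(spec$seed)
  n_init <- min(budget, max(4, d + 1))
  U <- lhs::randomLHS(n_init, d)
  obj <- numeric(0)
  hist_hyper <- list()
  for (i in seq_len(n_init)) {
    h <- decode_unit(U[i, ], spec$search_space)
    hist_hyper[[i]] <- h
    obj[i] <- cv_objective(spec$kind, h, X, y, plan, seed = spec$seed + i)
  }
  while (length(obj) < budget) {
    surrogate <- tryCatch(
      gp_fit(U, log(pmax(obj, 1e-300)), kernel = "matern52",
             lengthscale = 0.5, noise = 1e-4),
      error = function(e) NULL)
    cand <- stats::runif(256 * d)
    dim(cand) <- c(256, d)
    u_next <- if (is.null(surrogate)) cand[1, , drop = FALSE] else {
      ei <- expected_improvement(surrogate, cand, min(log(pmax(obj, 1e-300))))
      cand[which.max(ei), , drop = FALSE]
    }
    h <- decode_unit(u_next[1, ], spec$search_space)
    U <- rbind(U, u_next)
    hist_hyper[[length(obj) + 1]] <- h
    obj[length(obj) + 1] <- cv_objective(spec$kind, h, X, y, plan,
                                         seed = spec$seed + length(obj) + 1)
  }
  best_i <- which.min(obj)
  best_hyper <- hist_hyper[[best_i]]
  final <- fit_one_model(spec$kind, best_hyper,
                         X[plan$cv_rows, , drop = FALSE], y[plan$cv_rows],
                         seed = spec$seed)
  structure(list(model = final, best_hyper = best_hyper,
                 history = list(hyper = hist_hyper, objective = obj),
                 spec = spec, trait = trait, feature_cols = fcols),
            class = "canopy_model")
}

#' @export
predict.canopy_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  predict_one_model(object$model, X)
}

#' @export
print.canopy_model <- function(x, ...) {
  cat("<canopy_model> ", x$spec$kind, " for ", x$trait, "; ",
      length(x$history$objective), " HPO evaluations, best CV MSE ",
      format(min(x$history$objective), digits = 4), "\n", sep = "")
  cat("  best hyperparameters: ",
      paste(names(x$best_hyper),
            vapply(x$best_hyper, function(v) format(v, digits = 3), ""),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Regression metrics
#'
#' R2 = 1 - SS_res / SS_tot (centered on the mean of \code{truth}),
#' MAE = mean |e|, RMSE = sqrt(mean e^2) with e = predictions - truth.
#'
#' @param truth,predictions numeric vectors of equal length (>= 2).
#' @return list with \code{R2}, \code{MAE}, \code{RMSE}.
#' @export
regression_metrics <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions), length(truth) >= 2)
  e <- predictions - truth
  list(R2 = 1 - sum(e^2) / sum((truth - mean(truth))^2),
       MAE = mean(abs(e)), RMSE = sqrt(mean(e^2)))
}

#' Regression metrics on held-out rows
#'
#' Applies [regression_metrics()] to a fitted model's predictions on
#' held-out rows.
#'
#' @param model a \code{canopy_model} (or any object with a matching
#'   \code{predict} method).
#' @param matrix the \code{feature_matrix}.
#' @param test_rows row indices disjoint from training.
#' @param trait label column; defaults to the model's trait.
#' @return list of class \code{model_report}: \code{kind}, \code{fs_id},
#'   \code{trait}, \code{R2}, \code{MAE}, \code{RMSE}, \code{n_test},
#'   \code{predictions}, \code{truth}.
#' @export
evaluate_model <- function(model, matrix, test_rows, trait = model$trait) {
  if (length(test_rows) < 2) stop("need at least 2 test rows")
  truth <- matrix[[trait]][test_rows]
  pred <- stats::predict(model, matrix[test_rows, , drop = FALSE])
  mt <- regression_metrics(truth, pred)
  structure(list(kind = model$spec$kind, fs_id = attr(matrix, "fs_id"),
                 trait = trait,
                 R2 = mt$R2, MAE = mt$MAE, RMSE = mt$RMSE,
                 n_test = length(test_rows), predictions = pred,
                 truth = truth, best_hyper = model$best_hyper),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s / %s / %s: R2 = %.4f, MAE = %.4f, RMSE = %.4f (n = %d)\n",
              x$kind, x$fs_id, x$trait, x$R2, x$MAE, x$RMSE, x$n_test))
  invisible(x)
}
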