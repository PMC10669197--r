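#' Age-prediction evaluation metrics
#'
#' For real ages `x` and predicted ages `y`: Pearson correlation `r`;
#' `RMSE = sqrt(mean((x - y)^2))` in years; `MAPE = mean(abs(x - y) / x)`
#' (dimensionless; absolute errors, so the metric is nonnegative); and the
#' coefficient of determination `R2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2)`,
#' which is computed directly on the given pair and can be negative on
#' validation data.
#'
#' @param x Real ages in years (positive; the MAPE denominator).
#' @param y Predicted ages, same length, at least 2 values.
#' @return Object of class `vm_metrics`: list with `r`, `rmse`, `mape`,
#'   `r2` and `n`. If `x` or `y` is constant, `r` is `NA` and the
#'   remaining metrics are still returned (with a `note`).
#' @examples
#' m <- evaluate_predictions(c(50, 60), c(55, 54))
#' m$rmse  # sqrt((25 + 36) / 2)
#' m$mape  # 0.1
#' @export
evaluate_predictions <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    vm_stop("x and y must have equal length >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    vm_stop("x and y must be finite")
  if (any(x <= 0))
    vm_stop("real ages must be positive (MAPE denominator)")
  note <- NULL
  r <- if (sd(x) == 0 || sd(y) == 0) {
    note <- "constant input: Pearson r undefined"
    NA_real_
  } else {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  sse <- sum((x - y)^2)
  sst <- sum((x - mean(x))^2)
  structure(list(r = r,
                 rmse = sqrt(sse / length(x)),
                 mape = mean(abs(x - y) / x),
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 n = length(x), note = note),
            class = "vm_metrics")
}

#' @export
print.vm_metrics <- function(x, ...) {
  cat(sprintf("r = %.3f, RMSE = %.3f, MAPE = %.3f, R2 = %.3f (n = %d)\n",
              x$r, x$rmse, x$mape, x$r2, x$n))
  invisible(x)
}

#' Random fold assignment
#'
#' Uniform random partition of the subjects into `k` groups whose sizes
#' differ by at most one; reproducible under `seed`.
#'
#' @param ids Subject identifiers.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold labels (1..k) named by `ids`.
#' @export
assign_folds <- function(ids, k = 4, seed = 1L) {
  n <- length(ids)
  if (k < 2) vm_stop("k must be >= 2")
  if (n < k) vm_stop("need at least k subjects (", k, "), got ", n)
  withr::with_seed(as.integer(seed), {
    perm <- sample.int(n)
    fold <- integer(n)
    fold[perm] <- rep_len(seq_len(k), n)
    setNames(fold, ids)
  })
}

#' Randomized hyperparameter search
#'
#' Samples `n_iter` configurations uniformly from the spec's search space
#' and scores each by mean absolute error over an inner `inner_k`-fold split
#' of the supplied training table only; returns the spec updated to the best
#' configuration. With an empty search space the spec is returned unchanged
#' with a warning recorded in the `search_warning` attribute.
#'
#' @param spec A [model_spec()] with a `search_space`.
#' @param table Training `feature_table` (rows of the outer training fold).
#' @param n_iter Number of sampled configurations.
#' @param seed RNG seed (sampling and inner folds).
#' @param inner_k Inner CV fold count (default 3).
#' @return A tuned [model_spec()]; attribute `search_results` holds the
#'   sampled configurations and scores.
#' @export
randomized_search <- function(spec, table, n_iter = 10, seed = 1L,
                              inner_k = 3) {
  if (!inherits(spec, "model_spec")) vm_stop("spec must be a model_spec")
  if (is.null(spec$search_space) || !length(spec$search_space)) {
    warning("empty search space for ", spec$family,
            "; returning spec unchanged")
    attr(spec, "search_warning") <- "empty search space"
    return(spec)
  }
  X <- .design_of(table)
  y <- table$age
  cfgs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_iter), function(i) {
      lapply(spec$search_space, function(v) v[[sample.int(length(v), 1)]])
    })
  })
  folds <- assign_folds(seq_len(nrow(X)), k = inner_k,
                        seed = .child_seed(seed, 1))
  scores <- vapply(seq_along(cfgs), function(ci) {
    sp <- model_spec(spec$family, params = utils::modifyList(spec$params,
                                                             cfgs[[ci]]))
    maes <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f
      m <- fit_model(sp, X[tr, , drop = FALSE], y[tr],
                     seed = .child_seed(seed, 100 + ci))
      mean(abs(y[!tr] - predict(m, X[!tr, , drop = FALSE])))
    }, numeric(1))
    mean(maes)
  }, numeric(1))
  best <- which.min(scores)
  out <- model_spec(spec$family,
                    params = utils::modifyList(spec$params, cfgs[[best]]),
                    search_space = spec$search_space)
  attr(out, "search_results") <- list(configs = cfgs, scores = scores,
                                      best = best)
  out
}

.design_of <- function(table) {
  X <- as.matrix(table[, vm_feature_names(), drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Cross-validated training and evaluation
#'
#' For each of `k` folds: (optionally) tune each model on the training
#' portion by randomized search, fit, predict the held-out subjects, and
#' evaluate r, RMSE, MAPE and R2. Training-fold predictions are retained as
#' well. Aggregation is mean +/- SD across folds. Importances of tree-based
#' families are impurity-gain values averaged across folds.
#'
#' @param table A complete `feature_table`.
#' @param specs Named list of [model_spec()]s (default: all six families at
#'   their reference hyperparameters).
#' @param k Fold count (default 4).
#' @param seed Seed for fold assignment and all model fitting.
#' @param tune Run [randomized_search()] per fold (requires search spaces).
#' @param n_iter Search iterations when tuning.
#' @return An object of class `cv_result`.
#' @export
run_cv <- function(table, specs = default_model_specs(), k = 4, seed = 1L,
                   tune = FALSE, n_iter = 10) {
  if (!all(.table_schema() %in% names(table)))
    vm_stop("table does not follow the feature-table schema")
  if (anyNA(table[, .table_schema()])) vm_stop("table has missing values")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "family")
  X <- .design_of(table)
  y <- table$age
  folds <- assign_folds(table$subject_id, k = k, seed = seed)
  fold_metrics <- list()
  predictions <- list()
  importances <- list()
  errors <- list()
  for (mn in names(specs)) {
    sp <- specs[[mn]]
    per_fold <- list()
    imp_acc <- NULL
    for (f in seq_len(k)) {
      tr <- folds != f
      res <- tryCatch({
        sp_f <- sp
        if (tune && !is.null(sp$search_space))
          sp_f <- randomized_search(sp, table[tr, , drop = FALSE],
                                    n_iter = n_iter,
                                    seed = .child_seed(seed, f))
        m <- fit_model(sp_f, X[tr, , drop = FALSE], y[tr],
                       seed = .child_seed(seed, 10 * f))
        pv <- predict(m, X[!tr, , drop = FALSE])
        pt <- predict(m, X[tr, , drop = FALSE])
        list(model = m, val = evaluate_predictions(y[!tr], pv),
             train = evaluate_predictions(y[tr], pt), pv = pv, pt = pt)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          data.frame(model = mn, fold = f, message = conditionMessage(res))
        next
      }
      per_fold[[f]] <- res$val
      predictions[[length(predictions) + 1L]] <- data.frame(
        model = mn, fold = f, subject_id = table$subject_id[!tr],
        set = "validation", age = y[!tr], predicted = res$pv)
      predictions[[length(predictions) + 1L]] <- data.frame(
        model = mn, fold = f, subject_id = table$subject_id[tr],
        set = "training", age = y[tr], predicted = res$pt)
      if (isTRUE(sp$tree_based)) {
        imp <- res$model$fit$importance_raw
        imp <- if (sum(imp) > 0) imp / sum(imp) else
          rep(1 / length(imp), length(imp))
        imp_acc <- if (is.null(imp_acc)) imp else imp_acc + imp
      }
      fold_metrics[[length(fold_metrics) + 1L]] <- data.frame(
        model = mn, fold = f, r = res$val$r, rmse = res$val$rmse,
        mape = res$val$mape, r2 = res$val$r2)
    }
    if (!is.null(imp_acc)) {
      w <- imp_acc / sum(imp_acc)
      ord <- order(-w, seq_along(w))
      importances[[mn]] <- data.frame(feature = vm_feature_names()[ord],
                                      importance = w[ord])
    }
  }
  fm <- do.call(rbind, fold_metrics)
  agg <- do.call(rbind, lapply(split(fm, fm$model), function(d) {
    data.frame(model = d$model[1],
               rmse_mean = mean(d$rmse), rmse_sd = sd(d$rmse),
               r2_mean = mean(d$r2), r2_sd = sd(d$r2),
               mape_mean = mean(d$mape), mape_sd = sd(d$mape),
               r_mean = mean(d$r), r_sd = sd(d$r))
  }))
  agg <- agg[match(intersect(names(specs), agg$model), agg$model), ]
  rownames(agg) <- NULL
  structure(list(fold_metrics = fm, aggregated = agg,
                 folds = folds,
                 predictions = do.call(rbind, predictions),
                 importances = importances,
                 errors = if (length(errors)) do.call(rbind, errors) else NULL,
                 k = k, seed = seed),
            class = "cv_result")
}

#' Reference model set
#'
#' All six families at their registry defaults.
#'
#' @return Named list of [model_spec()]s.
#' @export
default_model_specs <- function() {
  fams <- c("random_forest", "linear", "adaboost", "gradient_boosting",
            "bayesian_ridge", "xgb_style_boosting")
  setNames(lapply(fams, model_spec), fams)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  a <- x$aggregated
  cat(sprintf("%-22s %-16s %-16s %-16s %-16s\n", "Model", "RMSE", "R2",
              "MAPE", "Pearson r"))
  for (i in seq_len(nrow(a))) {
    cat(sprintf("%-22s %6.3f +/- %-6.3f %6.3f +/- %-6.3f %6.3f +/- %-6.3f %6.3f +/- %-6.3f\n",
                a$model[i], a$rmse_mean[i], a$rmse_sd[i], a$r2_mean[i],
                a$r2_sd[i], a$mape_mean[i], a$mape_sd[i], a$r_mean[i],
                a$r_sd[i]))
  }
  invisible(x)
}

#' Real-vs-predicted age scatter plot
#'
#' Writes a scatter of real against predicted ages with the identity line,
#' plus a CSV sidecar of the plotted coordinates for programmatic checks.
#' The device is chosen from the file extension (`.pdf` or `.png`).
#'
#' @param x Real ages.
#' @param y Predicted ages.
#' @param path Output image path.
#' @param title Plot title.
#' @return `path`, invisibly.
#' @export
scatter_plot <- function(x, y, path, title = "Age prediction") {
  if (length(x) != length(y) || length(x) == 0L)
    vm_stop("x and y must be nonempty and of equal length")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = 600, height = 600, type = "cairo")
  } else {
    grDevices::pdf(path, width = 6, height = 6)
  }
  on.exit(grDevices::dev.off())
  rng <- range(c(x, y))
  graphics::plot(x, y, col = "blue", pch = 16, xlim = rng, ylim = rng,
                 xlab = "Real age (years)", ylab = "Predicted age (years)",
                 main = title)
  graphics::abline(0, 1, col = "red")
  write.csv(data.frame(age = x, predicted = y),
            paste0(tools::file_path_sans_ext(path), "_points.csv"),
            row.names = FALSE)
  invisible(path)
}
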