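#' Stratified train/test split
#'
#' Splits a labeled feature table 70/30 (by default) stratified by label, so
#' both classes are represented in both partitions at the overall fraction
#' to within one record per class.
#'
#' @param features Data frame of covariates (numeric modeling columns;
#'   coordinate/meta columns `x`, `y`, `row`, `col`, `season`, `label`,
#'   `source` are carried along but not modeled).
#' @param labels Positive-class indicator per row (see [auc_score()]).
#' @param train_fraction Training share (default 0.7).
#' @param seed Integer seed; same seed, same split.
#' @return A tibble of class `training_table`: features plus `label` (0/1)
#'   and `split` (`"train"`/`"test"`). Attributes `feature_vars`,
#'   `split_seed`, `train_fraction`.
#' @export
split_table <- function(features, labels, train_fraction = 0.7, seed = 1L) {
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  lab <- as_binary_labels(labels)
  if (length(lab) != nrow(features)) {
    abort("`labels` must have one value per feature row.")
  }
  assert_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  for (cls in c(0L, 1L)) {
    if (sum(lab == cls) < 10L) {
      abort(sprintf("Need at least 10 rows per class; class %d has %d.", cls, sum(lab == cls)))
    }
  }
  split <- rep("test", length(lab))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(lab == cls)
      n_train <- round(train_fraction * length(idx))
      split[sample(idx, n_train)] <- "train"
    }
  })
  out <- as_tibble(features)
  out$label <- lab
  out$split <- split
  meta <- c("x", "y", "row", "col", "season", "source", "label", "split")
  fv <- names(out)[vapply(out, is.numeric, logical(1))]
  fv <- setdiff(fv, meta)
  if (length(fv) == 0L) abort("No numeric covariate columns found.")
  for (p in c("train", "test")) {
    if (length(unique(out$label[out$split == p])) < 2L) {
      abort(sprintf("Both classes must be present in the %s partition.", p))
    }
  }
  attr(out, "feature_vars") <- fv
  attr(out, "split_seed") <- as.integer(seed)
  attr(out, "train_fraction") <- train_fraction
  class(out) <- unique(c("training_table", class(out)))
  out
}

# ---------------------------------------------------------------------------
# Learner registries. Each learner: tag + fit(x_df, y_int, seed) + predict
# (model, x_df) -> P(label = 1). "fire6" is the six-learner wildfire suite;
# "sdm8" the eight-learner species-habitat suite. Proprietary learners in
# the originating workflow are represented by functionally equivalent open
# implementations (xgboost for the boosted tree ensemble, glmnet for the
# regularized logistic path, a natural-spline basis logistic regression for
# the adaptive-spline member).
# ---------------------------------------------------------------------------

learner_logistic <- function() {
  list(
    tag = "logistic",
    fit = function(x, y, seed) {
      d <- x
      d$.label <- y
      suppressWarnings(glm(.label ~ ., family = binomial(), data = d))
    },
    predict = function(model, x) {
      unname(suppressWarnings(predict(model, newdata = x, type = "response")))
    }
  )
}

learner_spline_logistic <- function(df = 3L) {
  list(
    tag = "spline_logistic",
    fit = function(x, y, seed) {
      terms <- vapply(names(x), function(nm) {
        if (length(unique(x[[nm]])) > 2L * df) {
          sprintf("splines::ns(%s, df = %d)", nm, df)
        } else {
          nm
        }
      }, character(1))
      d <- x
      d$.label <- y
      f <- stats::as.formula(paste(".label ~", paste(terms, collapse = " + ")))
      suppressWarnings(glm(f, family = binomial(), data = d))
    },
    predict = function(model, x) {
      unname(suppressWarnings(predict(model, newdata = x, type = "response")))
    }
  )
}

learner_cta <- function() {
  list(
    tag = "cta",
    fit = function(x, y, seed) {
      d <- x
      d$.label <- factor(y, levels = c(0L, 1L))
      with_seed(seed, rpart::rpart(.label ~ ., data = d, method = "class"))
    },
    predict = function(model, x) {
      unname(predict(model, newdata = x, type = "prob")[, "1"])
    }
  )
}

learner_rf <- function(ntree = 500L) {
  list(
    tag = "rf",
    fit = function(x, y, seed) {
      with_seed(seed, randomForest::randomForest(
        x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)), ntree = ntree
      ))
    },
    predict = function(model, x) {
      unname(predict(model, newdata = as.data.frame(x), type = "prob")[, "1"])
    }
  )
}

learner_gbt <- function(nrounds = 60L) {
  list(
    tag = "gbt",
    fit = function(x, y, seed) {
      vars <- names(x)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1L)
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", max_depth = 3L, eta = 0.3,
          nthread = 1L, seed = seed
        ),
        data = dtrain, nrounds = nrounds, verbose = 0
      ))
      list(fit = fit, vars = vars)
    },
    predict = function(model, x) {
      dm <- xgboost::xgb.DMatrix(as.matrix(x[model$vars]), nthread = 1L)
      unname(predict(model$fit, newdata = dm))
    }
  )
}

learner_enet <- function(alpha = 0.5) {
  list(
    tag = "enet",
    fit = function(x, y, seed) {
      xm <- as.matrix(x)
      foldid <- with_seed(seed, sample(rep(1:5, length.out = length(y))))
      fit <- glmnet::cv.glmnet(
        xm, y, family = "binomial", alpha = alpha,
        foldid = foldid, type.measure = "auc"
      )
      list(fit = fit, vars = colnames(xm))
    },
    predict = function(model, x) {
      as.numeric(predict(
        model$fit, newx = as.matrix(x[model$vars]),
        s = "lambda.min", type = "response"
      ))
    }
  )
}

learner_gam <- function(k = 5L) {
  list(
    tag = "gam",
    fit = function(x, y, seed) {
      terms <- vapply(names(x), function(nm) {
        if (length(unique(x[[nm]])) > 2L * k) sprintf("s(%s, k = %d)", nm, k) else nm
      }, character(1))
      d <- x
      d$.label <- y
      f <- stats::as.formula(paste(".label ~", paste(terms, collapse = " + ")))
      suppressWarnings(mgcv::gam(f, family = binomial(), data = d, method = "REML"))
    },
    predict = function(model, x) {
      as.numeric(suppressWarnings(predict(model, newdata = x, type = "response")))
    }
  )
}

learner_ann <- function(size = 4L, decay = 0.01, maxit = 300L) {
  list(
    tag = "ann",
    fit = function(x, y, seed) {
      mu <- vapply(x, mean, numeric(1))
      sdev <- pmax(vapply(x, stats::sd, numeric(1)), 1e-12)
      z <- scale(as.matrix(x), center = mu, scale = sdev)
      fit <- with_seed(seed, nnet::nnet(
        x = z, y = y, size = size, decay = decay, maxit = maxit,
        entropy = TRUE, trace = FALSE
      ))
      list(fit = fit, center = mu, scale = sdev, vars = names(x))
    },
    predict = function(model, x) {
      z <- scale(as.matrix(x[model$vars]), center = model$center, scale = model$scale)
      as.numeric(predict(model$fit, z))
    }
  )
}

learner_svm <- function() {
  list(
    tag = "svm",
    fit = function(x, y, seed) {
      with_seed(seed, e1071::svm(
        x = as.matrix(x), y = factor(y, levels = c(0L, 1L)),
        kernel = "radial", probability = TRUE
      ))
    },
    predict = function(model, x) {
      p <- predict(model, newdata = as.matrix(x), probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    }
  )
}

#' Learner registries for the classification suites
#'
#' `"fire6"` is the six-learner wildfire-risk suite (bagged trees, single
#' classification tree, spline-basis logistic, gradient-boosted trees,
#' elastic-net logistic path, plain logistic regression). `"sdm8"` is the
#' eight-learner species-habitat suite (adds a generalized additive model, a
#' single-hidden-layer neural network and a kernel max-margin classifier).
#'
#' @param registry `"fire6"` or `"sdm8"`, or a custom list of learners (each
#'   a list with `tag`, `fit(x, y, seed)`, `predict(model, x)`).
#' @return A named list of learner definitions.
#' @export
learner_registry <- function(registry = c("fire6", "sdm8")) {
  if (is.list(registry)) {
    return(registry)
  }
  registry <- match.arg(registry)
  members <- switch(registry,
    fire6 = list(
      learner_rf(), learner_cta(), learner_spline_logistic(),
      learner_gbt(), learner_enet(), learner_logistic()
    ),
    sdm8 = list(
      learner_logistic(), learner_gam(), learner_spline_logistic(),
      learner_gbt(), learner_cta(), learner_rf(), learner_ann(), learner_svm()
    )
  )
  setNames(members, vapply(members, `[[`, character(1), "tag"))
}

#' Fit a multi-learner classifier suite and weight it by AUC
#'
#' Fits every learner in the registry on the training partition, scores it
#' on the test partition, and records the test AUC as the member's ensemble
#' weight (normalized to sum 1). Learners that fail to fit are dropped with
#' a warning and the ensemble proceeds with the survivors; fewer than two
#' survivors is an error.
#'
#' @param table A `training_table` from [split_table()].
#' @param registry Registry id or custom learner list (see
#'   [learner_registry()]).
#' @param seed Integer seed; member fits are seeded deterministically from
#'   it.
#' @param weight_mode `"auc"` (raw test AUC, default) or `"auc_excess"`
#'   (AUC − 0.5, floored at 0), controlling the ensemble weights.
#' @return An object of class `classifier_ensemble`.
#' @export
fit_suite <- function(table, registry = "fire6", seed = 1L,
                      weight_mode = c("auc", "auc_excess")) {
  if (!inherits(table, "training_table")) abort("`table` must come from split_table().")
  weight_mode <- match.arg(weight_mode)
  learners <- learner_registry(registry)
  fv <- attr(table, "feature_vars")
  train <- table[table$split == "train", ]
  test <- table[table$split == "test", ]
  members <- list()
  dropped <- character(0)
  for (i in seq_along(learners)) {
    ln <- learners[[i]]
    fitted <- tryCatch(
      {
        model <- ln$fit(train[fv], train$label, seed = seed + i)
        p_test <- ln$predict(model, test[fv])
        if (anyNA(p_test)) stop("learner produced NA predictions")
        list(model = model, auc = auc_score(p_test, test$label), p_test = p_test)
      },
      error = function(e) e
    )
    if (inherits(fitted, "error")) {
      warn(sprintf("Learner '%s' failed to fit and was dropped: %s",
                   ln$tag, conditionMessage(fitted)))
      dropped <- c(dropped, ln$tag)
      next
    }
    members[[ln$tag]] <- list(
      tag = ln$tag, model = fitted$model, predict = ln$predict,
      auc = fitted$auc, p_test = fitted$p_test
    )
  }
  if (length(members) < 2L) {
    abort("Fewer than 2 learners survived fitting; cannot build an ensemble.")
  }
  aucs <- vapply(members, `[[`, numeric(1), "auc")
  w <- switch(weight_mode, auc = aucs, auc_excess = pmax(aucs - 0.5, 0))
  if (sum(w) <= 0) w <- rep(1, length(w)) # degenerate: fall back to equal weights
  w <- w / sum(w)
  test_scores <- as.vector(vapply(members, `[[`, numeric(nrow(test)), "p_test") %*% w)
  structure(
    list(
      members = members,
      weights = setNames(w, names(members)),
      feature_vars = fv,
      registry = if (is.character(registry)) registry else "custom",
      weight_mode = weight_mode,
      dropped = dropped,
      test_scores = test_scores,
      test_labels = test$label,
      seed = as.integer(seed)
    ),
    class = "classifier_ensemble"
  )
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  cat(sprintf(
    "<classifier_ensemble> registry '%s', %d member(s), AUC-%s weighting\n",
    x$registry, length(x$members),
    if (x$weight_mode == "auc") "proportional" else "excess"
  ))
  for (nm in names(x$members)) {
    cat(sprintf("  %-16s test AUC %.3f  weight %.3f\n",
                nm, x$members[[nm]]$auc, x$weights[[nm]]))
  }
  if (length(x$dropped) > 0L) {
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn fit_suite Predict weighted-ensemble probabilities for new data
#'   (a data frame containing the feature columns).
#' @param object A `classifier_ensemble`.
#' @param newdata Data frame with the ensemble's feature columns.
#' @param ... Unused.
#' @export
predict.classifier_ensemble <- function(object, newdata, ...) {
  check_columns(newdata, object$feature_vars)
  x <- newdata[object$feature_vars]
  p <- vapply(
    object$members,
    function(m) as.numeric(m$predict(m$model, x)),
    numeric(nrow(x))
  )
  if (nrow(x) == 1L) p <- matrix(p, nrow = 1L) # vapply drops to vector
  as.vector(p %*% object$weights)
}

#' Predict an ensemble probability surface over a raster stack
#'
#' Cell value = the AUC-weighted mean of member probabilities; bounded by
#' the member minimum and maximum at every cell. Nodata propagates: cells
#' that are nodata in any required layer are nodata in the output.
#'
#' @param ensemble A `classifier_ensemble` from [fit_suite()].
#' @param stack A `raster_stack` whose layers cover the ensemble's feature
#'   names (extra layers are ignored; a missing layer is an error naming
#'   it).
#' @return A probability `raster_grid` with values in `[0, 1]`.
#' @export
predict_ensemble <- function(ensemble, stack) {
  if (!inherits(ensemble, "classifier_ensemble")) {
    abort("`ensemble` must be a classifier_ensemble.")
  }
  if (!inherits(stack, "raster_stack")) abort("`stack` must be a raster_stack.")
  missing <- setdiff(ensemble$feature_vars, names(stack$layers))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Stack is missing layer(s) required by the ensemble: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  cells <- as_tibble(stack, drop_na = TRUE)
  p <- predict(ensemble, cells)
  ref <- stack$layers[[1L]]
  v <- rep(NA_real_, length(ref$values))
  lin <- (cells$col - 1L) * nrow(ref$values) + cells$row
  v[lin] <- p
  raster_grid(matrix(v, nrow(ref$values), ncol(ref$values)),
              ref$cell_size, ref$origin, ref$crs)
}

#' Permutation variable importance from a bagged-tree learner
#'
#' Fits the bagged-tree (random forest) learner on the training partition,
#' then measures each variable's importance as the mean drop in test AUC
#' over `n_perm` random permutations of that variable (floored at 0) and
#' normalizes the weights to sum 1.
#'
#' @param table A `training_table`.
#' @param seed Integer seed (fit and permutations).
#' @param n_perm Permutations per variable (default 10).
#' @param tag Optional season tag recorded on the rows.
#' @return A tibble of class `importance_table` with columns `variable`,
#'   `weight` (and `tag`), sorted by decreasing weight.
#' @export
variable_importance <- function(table, seed = 1L, n_perm = 10L, tag = NA_character_) {
  if (!inherits(table, "training_table")) abort("`table` must come from split_table().")
  if (n_perm < 1L) abort("`n_perm` must be >= 1.")
  fv <- attr(table, "feature_vars")
  train <- table[table$split == "train", ]
  test <- table[table$split == "test", ]
  rf <- learner_rf()
  model <- rf$fit(train[fv], train$label, seed = seed)
  base_auc <- auc_score(rf$predict(model, test[fv]), test$label)
  drops <- with_seed(seed + 1L, vapply(fv, function(v) {
    mean(vapply(seq_len(n_perm), function(i) {
      perm <- test[fv]
      perm[[v]] <- sample(perm[[v]])
      base_auc - auc_score(rf$predict(model, perm), test$label)
    }, numeric(1)))
  }, numeric(1)))
  w <- pmax(drops, 0)
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  out <- tibble(variable = fv, weight = unname(w), tag = as.character(tag))
  out <- out[order(-out$weight), ]
  class(out) <- unique(c("importance_table", class(out)))
  out
}

#' @export
tidy.classifier_ensemble <- function(x, ...) {
  tibble(
    learner = names(x$members),
    auc = vapply(x$members, `[[`, numeric(1), "auc"),
    weight = unname(x$weights)
  )
}

#' @export
glance.classifier_ensemble <- function(x, ...) {
  tibble(
    registry = x$registry,
    n_learners = length(x$members),
    n_dropped = length(x$dropped),
    mean_member_auc = mean(vapply(x$members, `[[`, numeric(1), "auc")),
    ensemble_auc = auc_score(x$test_scores, x$test_labels)
  )
}
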