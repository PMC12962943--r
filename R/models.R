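# Classifier back-ends and probability-score fusion.
#
# All four classifiers return risk scores in [0, 1], handle the 1:4 class
# imbalance with inverse-prevalence class weights, and are deterministic
# given a seed. Hyperparameters are fixed (no tuning): ridge logistic
# regression (lambda = 1/n, the C = 1 convention), RBF-kernel SVM (cost 1,
# gamma = 1/p on standardized inputs) with Platt scaling fit on the training
# decision values, random forest with 500 trees and sqrt-p variables per
# split, and XGBoost with 200 depth-3 rounds at learning rate 0.1.

classifier_kinds <- c("logistic", "svm", "rf", "xgb")

#' Train a risk classifier
#'
#' @param kind One of `"logistic"`, `"svm"`, `"rf"`, `"xgb"`.
#' @param X Numeric training matrix (rows = cases, named columns).
#' @param y Binary labels (`MSI-H`/logical/0-1), both classes present.
#' @param seed Integer seed (drives the stochastic learners).
#' @return A `msirad_model` object; score cases with [score_cases()].
#' @export
train_risk_model <- function(kind = classifier_kinds, X, y, seed = 1L) {
  kind <- match.arg(kind)
  y <- check_two_classes(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  w <- ifelse(y, n / (2 * sum(y)), n / (2 * sum(!y)))

  scaler <- NULL
  if (kind %in% c("logistic", "svm")) {
    mu <- colMeans(X)
    sdev <- apply(X, 2L, sd)
    sdev[sdev == 0] <- 1
    scaler <- list(mean = mu, sd = sdev)
    X <- scale_matrix(X, scaler)
  }

  fit <- switch(kind,
    logistic = {
      Xg <- if (ncol(X) == 1L) cbind(X, .dummy = 0) else X
      suppressWarnings(
        glmnet::glmnet(Xg, factor(y), family = "binomial", alpha = 0,
                       lambda = 1 / n, weights = w, standardize = FALSE)
      )
    },
    svm = {
      sv <- e1071::svm(X, factor(y), kernel = "radial", cost = 1,
                       gamma = 1 / ncol(X), scale = FALSE,
                       class.weights = c("FALSE" = n / (2 * sum(!y)),
                                         "TRUE" = n / (2 * sum(y))))
      dv <- as.numeric(attr(predict(sv, X, decision.values = TRUE),
                            "decision.values"))
      platt <- suppressWarnings(glm(y ~ dv, family = binomial()))
      co <- coef(platt)
      co[is.na(co)] <- 0
      list(svm = sv, platt = co)
    },
    rf = withr::with_seed(seed, {
      randomForest::randomForest(
        X, factor(y), ntree = 500,
        mtry = max(1L, floor(sqrt(ncol(X)))),
        classwt = c("FALSE" = sum(y) / n, "TRUE" = sum(!y) / n)
      )
    }),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      params <- list(objective = "binary:logistic", max_depth = 3,
                     eta = 0.1, nthread = 1, seed = seed,
                     scale_pos_weight = sum(!y) / sum(y))
      xgboost::xgb.train(params = params, data = dtrain, nrounds = 200,
                         verbose = 0)
    }
  )
  structure(
    list(kind = kind, fit = fit, features = colnames(X)[!startsWith(colnames(X), ".dummy")],
         scaler = scaler, seed = seed),
    class = "msirad_model"
  )
}

scale_matrix <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$mean[colnames(X)], "-"),
        2L, scaler$sd[colnames(X)], "/")
}

#' Score cases with a fitted risk model
#'
#' Column matching is name-based: input columns may be in any order and may
#' contain extras, but every model feature must be present.
#'
#' @param model A `msirad_model`.
#' @param X Numeric matrix or feature tibble to score.
#' @return Risk scores in `[0, 1]`, one per row.
#' @export
score_cases <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "case_id")])
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, model$features))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing) > 0L) {
    stop_schema(paste0("missing feature column(s): ",
                       paste(head(missing, 5L), collapse = ", ")))
  }
  X <- X[, model$features, drop = FALSE]
  if (!is.null(model$scaler)) X <- scale_matrix(X, model$scaler)
  s <- switch(model$kind,
    logistic = {
      Xg <- if (ncol(X) == 1L) cbind(X, .dummy = 0) else X
      as.numeric(predict(model$fit, Xg, type = "response"))
    },
    svm = {
      dv <- as.numeric(attr(predict(model$fit$svm, X, decision.values = TRUE),
                            "decision.values"))
      as.numeric(plogis(model$fit$platt[1] + model$fit$platt[2] * dv))
    },
    rf = as.numeric(predict(model$fit, X, type = "prob")[, "TRUE"]),
    xgb = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X)))
  )
  pmin(1, pmax(0, s))
}

#' @export
predict.msirad_model <- function(object, newdata, ...) score_cases(object, newdata)

#' @export
print.msirad_model <- function(x, ...) {
  cat("<msirad_model> ", x$kind, " on ", length(x$features), " feature(s): ",
      paste(head(x$features, 5L), collapse = ", "),
      if (length(x$features) > 5L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Fuse tumor- and pancreas-model risk scores
#'
#' Fits the combined (IntRad) model: a two-input logistic regression (plus
#' intercept) of the MSI label on the tumor-model and pancreas-model
#' probability scores. The channel scores supplied here must be out-of-fold
#' (leak-free) for the training cases.
#'
#' @param tum_scores,panc_scores Out-of-fold channel scores for the training
#'   cases.
#' @param y Binary training labels.
#' @return A `msirad_fusion` object; score with [score_fusion()].
#' @export
train_fusion <- function(tum_scores, panc_scores, y) {
  y <- check_two_classes(y)
  df <- data.frame(tum = tum_scores, panc = panc_scores, y = y)
  fit <- suppressWarnings(glm(y ~ tum + panc, family = binomial(), data = df))
  co <- coef(fit)
  co[is.na(co)] <- 0
  structure(list(coef = co), class = "msirad_fusion")
}

#' Score the fusion model
#'
#' @param fusion A `msirad_fusion`.
#' @param tum_scores,panc_scores Channel scores of the cases to score.
#' @return Fused risk scores in `[0, 1]`.
#' @export
score_fusion <- function(fusion, tum_scores, panc_scores) {
  as.numeric(plogis(fusion$coef[1] + fusion$coef[2] * tum_scores +
                      fusion$coef[3] * panc_scores))
}

#' @export
predict.msirad_fusion <- function(object, tum_scores, panc_scores, ...) {
  score_fusion(object, tum_scores, panc_scores)
}
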