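#' Bundle features and win/loss labels for classification
#'
#' @param features Numeric matrix or data.frame (rows = sessions, named
#'   columns = measures). No missing values.
#' @param labels Character/factor vector of `"WIN"` / `"LOSS"`.
#' @return A `spy_dataset` with `features` (matrix), `labels` (factor with
#'   levels LOSS, WIN) and `class_counts`.
#' @export
labelled_dataset <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  if (anyNA(features)) spy_abort("features contain missing values",
                                 "spyquest_bad_dataset")
  labels <- factor(as.character(labels), levels = c("LOSS", "WIN"))
  if (anyNA(labels) || length(labels) != nrow(features)) {
    spy_abort("labels must be WIN/LOSS, one per feature row",
              "spyquest_bad_dataset")
  }
  structure(list(features = features, labels = labels,
                 class_counts = table(labels)),
            class = "spy_dataset")
}

#' Session table to labelled dataset
#'
#' @param sessions A session table from [summarize_sessions()].
#' @param feature_cols Which numeric columns to use as features; the
#'   default single-feature model uses the player's elimination count.
#' @return A `spy_dataset`. Rows flagged with an `excluded_reason` or with
#'   missing feature values are dropped first.
#' @export
sessions_to_dataset <- function(sessions, feature_cols = "n_player_eliminated") {
  keep <- rep(TRUE, nrow(sessions))
  if ("excluded_reason" %in% names(sessions)) {
    keep <- keep & is.na(sessions$excluded_reason)
  }
  for (col in feature_cols) keep <- keep & !is.na(sessions[[col]])
  s <- sessions[keep, , drop = FALSE]
  labelled_dataset(as.matrix(s[feature_cols]),
                   ifelse(s$won, "WIN", "LOSS"))
}

#' SMOTE: synthetic minority oversampling
#'
#' Grows the minority class to the majority count by interpolation: each
#' synthetic point is `x_i + u * (x_nn - x_i)` for a random minority point
#' `x_i`, one of its `k` nearest minority neighbours `x_nn` (Euclidean
#' distance on features standardized by their overall SD), and
#' `u ~ Uniform(0, 1)`. Majority rows pass through untouched; the output
#' has equal class counts; the draw is deterministic under the seed.
#'
#' @param dataset A `spy_dataset`.
#' @param k Number of nearest minority neighbours (default 5; capped at
#'   minority size minus one).
#' @param seed Integer seed.
#' @return A balanced `spy_dataset`.
#' @export
smote_oversample <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "spy_dataset"), k >= 1L)
  counts <- dataset$class_counts
  if (counts[1] == counts[2]) return(dataset)
  minority <- names(counts)[which.min(counts)]
  X <- dataset$features
  min_idx <- which(dataset$labels == minority)
  n_min <- length(min_idx)
  if (n_min < 2L) spy_abort("minority class needs >= 2 members for SMOTE",
                            "spyquest_too_few_minority_samples")
  n_needed <- max(counts) - n_min
  Xm <- X[min_idx, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  Z <- sweep(Xm, 2, sds, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  k_eff <- min(as.integer(k), n_min - 1L)
  nn <- apply(D, 1, function(d) order(d)[seq_len(k_eff)])
  nn <- if (k_eff == 1L) matrix(nn, ncol = 1L) else t(nn)

  set.seed(seed)
  base <- sample.int(n_min, n_needed, replace = TRUE)
  pick <- vapply(base, function(i) nn[i, sample.int(k_eff, 1L)], integer(1))
  u <- stats::runif(n_needed)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  labelled_dataset(rbind(X, synth),
                   c(as.character(dataset$labels), rep(minority, n_needed)))
}

#' Stratified train/test split
#'
#' @param dataset A `spy_dataset`.
#' @param prop Training proportion (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` `spy_dataset`s (disjoint rows,
#'   stratified by label).
#' @export
split_train_test <- function(dataset, prop = 0.8, seed = 1L) {
  stopifnot(prop > 0, prop < 1)
  set.seed(seed)
  idx_train <- integer(0)
  for (cl in levels(dataset$labels)) {
    rows <- which(dataset$labels == cl)
    idx_train <- c(idx_train, sort(sample(rows, round(prop * length(rows)))))
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(dataset$labels), idx_train)
  list(
    train = labelled_dataset(dataset$features[idx_train, , drop = FALSE],
                             dataset$labels[idx_train]),
    test = labelled_dataset(dataset$features[idx_test, , drop = FALSE],
                            dataset$labels[idx_test])
  )
}

# Ridge-penalized IRLS; the fallback when maximum likelihood separates.
# The intercept is not penalized.
ridge_logistic <- function(X, y, lambda, tol = 1e-8, maxit = 100L) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    new_beta <- solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z))
    if (max(abs(new_beta - beta)) < tol) { beta <- drop(new_beta); converged <- TRUE; break }
    beta <- drop(new_beta)
  }
  list(coefficients = stats::setNames(beta, colnames(Xd)),
       converged = converged, iterations = it)
}

#' Fit the win/loss logistic regression
#'
#' Binary logistic regression (WIN = 1) fitted by iteratively reweighted
#' least squares via [stats::glm()] with convergence tolerance `1e-8` and
#' at most 100 iterations. Perfect separation is detected and flagged; the
#' model is then refitted with a tiny ridge penalty (`lambda = 1e-6`) so
#' coefficients stay finite.
#'
#' @param train A `spy_dataset` with both classes present.
#' @return A `spy_winloss_model`: `coefficients` (intercept first),
#'   `converged`, `iterations`, `separation`, `lambda`.
#' @export
fit_winloss_model <- function(train) {
  stopifnot(inherits(train, "spy_dataset"))
  if (any(train$class_counts == 0)) {
    spy_abort("both classes must be present to fit", "spyquest_bad_dataset")
  }
  df <- as.data.frame(train$features)
  df$.y <- as.integer(train$labels == "WIN")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) separation <- TRUE
  lambda <- 0
  if (separation) {
    lambda <- 1e-6
    rf <- ridge_logistic(train$features, df$.y, lambda)
    coefs <- rf$coefficients
    converged <- rf$converged
    iterations <- rf$iterations
  } else {
    coefs <- stats::coef(fit)
    converged <- fit$converged
    iterations <- fit$iter
    if (!converged) {
      spy_warn("logistic regression did not converge in 100 iterations",
               "spyquest_non_convergence")
    }
  }
  structure(list(coefficients = coefs, converged = converged,
                 iterations = iterations, separation = separation,
                 lambda = lambda,
                 feature_names = colnames(train$features)),
            class = "spy_winloss_model")
}

#' @export
print.spy_winloss_model <- function(x, ...) {
  cat(sprintf("<spy_winloss_model>%s\n",
              if (x$separation) " [separation; ridge fallback]" else ""))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
predict.spy_winloss_model <- function(object, newdata, type = c("prob", "class"),
                                      ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spy_dataset")) newdata$features else
    as.matrix(newdata)
  X <- X[, object$feature_names, drop = FALSE]
  p <- stats::plogis(drop(cbind(1, X) %*% object$coefficients))
  if (type == "prob") p else ifelse(p >= 0.5, "WIN", "LOSS")
}

#' Evaluate a fitted model on held-out sessions
#'
#' Classifies at threshold 0.5 and reports accuracy, per-class precision,
#' recall and F1 (harmonic mean of the two), and confusion counts.
#'
#' @param model A `spy_winloss_model`.
#' @param test A `spy_dataset` disjoint from the training rows.
#' @return A `spy_classifier_report`: `accuracy`, `per_class` (data.frame
#'   with class, precision, recall, f1, support), `confusion` (2x2 counts,
#'   rows = truth), `threshold`, `n`.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "spy_winloss_model"), inherits(test, "spy_dataset"))
  if (!length(test$labels)) spy_abort("empty test set", "spyquest_empty_test_set")
  pred <- factor(predict(model, test, type = "class"),
                 levels = c("LOSS", "WIN"))
  truth <- test$labels
  confusion <- table(truth = truth, predicted = pred)
  per_class <- do.call(rbind, lapply(c("LOSS", "WIN"), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               support = sum(truth == cl), stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = mean(pred == truth), per_class = per_class,
                 confusion = confusion, threshold = 0.5,
                 n = length(truth)),
            class = "spy_classifier_report")
}

#' @export
print.spy_classifier_report <- function(x, ...) {
  cat(sprintf("<spy_classifier_report> accuracy %.3f on n = %d\n",
              x$accuracy, x$n))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Full outcome-analysis pipeline on a session table
#'
#' The analysis pattern for imbalanced win/loss outcomes: stratified 80/20
#' train/test split, SMOTE rebalancing of the *training fold only* (no
#' leakage into the test fold), logistic regression, evaluation on the
#' untouched test fold.
#'
#' @param sessions Session table from [summarize_sessions()].
#' @param feature_cols Feature columns (default the elimination count).
#' @param seed Integer seed driving split and SMOTE.
#' @param k SMOTE neighbourhood size.
#' @param prop Training proportion.
#' @return List: `model`, `report`, `train_counts_before`,
#'   `train_counts_after`.
#' @export
analyze_outcomes <- function(sessions, feature_cols = "n_player_eliminated",
                             seed = 1L, k = 5L, prop = 0.8) {
  dataset <- sessions_to_dataset(sessions, feature_cols)
  parts <- split_train_test(dataset, prop = prop, seed = seed)
  before <- parts$train$class_counts
  train_bal <- smote_oversample(parts$train, k = k, seed = seed + 1L)
  model <- fit_winloss_model(train_bal)
  report <- evaluate_classifier(model, parts$test)
  list(model = model, report = report,
       train_counts_before = before,
       train_counts_after = train_bal$class_counts)
}

#' Simulate session outcomes with a known eliminations-to-win link
#'
#' Generates elimination counts uniform on 0..50 and win labels from
#' `logit(P(win)) = intercept + slope * eliminations`. Used to check that
#' the fitted model recovers a known monotone link.
#'
#' @param n Number of sessions.
#' @param intercept,slope True model parameters (defaults -2.5 and 0.1
#'   give win probabilities spanning roughly 0.08 to 0.92 over the room).
#' @param seed Integer seed.
#' @return A `spy_dataset` with the single feature `n_player_eliminated`.
#' @export
simulate_winloss_sessions <- function(n, intercept = -2.5, slope = 0.1,
                                      seed = 1L) {
  set.seed(seed)
  elim <- sample(0:50, n, replace = TRUE)
  p <- stats::plogis(intercept + slope * elim)
  won <- stats::runif(n) < p
  labelled_dataset(matrix(elim, ncol = 1,
                          dimnames = list(NULL, "n_player_eliminated")),
                   ifelse(won, "WIN", "LOSS"))
}
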