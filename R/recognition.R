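# Emotion-recognition harness: stratified 8:2 split, an 11-classifier
# roster, and accuracy aggregation across participant groups and stimulus
# sources.

#' Default classifier roster
#'
#' Eleven commonly used classical classifiers: random forest, k-nearest
#' neighbours, linear and RBF support vector machines, multinomial logistic
#' regression, naive Bayes, a decision tree, gradient boosting, linear and
#' quadratic discriminant analysis, and a single-hidden-layer MLP.
#'
#' @return character vector of 11 classifier names.
#' @export
default_roster <- function() {
  c("random_forest", "knn", "svm_linear", "svm_rbf", "logistic",
    "naive_bayes", "decision_tree", "gradient_boosting", "lda", "qda", "mlp")
}

#' Stratified train/test split
#'
#' Splits epochs into disjoint, exhaustive train and test sets, preserving
#' per-class proportions within rounding; reproducible for a fixed seed.
#'
#' @param labels class label per epoch.
#' @param ratio training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed RNG seed.
#' @param min_per_class smallest admissible class size (default 5).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, ratio = 0.8, seed = 1L, min_per_class = 5L) {
  if (!(ratio > 0 && ratio < 1)) stop_field("ratio", "ratio must lie strictly in (0, 1)")
  tab <- table(labels)
  if (any(tab < min_per_class))
    stop_field("class", sprintf("class '%s' has only %d epochs (need >= %d)",
               names(tab)[which.min(tab)], min(tab), min_per_class))
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_tr <- round(ratio * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

standardize_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = scale(xtr, mu, sdv), test = scale(xte, mu, sdv))
}

train_predict <- function(name, xtr, ytr, xte, seed = 1L) {
  ytr <- factor(ytr)
  set.seed(seed)
  scaled_models <- c("knn", "svm_linear", "svm_rbf", "logistic",
                     "naive_bayes", "lda", "qda", "mlp")
  if (name %in% scaled_models) {
    z <- standardize_train_test(xtr, xte)
    xtr <- z$train; xte <- z$test
  }
  pred <- switch(name,
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
      predict(fit, xte)
    },
    knn = class::knn(xtr, xte, ytr, k = 5),
    svm_linear = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear")
      predict(fit, xte)
    },
    svm_rbf = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial")
      predict(fit, xte)
    },
    logistic = {
      d <- data.frame(y = ytr, xtr)
      fit <- nnet::multinom(y ~ ., data = d, trace = FALSE, MaxNWts = 5000)
      predict(fit, data.frame(xte))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte)
    },
    decision_tree = {
      d <- data.frame(y = ytr, xtr)
      fit <- rpart::rpart(y ~ ., data = d, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         minbucket = 2,
                                                         cp = 0.001))
      predict(fit, data.frame(xte), type = "class")
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(xtr, label = as.integer(ytr) - 1L,
                                     nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = nlevels(ytr),
                      max_depth = 4, eta = 0.3, nthread = 1),
        data = dtrain, nrounds = 60, verbose = 0)
      prob <- predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
      if (!is.matrix(prob))
        prob <- matrix(prob, ncol = nlevels(ytr), byrow = TRUE)
      levels(ytr)[max.col(prob)]
    },
    lda = {
      fit <- MASS::lda(xtr, ytr)
      predict(fit, xte)$class
    },
    qda = {
      fit <- MASS::qda(xtr, ytr)
      predict(fit, xte)$class
    },
    mlp = {
      ymat <- nnet::class.ind(ytr)
      fit <- nnet::nnet(xtr, ymat, size = 8, decay = 0.01, maxit = 200,
                        softmax = TRUE, MaxNWts = 5000, trace = FALSE)
      levels(ytr)[max.col(predict(fit, xte))]
    },
    stop_field("classifier", sprintf("unknown classifier '%s'", name))
  )
  as.character(pred)
}

#' Train and evaluate a roster of classifiers
#'
#' Fits every roster member on the training epochs and reports top-1 test
#' accuracy on the three-class problem. Features are z-standardized with
#' training-set statistics for scale-sensitive classifiers; tree ensembles
#' receive raw features.
#'
#' @param train_x,train_y training feature matrix and labels.
#' @param test_x,test_y test feature matrix and labels.
#' @param roster classifier names (default [default_roster()]).
#' @param seed RNG seed, logged in the result.
#' @return data.frame of class `roster_eval` with `classifier` and
#'   `accuracy` (percent); the best classifier is in `attr(, "best")`.
#' @export
train_evaluate_classifiers <- function(train_x, train_y, test_x, test_y,
                                       roster = default_roster(), seed = 1L) {
  stopifnot(ncol(train_x) == ncol(test_x))
  if (length(unique(train_y)) < 2L)
    stop_field("labels", "degenerate single-class training set")
  acc <- vapply(roster, function(nm) {
    pred <- train_predict(nm, train_x, train_y, test_x, seed = seed)
    100 * mean(pred == as.character(test_y))
  }, numeric(1))
  out <- data.frame(classifier = roster, accuracy = unname(acc),
                    stringsAsFactors = FALSE)
  attr(out, "best") <- out$classifier[which.max(out$accuracy)]
  attr(out, "seed") <- seed
  class(out) <- c("roster_eval", "data.frame")
  out
}

#' @export
print.roster_eval <- function(x, ...) {
  df <- as.data.frame(x)
  df$accuracy <- round_half_up(df$accuracy, 2)
  print(df[order(-df$accuracy), ], row.names = FALSE)
  cat("best:", attr(x, "best"), "\n")
  invisible(x)
}

#' Evaluate one participant group by stimulus source
#'
#' Convenience wrapper: splits a group's epochs per stimulus source
#' (specific / comparison / film), runs a stratified 8:2 split and one
#' classifier, and returns the accuracy per source.
#'
#' @param feats an `epoch_features` object whose epochs carry stimulus ids.
#' @param gender,age_band the participant group (used to classify sources).
#' @param classifier roster member to use (default `"random_forest"`).
#' @param ratio,seed split parameters.
#' @return data.frame with `source` and `accuracy` (percent).
#' @export
evaluate_group_sources <- function(feats, gender, age_band,
                                   classifier = "random_forest",
                                   ratio = 0.8, seed = 1L) {
  src <- vapply(feats$epochs$stimulus_id, classify_source, character(1),
                gender = gender, age_band = age_band)
  out <- lapply(unique(src), function(s) {
    sel <- src == s
    x <- feats$features[sel, , drop = FALSE]
    y <- feats$labels[sel]
    sp <- split_train_test(y, ratio = ratio, seed = seed)
    ev <- train_evaluate_classifiers(x[sp$train, , drop = FALSE], y[sp$train],
                                     x[sp$test, , drop = FALSE], y[sp$test],
                                     roster = classifier, seed = seed)
    data.frame(source = s, accuracy = ev$accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate per-group accuracies into a sources table
#'
#' Builds the groups x sources accuracy matrix and appends the unweighted
#' arithmetic mean of each source column, rounded half-up to 2 decimal
#' places. Aggregation is permutation-invariant over groups.
#'
#' @param reports data.frame with columns `group`, `source`, `accuracy`
#'   (percent), one row per (group, source).
#' @return data.frame: one row per group plus an `"Average accuracy"` row;
#'   one column per source.
#' @export
aggregate_accuracy_table <- function(reports) {
  stopifnot(all(c("group", "source", "accuracy") %in% names(reports)))
  groups <- unique(reports$group)
  sources <- unique(reports$source)
  m <- matrix(NA_real_, length(groups), length(sources),
              dimnames = list(groups, sources))
  for (i in seq_len(nrow(reports)))
    m[reports$group[i], reports$source[i]] <- reports$accuracy[i]
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_field("cell", sprintf("missing accuracy for group '%s', source '%s'",
               groups[idx[1]], sources[idx[2]]))
  }
  out <- as.data.frame(round_half_up(m, 2))
  out$group <- groups
  avg <- as.data.frame(t(round_half_up(colMeans(m), 2)))
  avg$group <- "Average accuracy"
  res <- rbind(out, avg)
  rownames(res) <- NULL
  res[, c("group", sources)]
}
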