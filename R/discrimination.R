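#' Classifier specification for the discrimination bench
#'
#' Fixes the algorithm and its hyperparameters. Defaults: kNN uses k = 5
#' with Euclidean distance; the decision tree uses binary splits with a
#' minimum parent-node size of 10 (Gini impurity, no further pruning); the
#' neural network is a single hidden layer of 10 units trained with a
#' cross-entropy loss; the SVM is a single binary machine (one-versus-one
#' coding collapses to one machine for two classes) with a linear kernel by
#' default; kernel naive Bayes uses Gaussian kernel densities with a
#' normal-reference bandwidth per feature per class; LDA/QDA use empirical
#' class priors and a zero decision threshold.
#'
#' @param algorithm One of `"LDA"`, `"QDA"`, `"NB"`, `"kNB"`, `"kNN"`,
#'   `"SVM"`, `"DT"`, `"ANN"`.
#' @param seed Integer seed controlling any stochastic element of training.
#' @param ... Hyperparameter overrides: `k` (kNN), `min_parent` (DT),
#'   `hidden` and `maxit` (ANN), `kernel` and `cost` (SVM).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("LDA", "QDA", "NB", "kNB", "kNN",
                                          "SVM", "DT", "ANN"),
                            seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    kNN = list(k = 5L),
    DT = list(min_parent = 10L),
    ANN = list(hidden = 10L, maxit = 500L),
    SVM = list(kernel = "linear", cost = 1),
    list())
  hp <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' The default eight-classifier bench
#'
#' @param seed Integer seed shared by all specs.
#' @return Named list of [classifier_spec()] objects (LDA, QDA, NB, kNB,
#'   kNN, SVM, DT, ANN).
#' @export
default_classifiers <- function(seed = 1L) {
  algos <- c("LDA", "QDA", "NB", "kNB", "kNN", "SVM", "DT", "ANN")
  stats::setNames(lapply(algos, classifier_spec, seed = seed), algos)
}

# drop rows with non-finite features; warn once
drop_nonfinite <- function(x, y) {
  ok <- apply(is.finite(as.matrix(x)), 1, all)
  if (!all(ok))
    warning(sprintf("dropping %d rows with non-finite features", sum(!ok)))
  list(x = x[ok, , drop = FALSE], y = y[ok])
}

# z-score with training statistics; zero-variance columns are dropped with a
# warning so covariance-based learners (LDA/QDA) degrade gracefully
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  keep <- sdev > 0
  if (!all(keep))
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  if (!any(keep)) stop("all feature columns are constant")
  list(center = mu[keep], scale = sdev[keep], keep = names(mu)[keep])
}

standardize_apply <- function(x, std) {
  scale(as.matrix(x[, std$keep, drop = FALSE]),
        center = std$center, scale = std$scale)
}

#' Train one classifier on a labeled cohort
#'
#' Features are z-scored with training-split statistics (leak-free); rows
#' with non-finite features are dropped with a warning; both classes must be
#' present. Training is deterministic given `spec$seed`.
#'
#' @param spec A [classifier_spec()].
#' @param cohort Feature tibble with a `state` column (healthy/tumoral).
#' @param features Feature columns (default the five parameters present).
#' @param positive Positive class label (default `"tumoral"`).
#' @return An object of class `pc_classifier` with a [predict][
#'   predict.pc_classifier] method.
#' @export
train_classifier <- function(spec, cohort, features = NULL,
                             positive = "tumoral") {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(features)) features <- intersect(.parameters, names(cohort))
  if (!length(features)) stop("no feature columns found")
  y <- factor(cohort$state, levels = c(setdiff(unique(cohort$state), positive),
                                       positive))
  d <- drop_nonfinite(cohort[, features, drop = FALSE], y)
  if (nlevels(droplevels(d$y)) < 2)
    stop("both classes must be present in the training data")
  std <- standardize_fit(d$x)
  xs <- standardize_apply(d$x, std)
  hp <- spec$hyperparameters
  train_df <- data.frame(xs, y = d$y, check.names = FALSE)
  model <- withr::with_seed(spec$seed, switch(spec$algorithm,
    LDA = MASS::lda(xs, grouping = d$y),
    QDA = MASS::qda(xs, grouping = d$y),
    NB = e1071::naiveBayes(data.frame(xs, check.names = FALSE), d$y),
    kNB = kernel_nb_fit(xs, d$y),
    kNN = list(train = xs, cl = d$y, k = hp$k),
    SVM = e1071::svm(xs, d$y, kernel = hp$kernel, cost = hp$cost,
                     scale = FALSE),
    DT = rpart::rpart(y ~ ., data = train_df, method = "class",
                      control = rpart::rpart.control(minsplit = hp$min_parent,
                                                     cp = 0, xval = 0)),
    # nnet selects the cross-entropy fit automatically for a two-level
    # factor response
    ANN = nnet::nnet(y ~ ., data = train_df, size = hp$hidden,
                     maxit = hp$maxit, trace = FALSE,
                     abstol = 1e-6, MaxNWts = 5000)))
  structure(list(spec = spec, model = model, std = std, features = features,
                 levels = levels(d$y), positive = positive),
            class = "pc_classifier")
}

# Gaussian kernel-density naive Bayes: per-class, per-feature KDE with
# normal-reference bandwidth; log densities summed across features
kernel_nb_fit <- function(x, y) {
  classes <- levels(y)
  dens <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(xc)), function(j) {
      v <- xc[, j]
      bw <- bw.nrd0(v)
      if (!is.finite(bw) || bw <= 0) bw <- 1e-3
      list(values = v, bw = bw)
    })
  })
  names(dens) <- classes
  prior <- table(y) / length(y)
  list(densities = dens, prior = prior, classes = classes)
}

kernel_nb_predict <- function(fit, xnew) {
  loglik <- sapply(fit$classes, function(cl) {
    ll <- rep(log(as.numeric(fit$prior[[cl]])), nrow(xnew))
    for (j in seq_len(ncol(xnew))) {
      d <- fit$densities[[cl]][[j]]
      f <- vapply(xnew[, j],
                  function(q) mean(dnorm(q, mean = d$values, sd = d$bw)),
                  numeric(1))
      ll <- ll + log(pmax(f, 1e-300))
    }
    ll
  })
  factor(fit$classes[max.col(loglik, ties.method = "first")],
         levels = fit$classes)
}

#' Predict class labels with a trained classifier
#'
#' @param object A `pc_classifier` from [train_classifier()].
#' @param newdata Feature tibble (same columns as training).
#' @param ... Unused.
#' @return Factor of predicted states with the training levels.
#' @export
predict.pc_classifier <- function(object, newdata, ...) {
  xs <- standardize_apply(newdata[, object$features, drop = FALSE],
                          object$std)
  m <- object$model
  out <- switch(object$spec$algorithm,
    LDA = predict(m, xs)$class,
    QDA = predict(m, xs)$class,
    NB = predict(m, data.frame(xs, check.names = FALSE)),
    kNB = kernel_nb_predict(m, xs),
    kNN = class::knn(m$train, xs, m$cl, k = m$k, use.all = TRUE),
    SVM = predict(m, xs),
    DT = predict(m, newdata = data.frame(xs, check.names = FALSE),
                 type = "class"),
    ANN = {
      p <- predict(m, newdata = data.frame(xs, check.names = FALSE),
                   type = "raw")
      factor(ifelse(p[, 1] > 0.5, object$levels[2], object$levels[1]),
             levels = object$levels)
    })
  factor(as.character(out), levels = object$levels)
}

#' False-positive / false-negative error decomposition
#'
#' With tumoral as the positive class: the false-positive rate is the
#' fraction of healthy observations classified tumoral, the false-negative
#' rate the fraction of tumoral observations classified healthy. The total
#' error is their sum (so chance-level two-class performance gives a total
#' near 1), sensitivity = 1 - FN and specificity = 1 - FP.
#'
#' @param truth,predicted Factors or character vectors of states.
#' @param positive Positive class label.
#' @return One-row tibble: `fp_rate`, `fn_rate`, `total`, `sensitivity`,
#'   `specificity`.
#' @export
error_rates <- function(truth, predicted, positive = "tumoral") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  neg <- truth != positive
  pos <- truth == positive
  fp <- if (any(neg)) mean(predicted[neg] == positive) else NA_real_
  fn <- if (any(pos)) mean(predicted[pos] != positive) else NA_real_
  tibble(fp_rate = fp, fn_rate = fn, total = fp + fn,
         sensitivity = 1 - fn, specificity = 1 - fp)
}

#' Re-substitution error of one classifier
#'
#' Trains on all rows and predicts the same rows -- the optimistic protocol:
#' useful as a first check, not as a generalization estimate.
#'
#' @inheritParams train_classifier
#' @return One-row tibble of [error_rates()].
#' @export
resubstitution_errors <- function(spec, cohort, features = NULL,
                                  positive = "tumoral") {
  model <- train_classifier(spec, cohort, features, positive)
  pred <- predict(model, cohort)
  error_rates(cohort$state, pred, positive)
}

#' Repeated stratified cross-validation error of one classifier
#'
#' Stratified k-fold cross-validation, repeated with reshuffled fold
#' assignments. Within each repeat the held-out predictions of all folds are
#' pooled into one FP/FN decomposition; rates are then averaged over
#' repeats. The seed controls fold assignment (and any stochastic training),
#' so a rerun with the same spec and seed is identical.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (default 10); reduced with a warning when a
#'   class has fewer members than folds.
#' @param repeats Number of repeats (default 5).
#' @param seed Seed for fold assignment (default: the spec's seed).
#' @return One-row tibble of averaged [error_rates()].
#' @export
cross_validation_errors <- function(spec, cohort, features = NULL,
                                    folds = 10L, repeats = 5L,
                                    positive = "tumoral", seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(seed)) seed <- spec$seed
  min_class <- min(table(cohort$state))
  if (min_class < folds) {
    warning(sprintf("smallest class has %d rows; reducing folds from %d to %d",
                    min_class, folds, min_class))
    folds <- min_class
  }
  if (folds < 2) stop("need at least 2 folds")
  per_repeat <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(nrow(cohort))
      for (cl in unique(cohort$state)) {
        idx <- which(cohort$state == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      pred <- factor(rep(NA_character_, nrow(cohort)))
      for (f in seq_len(folds)) {
        hold <- fold == f
        model <- train_classifier(spec, cohort[!hold, , drop = FALSE],
                                  features, positive)
        p <- predict(model, cohort[hold, , drop = FALSE])
        pred <- factor(replace(as.character(pred), hold, as.character(p)))
      }
      error_rates(cohort$state, pred, positive)
    })
  })
  reps <- dplyr::bind_rows(per_repeat)
  fp <- mean(reps$fp_rate); fn <- mean(reps$fn_rate)
  tibble(fp_rate = fp, fn_rate = fn, total = fp + fn,
         sensitivity = 1 - fn, specificity = 1 - fp)
}

#' Full evaluation report over classifiers, tissues and magnifications
#'
#' For every classifier x tissue x magnification cell with both states
#' present, computes re-substitution and cross-validation FP/FN rates and
#' flags cells with total error (FP + FN) below `flag_threshold`.
#'
#' @param cohort Feature tibble with `tissue`, `state`, `magnification`.
#' @param specs List of [classifier_spec()] (default [default_classifiers()]).
#' @param magnifications Subset of magnifications (default: all present).
#' @param folds,repeats Cross-validation settings.
#' @param flag_threshold Total-error threshold for the `flagged` column
#'   (default 0.1).
#' @inheritParams train_classifier
#' @return Tibble: `classifier`, `tissue`, `magnification`, `error_type`
#'   (`"resub"` / `"cv"`), `fp_rate`, `fn_rate`, `total`, `sensitivity`,
#'   `specificity`, `flagged`. Empty cells are reported as `NA` rows with a
#'   warning.
#' @export
error_report <- function(cohort, specs = default_classifiers(),
                         magnifications = NULL, folds = 10L, repeats = 5L,
                         features = NULL, positive = "tumoral",
                         flag_threshold = 0.1) {
  if (is.null(magnifications))
    magnifications <- sort(unique(cohort$magnification))
  tissues <- sort(unique(cohort$tissue))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$algorithm, character(1))
  rows <- list()
  for (nm in names(specs)) for (ti in tissues) for (mg in magnifications) {
    sub <- cohort[cohort$tissue == ti & cohort$magnification == mg, ]
    key <- tibble(classifier = nm, tissue = ti, magnification = mg)
    if (!nrow(sub) || length(unique(sub$state)) < 2) {
      warning(sprintf("cell %s/%s has no data for both states; left blank",
                      ti, mg))
      blank <- tibble(fp_rate = NA_real_, fn_rate = NA_real_,
                      total = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_)
      rows <- c(rows, list(
        dplyr::bind_cols(key, error_type = "resub", blank),
        dplyr::bind_cols(key, error_type = "cv", blank)))
      next
    }
    resub <- resubstitution_errors(specs[[nm]], sub, features, positive)
    cv <- cross_validation_errors(specs[[nm]], sub, features, folds = folds,
                                  repeats = repeats, positive = positive)
    rows <- c(rows, list(
      dplyr::bind_cols(key, error_type = "resub", resub),
      dplyr::bind_cols(key, error_type = "cv", cv)))
  }
  out <- dplyr::bind_rows(rows)
  out$flagged <- !is.na(out$total) & out$total < flag_threshold
  out
}
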