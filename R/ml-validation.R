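#' Construct leave-n-out cross-validation folds
#'
#' Record-wise folds assign individual records to folds irrespective of
#' subject, so records of one subject can span train and test; subject-wise
#' folds assign whole subjects, so no subject ever spans both sides of a
#' fold. Units are shuffled deterministically per seed and dealt into
#' folds of \code{nLeaveOut} test units (sizes equal within one unit).
#'
#' @param table feature table: data.frame(subject_id, record_id, label,
#'   f1..fk).
#' @param scheme "record-wise" or "subject-wise".
#' @param nLeaveOut test units (records or subjects) per fold.
#' @param seed integer seed.
#' @return a \code{"foldPlan"}: list(scheme, folds = list of list(train,
#'   test) of record_ids, seed). Folds partition all records.
#' @export
makeFolds <- function(table, scheme = c("record-wise", "subject-wise"),
                      nLeaveOut = 1, seed = 1) {
  scheme <- match.arg(scheme)
  units <- if (scheme == "record-wise") unique(table$record_id)
           else unique(table$subject_id)
  if (nLeaveOut >= length(units))
    stop("configuration error: nLeaveOut must be smaller than the number ",
         "of ", if (scheme == "record-wise") "records" else "subjects",
         call. = FALSE)
  set.seed(seed)
  units <- sample(units)
  nf <- ceiling(length(units) / nLeaveOut)
  foldOf <- rep(seq_len(nf), each = nLeaveOut, length.out = length(units))
  folds <- lapply(seq_len(nf), function(f) {
    testUnits <- units[foldOf == f]
    if (scheme == "record-wise") {
      test <- testUnits
    } else {
      test <- table$record_id[table$subject_id %in% testUnits]
    }
    list(train = setdiff(table$record_id, test), test = test)
  })
  structure(list(scheme = scheme, folds = folds, seed = seed),
            class = "foldPlan")
}

#' Reference classifiers
#'
#' Pluggable fit/predict pairs for [crossValidate()]: a nearest-centroid
#' classifier (closed form, hand-checkable) and a ridge-regularized linear
#' classifier (least-squares on +/-1 targets, class-balanced intercept,
#' sign decision). The fit function may accept an optional third argument
#' with per-record subject ids; the ridge classifier uses it to equalize
#' the number of subjects per class before fitting (dropping surplus
#' subjects by sorted id), which removes the below-chance bias that
#' unequal class-mean estimation variance otherwise induces in
#' leave-one-subject-out folds.
#'
#' @param lambda ridge penalty.
#' @param balanceSubjects equalize subjects per class when subject ids are
#'   available.
#' @return list(fit = function(X, y, subjects = NULL), predict =
#'   function(model, X), descriptor).
#' @export
nearestCentroidClassifier <- function() {
  list(
    descriptor = "nearest-centroid",
    fit = function(X, y) {
      lev <- sort(unique(y))
      centroids <- do.call(rbind, lapply(lev, function(l)
        colMeans(X[y == l, , drop = FALSE])))
      list(levels = lev, centroids = centroids)
    },
    predict = function(model, X) {
      d <- vapply(seq_len(nrow(model$centroids)), function(i)
        rowSums(sweep(X, 2, model$centroids[i, ], "-")^2),
        numeric(nrow(X)))
      if (is.null(dim(d))) d <- matrix(d, 1)
      model$levels[max.col(-d, ties.method = "first")]
    }
  )
}

#' @rdname nearestCentroidClassifier
#' @export
ridgeClassifier <- function(lambda = 1, balanceSubjects = TRUE) {
  list(
    descriptor = sprintf("ridge(lambda=%g)", lambda),
    fit = function(X, y, subjects = NULL) {
      if (balanceSubjects && !is.null(subjects)) {
        keep <- balancedSubjectIndex(y, subjects)
        X <- X[keep, , drop = FALSE]
        y <- y[keep]
      }
      lev <- sort(unique(y))
      yy <- ifelse(y == lev[2], 1, -1)
      mu <- colMeans(X)
      Xc <- sweep(X, 2, mu, "-")
      w <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, yy))
      # class-balanced intercept: boundary midway between class score
      # means, so training-set imbalance does not bias held-out subjects
      s <- Xc %*% w
      b <- -(mean(s[yy > 0]) + mean(s[yy < 0])) / 2
      list(levels = lev, w = w, mu = mu, b = b)
    },
    predict = function(model, X) {
      s <- sweep(X, 2, model$mu, "-") %*% model$w + model$b
      model$levels[(s > 0) + 1]
    }
  )
}

# Indices retaining an equal number of subjects per class (surplus
# subjects of the larger class dropped by sorted id; deterministic).
balancedSubjectIndex <- function(y, subjects) {
  bySubj <- tapply(y, subjects, function(v) v[1])
  tab <- table(bySubj)
  if (length(tab) < 2 || tab[1] == tab[2]) return(seq_along(y))
  big <- names(tab)[which.max(tab)]
  surplus <- max(tab) - min(tab)
  bigSubj <- sort(names(bySubj)[bySubj == big])
  drop <- utils::tail(bigSubj, surplus)
  which(!(subjects %in% drop))
}

resolveClassifier <- function(classifier) {
  if (is.list(classifier)) return(classifier)
  switch(classifier,
         "nearest-centroid" = nearestCentroidClassifier(),
         "ridge" = ridgeClassifier(),
         stop("unknown classifier: ", classifier, call. = FALSE))
}

featureMatrix <- function(table) {
  as.matrix(table[, grep("^f[0-9]+$", names(table)), drop = FALSE])
}

#' Cross-validate a classifier over a fold plan
#'
#' Trains on each fold's training records and scores accuracy on its test
#' records; the mean over folds is the reported accuracy. Training folds
#' containing a single class are skipped with a degenerate-fold warning
#' and excluded from the mean (and counted in the result).
#'
#' @param table feature table.
#' @param plan a [makeFolds()] plan consistent with the table.
#' @param classifier "nearest-centroid", "ridge", or a list(fit, predict,
#'   descriptor).
#' @param seed integer seed (recorded; reference classifiers are
#'   deterministic).
#' @return a \code{"cvResult"}: list(per_fold_accuracy, mean_accuracy,
#'   scheme, classifier, seed, skipped_folds).
#' @export
crossValidate <- function(table, plan, classifier = "nearest-centroid",
                          seed = 1) {
  clf <- resolveClassifier(classifier)
  X <- featureMatrix(table)
  y <- as.character(table$label)
  rid <- table$record_id
  acc <- numeric(0)
  skipped <- integer(0)
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    tr <- match(f$train, rid); te <- match(f$test, rid)
    if (length(unique(y[tr])) < 2) {
      warning("degenerate-fold warning: fold ", k,
              " has a single-class training set; skipped")
      skipped <- c(skipped, k)
      next
    }
    model <- if (length(formals(clf$fit)) >= 3)
      clf$fit(X[tr, , drop = FALSE], y[tr], table$subject_id[tr])
    else clf$fit(X[tr, , drop = FALSE], y[tr])
    pred <- clf$predict(model, X[te, , drop = FALSE])
    acc <- c(acc, mean(pred == y[te]))
  }
  structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 scheme = plan$scheme, classifier = clf$descriptor,
                 seed = seed, skipped_folds = skipped),
            class = "cvResult")
}

#' Quantify record-wise vs subject-wise accuracy inflation
#'
#' Runs leave-n-out cross-validation under both fold schemes on identical
#' data and classifier and reports the inflation: record-wise mean
#' accuracy minus subject-wise mean accuracy. With subject-clustered
#' features and no true class effect, record-wise folds leak
#' subject-specific signal into training and inflate accuracy, while
#' subject-wise folds stay at chance.
#'
#' @inheritParams crossValidate
#' @param nLeaveOut records (record-wise) / subjects (subject-wise) per
#'   test fold.
#' @param seed integer seed for both fold plans.
#' @return list(recordWise, subjectWise, inflation).
#' @export
compareSchemes <- function(table, classifier = "ridge", nLeaveOut = 1,
                           seed = 1) {
  rw <- crossValidate(table,
                      makeFolds(table, "record-wise", nLeaveOut, seed),
                      classifier, seed)
  sw <- crossValidate(table,
                      makeFolds(table, "subject-wise", nLeaveOut, seed),
                      classifier, seed)
  list(recordWise = rw, subjectWise = sw,
       inflation = rw$mean_accuracy - sw$mean_accuracy)
}

#' Subject-respecting train/holdout split
#'
#' Sets aside a locked holdout (whole subjects by default) for external
#' validation of a model tuned by cross-validation on the remainder.
#'
#' @param table feature table.
#' @param fraction holdout fraction of units.
#' @param bySubject split whole subjects (TRUE) or records.
#' @param seed integer seed.
#' @return list(train, holdout): two disjoint feature tables.
#' @export
trainHoldoutSplit <- function(table, fraction = 0.2, bySubject = TRUE,
                              seed = 1) {
  set.seed(seed)
  units <- if (bySubject) unique(table$subject_id) else table$record_id
  nHold <- max(1, round(fraction * length(units)))
  hold <- sample(units, nHold)
  inHold <- if (bySubject) table$subject_id %in% hold
            else table$record_id %in% hold
  list(train = table[!inHold, , drop = FALSE],
       holdout = table[inHold, , drop = FALSE])
}
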