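#' RBF-SVM configuration
#'
#' @param cost regularisation weight C > 0 (default 1, the libsvm
#'   convention).
#' @param sigma RBF width; gamma is derived as 1/(2 sigma^2).
#' @param gamma RBF gamma directly (mutually exclusive with \code{sigma});
#'   if neither is given, gamma defaults to 1/p at fit time.
#' @param scale z-score features with training-fold statistics before the
#'   kernel (default TRUE; disable for strict raw-intensity fidelity).
#' @param seed integer seed for any stochastic solver path.
#' @return an [SvmConfig-class].
#' @export
svmConfig <- function(cost = 1, sigma = NULL, gamma = NULL, scale = TRUE,
                      seed = 1L) {
  if (!is.null(sigma) && !is.null(gamma))
    stop("give either sigma or gamma, not both", call. = FALSE)
  if (!is.null(sigma)) {
    if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
    gamma <- 1 / (2 * sigma^2)
  }
  new("SvmConfig", cost = cost,
      gamma = if (is.null(gamma)) NA_real_ else gamma,
      scale = isTRUE(scale), seed = as.integer(seed))
}

setMethod("show", "SvmConfig", function(object) {
  cat(sprintf("SvmConfig: C = %g, gamma = %s, per-fold scaling %s\n",
              object@cost,
              if (is.na(object@gamma)) "1/p (default)" else
                format(object@gamma),
              if (object@scale) "on" else "off"))
})

#' Gaussian radial basis kernel
#'
#' \eqn{K(x_1, x_2) = \exp(-\|x_1 - x_2\|^2 / (2\sigma^2))}: symmetric,
#' in (0, 1], and equal to 1 iff the vectors coincide.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param sigma kernel width > 0.
#' @return similarity in (0, 1].
#' @examples
#' rbfKernel(0, 2, sigma = 1)  # exp(-2)
#' @export
rbfKernel <- function(x1, x2, sigma) {
  if (length(x1) != length(x2))
    stop("vectors must have equal length", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0", call. = FALSE)
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity in percent, with pMCI as the
#' positive class: ACC = (TP+TN)/n, SEN = TP/(TP+FN), SPE = TN/(TN+FP).
#' Values are unrounded; round only for reporting.
#'
#' @param predicted,truth aligned label vectors.
#' @param positive positive-class label (default "pMCI").
#' @return named numeric vector \code{c(acc, sen, spe)} in percent.
#' @examples
#' confusionMetrics(rep(c("pMCI", "sMCI"), c(3, 3)),
#'                  rep(c("pMCI", "sMCI"), c(3, 3)))
#' @export
confusionMetrics <- function(predicted, truth, positive = "pMCI") {
  if (length(predicted) != length(truth))
    stop("predictions and labels must align", call. = FALSE)
  pos <- truth == positive
  if (!any(pos) || all(pos))
    stop("sensitivity/specificity undefined: need both classes in the truth",
         call. = FALSE)
  tp <- sum(predicted == positive & pos)
  fn <- sum(predicted != positive & pos)
  tn <- sum(predicted != positive & !pos)
  fp <- sum(predicted == positive & !pos)
  c(acc = 100 * (tp + tn) / length(truth),
    sen = 100 * tp / (tp + fn),
    spe = 100 * tn / (tn + fp))
}

#' ROC curve and AUC from decision scores
#'
#' Builds the ROC curve by sweeping every distinct score as a threshold
#' (prediction positive when score >= threshold) and integrates it by the
#' trapezoidal rule, which equals the Mann-Whitney concordance statistic
#' with ties counted 1/2. Constant scores give AUC 0.5 with a warning.
#'
#' @param scores per-subject real decision values (larger = more positive).
#' @param labels aligned class labels, both classes present.
#' @param positive positive-class label (default "pMCI").
#' @return list with \code{auc} and \code{roc}, a data.frame of (fpr, tpr)
#'   points from (0, 0) to (1, 1).
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8),
#'        c("sMCI", "sMCI", "pMCI", "pMCI"))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels, positive = "pMCI") {
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("constant decision scores: AUC is 0.5 by convention")
    return(list(auc = 0.5,
                roc = data.frame(fpr = c(0, 1), tpr = c(0, 1))))
  }
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(th) mean(scores[pos] >= th), 0)
  fpr <- vapply(ths, function(th) mean(scores[!pos] >= th), 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

# one training/scoring pass: F-score selection, optional z-scaling and an
# RBF SVM fit on the training rows, then a held-out decision value
fitScoreFold <- function(Xtr, ytr, Xte, k, svm, positive) {
  if (length(unique(ytr)) < 2L)
    stop("a fold's training set lost a class", call. = FALSE)
  fs <- fScore(Xtr, ytr, positive = positive)
  idx <- selectTopK(fs, k)
  Xs <- Xtr[, idx, drop = FALSE]
  Xt <- Xte[, idx, drop = FALSE]
  if (svm@scale) {
    mu <- colMeans(Xs)
    sdv <- apply(Xs, 2, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xs, 2, mu), 2, sdv, "/")
    Xt <- sweep(sweep(Xt, 2, mu), 2, sdv, "/")
  }
  gamma <- if (is.na(svm@gamma)) 1 / ncol(Xs) else svm@gamma
  neg <- setdiff(unique(ytr), positive)
  # the C-classification solver is deterministic; svm@seed is reserved for
  # stochastic solver paths and never touches the caller's RNG stream
  fit <- e1071::svm(Xs, factor(ytr, levels = c(neg, positive)),
                    kernel = "radial", cost = svm@cost, gamma = gamma,
                    scale = FALSE)
  pr <- predict(fit, Xt, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- drop(dv)
  if (!startsWith(colnames(dv)[1L], paste0(positive, "/")))
    score <- -score
  list(predicted = as.character(pr), score = score)
}

#' Leave-one-out RBF-SVM evaluation with per-fold feature selection
#'
#' For each subject in turn: the F-score ranking, the top-k feature choice
#' and (by default) the z-scaling parameters are fit on the remaining n-1
#' subjects only; an RBF SVM is trained on those and the held-out subject
#' is scored and labelled. Summary metrics (ACC/SEN/SPE in percent, AUC and
#' the ROC points) are computed from the n pooled held-out predictions.
#' Deterministic given the inputs and configuration.
#'
#' @param x subjects x features matrix, or a [FeatureSet-class] (optionally
#'   subset with [selectBlocks()] first).
#' @param labels class labels; taken from the FeatureSet when omitted.
#' @param k number of features selected within each fold.
#' @param svm an [SvmConfig-class].
#' @param positive positive-class label (default "pMCI").
#' @return a [CVResult-class].
#' @export
looEvaluate <- function(x, labels = NULL, k, svm = svmConfig(),
                        positive = "pMCI") {
  if (is(x, "FeatureSet")) {
    if (is.null(labels)) labels <- as.character(subjectGroups(x))
    x <- featureMatrix(x)
  }
  labels <- as.character(labels)
  n <- nrow(x)
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 subjects", call. = FALSE)
  if (k > ncol(x)) stop("k exceeds the feature count", call. = FALSE)
  predicted <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fold <- fitScoreFold(x[-i, , drop = FALSE], labels[-i],
                         x[i, , drop = FALSE], k, svm, positive)
    predicted[i] <- fold$predicted
    score[i] <- fold$score
  }
  cm <- confusionMetrics(predicted, labels, positive = positive)
  ra <- rocAuc(score, labels, positive = positive)
  subj <- rownames(x)
  if (is.null(subj)) subj <- sprintf("S%03d", seq_len(n))
  new("CVResult",
      perSubject = data.frame(subject = subj, fold = seq_len(n),
                              score = score, predicted = predicted,
                              truth = labels, stringsAsFactors = FALSE),
      acc = unname(cm["acc"]), sen = unname(cm["sen"]),
      spe = unname(cm["spe"]), auc = ra$auc, roc = ra$roc,
      kUsed = as.integer(k))
}

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d LOO folds, k = %d features/fold\n  ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  AUC %.4f\n",
    nrow(object@perSubject), object@kUsed,
    object@acc, object@sen, object@spe, object@auc))
})

#' Sweep the selected-feature count
#'
#' Runs [looEvaluate()] at every k in \code{kRange} and reports the metric
#' curve together with the argmax-k by accuracy (ties resolved to the
#' smallest k). That argmax uses pooled test-fold performance and is
#' therefore optimistic; for a leakage-safe alternative see
#' [looEvaluateNestedK()].
#'
#' @param x features (matrix or [FeatureSet-class]).
#' @param labels class labels (taken from a FeatureSet when omitted).
#' @param kRange integer vector of feature counts to evaluate.
#' @param svm an [SvmConfig-class].
#' @param positive positive-class label.
#' @return list with \code{curve} (data.frame k/acc/sen/spe/auc),
#'   \code{bestK}, and \code{best} (the [CVResult-class] at bestK).
#' @export
sweepFeatureCount <- function(x, labels = NULL, kRange,
                              svm = svmConfig(), positive = "pMCI") {
  if (length(kRange) == 0L) stop("empty k range", call. = FALSE)
  if (is(x, "FeatureSet")) {
    if (is.null(labels)) labels <- as.character(subjectGroups(x))
    x <- featureMatrix(x)
  }
  kRange <- sort(unique(as.integer(kRange)))
  results <- lapply(kRange, function(k)
    looEvaluate(x, labels, k = k, svm = svm, positive = positive))
  curve <- data.frame(k = kRange,
                      acc = vapply(results, slot, 0, "acc"),
                      sen = vapply(results, slot, 0, "sen"),
                      spe = vapply(results, slot, 0, "spe"),
                      auc = vapply(results, slot, 0, "auc"))
  bestIdx <- which(curve$acc == max(curve$acc))[1L]  # smallest k on ties
  list(curve = curve, bestK = kRange[bestIdx], best = results[[bestIdx]])
}

#' Leakage-safe nested selection of the feature count
#'
#' Within each outer LOO fold, an inner LOO over the training subjects
#' picks the k in \code{kRange} with the best inner accuracy (smallest k on
#' ties); the outer held-out subject is then scored with that k. No
#' test-fold information enters the choice of k.
#'
#' @inheritParams sweepFeatureCount
#' @return list with \code{result} (a [CVResult-class]; \code{kUsed} is the
#'   modal per-fold k) and \code{kPerFold}.
#' @export
looEvaluateNestedK <- function(x, labels = NULL, kRange,
                               svm = svmConfig(), positive = "pMCI") {
  if (length(kRange) == 0L) stop("empty k range", call. = FALSE)
  if (is(x, "FeatureSet")) {
    if (is.null(labels)) labels <- as.character(subjectGroups(x))
    x <- featureMatrix(x)
  }
  labels <- as.character(labels)
  n <- nrow(x)
  kRange <- sort(unique(as.integer(kRange)))
  predicted <- character(n)
  score <- numeric(n)
  kPerFold <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- x[-i, , drop = FALSE]; ytr <- labels[-i]
    innerAcc <- vapply(kRange, function(k)
      looEvaluate(Xtr, ytr, k = k, svm = svm, positive = positive)@acc, 0)
    kPerFold[i] <- kRange[which.max(innerAcc)]
    fold <- fitScoreFold(Xtr, ytr, x[i, , drop = FALSE], kPerFold[i],
                         svm, positive)
    predicted[i] <- fold$predicted
    score[i] <- fold$score
  }
  cm <- confusionMetrics(predicted, labels, positive = positive)
  ra <- rocAuc(score, labels, positive = positive)
  subj <- rownames(x)
  if (is.null(subj)) subj <- sprintf("S%03d", seq_len(n))
  kMode <- as.integer(names(sort(table(kPerFold), decreasing = TRUE))[1L])
  res <- new("CVResult",
             perSubject = data.frame(subject = subj, fold = seq_len(n),
                                     score = score, predicted = predicted,
                                     truth = labels,
                                     stringsAsFactors = FALSE),
             acc = unname(cm["acc"]), sen = unname(cm["sen"]),
             spe = unname(cm["spe"]), auc = ra$auc, roc = ra$roc,
             kUsed = kMode)
  list(result = res, kPerFold = kPerFold)
}
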