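#' F-score feature ranking
#'
#' For each feature i, with class means \eqn{\bar x_i^{(+)}},
#' \eqn{\bar x_i^{(-)}} and overall mean \eqn{\bar x_i} (over all samples),
#' the F-score is
#' \deqn{F(i) = \frac{(\bar x_i^{(+)} - \bar x_i)^2 +
#'   (\bar x_i^{(-)} - \bar x_i)^2}
#'   {\frac{1}{n_+ - 1}\sum_k (x_{k,i}^{(+)} - \bar x_i^{(+)})^2 +
#'    \frac{1}{n_- - 1}\sum_k (x_{k,i}^{(-)} - \bar x_i^{(-)})^2}.}
#' Larger F means better univariate class separation. F is invariant to
#' per-feature affine transforms with nonzero scale. Degenerate features
#' with both within-class variances zero get F = 0 when the class means are
#' equal, and an infinite, flagged F when they differ.
#'
#' @param x numeric matrix, subjects x features, or a [FeatureSet-class].
#' @param labels class labels (ignored for a FeatureSet, which carries its
#'   own groups); exactly two values, each with >= 2 members.
#' @param positive label of the positive class (default "pMCI").
#' @return an [FScoreRanking-class]; the ranking sorts by decreasing F with
#'   ties broken by ascending original feature index.
#' @examples
#' x <- cbind(f1 = c(1, 2, 3, 4, 5, 6))
#' fScore(x, rep(c("pMCI", "sMCI"), each = 3), positive = "pMCI")@F
#' @rdname fScore
#' @export
setMethod("fScore", "matrix", function(x, labels, positive = "pMCI") {
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("labels must match the subject rows", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("labels must take exactly two values", call. = FALSE)
  pos <- labels == positive
  nP <- sum(pos); nN <- sum(!pos)
  if (nP < 2L || nN < 2L)
    stop("both classes need at least 2 members", call. = FALSE)
  mAll <- colMeans(x)
  mP <- colMeans(x[pos, , drop = FALSE])
  mN <- colMeans(x[!pos, , drop = FALSE])
  vP <- colSums((x[pos, , drop = FALSE] -
                   rep(mP, each = nP))^2) / (nP - 1)
  vN <- colSums((x[!pos, , drop = FALSE] -
                   rep(mN, each = nN))^2) / (nN - 1)
  num <- (mP - mAll)^2 + (mN - mAll)^2
  den <- vP + vN
  F <- num / den
  degen <- den == 0
  F[degen & num == 0] <- 0          # constant feature, no separation
  flagged <- which(degen & num > 0) # perfect separation, zero spread
  F[flagged] <- Inf
  names(F) <- colnames(x)
  ranking <- order(-F, seq_along(F))
  new("FScoreRanking", F = F, ranking = as.integer(ranking),
      nPos = nP, nNeg = nN, flagged = as.integer(flagged))
})

#' @rdname fScore
#' @export
setMethod("fScore", "FeatureSet", function(x, labels, positive = "pMCI") {
  fScore(featureMatrix(x), as.character(subjectGroups(x)),
         positive = positive)
})

setMethod("show", "FScoreRanking", function(object) {
  cat(sprintf("FScoreRanking: %d features, classes n+ = %d, n- = %d\n",
              length(object@F), object@nPos, object@nNeg))
  top <- head(object@ranking, 5L)
  cat("  top features:",
      paste(sprintf("%s (F = %.4g)",
                    if (is.null(names(object@F))) top else
                      names(object@F)[top],
                    object@F[top]), collapse = ", "), "\n")
  if (length(object@flagged) > 0L)
    cat("  ", length(object@flagged),
        "degenerate zero-variance feature(s) flagged with infinite F\n")
})

#' Select the top-k ranked features
#'
#' Indices of the k largest F values; ties are broken by ascending original
#' feature index, so selections are deterministic and nested:
#' \code{selectTopK(r, k)} is a prefix of \code{selectTopK(r, k + 1)}.
#'
#' @param result an [FScoreRanking-class].
#' @param k number of features, 1 <= k <= total.
#' @return integer vector of k feature indices.
#' @export
selectTopK <- function(result, k) {
  p <- length(result@F)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > p)
    stop("k must be in 1..", p, call. = FALSE)
  result@ranking[seq_len(as.integer(k))]
}
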