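#' Pooled two-sample t-test from printed summary statistics
#'
#' Computes the equal-variance two-sample t statistic, df = n1 + n2 - 2 and
#' the two-sided p-value directly from group means, SDs and sizes — the
#' form needed to reproduce demographic comparisons from a published table
#' of mean +/- SD summaries. Equals the t of any raw sample having exactly
#' those moments.
#'
#' @param g1,g2 group summaries: numeric vectors or lists with elements
#'   \code{mean}, \code{sd} (>= 0) and \code{n} (>= 2).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' twoSampleTFromSummary(c(mean = 13.9, sd = 5.5, n = 46),
#'                       c(mean = 18.1, sd = 4.0, n = 33))
#' @export
twoSampleTFromSummary <- function(g1, g2) {
  g1 <- as.list(g1); g2 <- as.list(g2)
  for (g in list(g1, g2)) {
    if (g$n < 2) stop("each group needs n >= 2", call. = FALSE)
    if (g$sd < 0) stop("sd must be >= 0", call. = FALSE)
  }
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  if (sp2 == 0) {
    if (g1$mean == g2$mean)
      return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  tstat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' \eqn{\sum (O - E)^2 / E} with expected counts from the margin products,
#' df = 1. No continuity correction by default (the convention that
#' reproduces published gender-balance tests from count tables); set
#' \code{correction = TRUE} for the Yates variant.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = group, cols =
#'   category); all margins must be positive.
#' @param correction apply Yates continuity correction (default FALSE).
#' @return list with \code{chi2}, \code{df} (= 1), \code{p}.
#' @examples
#' chiSquare2x2(matrix(c(31, 15, 24, 9), 2, byrow = TRUE))
#' @export
chiSquare2x2 <- function(tab, correction = FALSE) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive", call. = FALSE)
  ct <- stats::chisq.test(tab, correct = correction)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Demographic comparison table for a cohort
#'
#' Reproduces the standard baseline comparison between the two MCI groups:
#' chi-square on the gender 2x2 table and pooled two-sample t-tests on age
#' and the baseline MMSE and ADAS-cog scores.
#'
#' @param subjects subject table with columns \code{group}, \code{gender},
#'   \code{age}, \code{mmse_bl}, \code{adas_bl}.
#' @param groups the two group labels, first vs second (default sMCI vs
#'   pMCI).
#' @return data.frame, one row per variable with statistic, df and p.
#' @export
cohortStats <- function(subjects, groups = c("sMCI", "pMCI")) {
  s1 <- subjects[subjects$group == groups[1L], ]
  s2 <- subjects[subjects$group == groups[2L], ]
  summ <- function(v) list(mean = mean(v), sd = sd(v), n = length(v))
  rows <- list()
  tab <- rbind(table(factor(s1$gender, levels = c(1, 0))),
               table(factor(s2$gender, levels = c(1, 0))))
  cs <- chiSquare2x2(tab)
  rows[["gender"]] <- data.frame(variable = "gender", test = "chi-square",
                                 statistic = cs$chi2, df = cs$df, p = cs$p)
  for (v in c("age", "mmse_bl", "adas_bl")) {
    tt <- twoSampleTFromSummary(summ(s1[[v]]), summ(s2[[v]]))
    rows[[v]] <- data.frame(variable = v, test = "two-sample t",
                            statistic = tt$t, df = tt$df, p = tt$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
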