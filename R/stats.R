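#' Hierarchical (ROIs-within-flies) mean and SEM
#'
#' Quantified variables are averaged first over all ROIs within a fly, then
#' across flies; the fly is the statistical unit. The result is invariant to
#' duplicating ROIs within a fly.
#'
#' @param values per-ROI values.
#' @param fly fly label per value.
#' @return list: `flyMeans` (named), `mean`, `sem` (`NA` with a `singleFly`
#'   flag when only one fly is present), `nFlies`.
#' @export
hierarchicalMean <- function(values, fly) {
  if (!length(values)) stop("empty input")
  stopifnot(length(values) == length(fly))
  flyMeans <- tapply(values, fly, mean)
  n <- length(flyMeans)
  list(flyMeans = flyMeans, mean = mean(flyMeans),
       sem = if (n > 1) sd(flyMeans) / sqrt(n) else NA_real_,
       nFlies = n, singleFly = n == 1L)
}

lillieforsP <- function(x) {
  if (length(x) < 4L || sd(x) == 0) return(NA_real_)
  nortest::lillie.test(x)$p.value
}

#' Compare an experimental group against two genetic controls
#'
#' Test routing follows the convention of the behavioral statistics: when
#' all groups pass the Lilliefors normality test (p > 0.05), two-tailed
#' unpaired t-tests are used, otherwise Wilcoxon rank-sum tests. The two
#' pairwise p-values (experimental vs each control) are Holm-Bonferroni
#' corrected, and the experimental group is flagged significant only when it
#' differs from BOTH controls at the corrected level.
#'
#' @param experimental,control1,control2 per-fly values (each >= 2).
#' @param alpha significance level.
#' @return a [GroupComparison-class] object.
#' @export
compareToControls <- function(experimental, control1, control2,
                              alpha = 0.05) {
  groups <- list(experimental = experimental, control1 = control1,
                 control2 = control2)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs >= 2 values")
  degenerate <- vapply(groups, function(g) sd(g) == 0, logical(1))
  normP <- vapply(groups, lillieforsP, numeric(1))
  useT <- all(!is.na(normP)) && all(normP > 0.05)
  testFun <- if (useT) {
    function(a, b) t.test(a, b, var.equal = FALSE)$p.value
  } else {
    function(a, b) suppressWarnings(wilcox.test(a, b, exact = FALSE))$p.value
  }
  pRaw <- c(vs_control1 = testFun(experimental, control1),
            vs_control2 = testFun(experimental, control2))
  pCor <- p.adjust(pRaw, method = "holm")
  cmp <- data.frame(pair = names(pRaw), pRaw = unname(pRaw),
                    pCorrected = unname(pCor), stringsAsFactors = FALSE)
  new("GroupComparison", test = if (useT) "t" else "wilcoxon",
      comparisons = cmp, correction = "holm",
      significantVsBoth = all(pCor < alpha), alpha = alpha,
      details = list(normalityP = normP, degenerateGroups = degenerate))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus one-way ANOVA across >= 3 groups, followed by pairwise t-tests
#' with Bonferroni correction.
#'
#' @param groups named list of >= 3 per-fly value vectors.
#' @param alpha significance level.
#' @return a [GroupComparison-class] object; `details` carries the omnibus
#'   `F` and `p`, `significantVsBoth` reports the omnibus decision.
#' @export
anovaBonferroni <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L) stop("need at least 3 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  fit <- aov(values ~ g)
  tab <- anova(fit)
  omniF <- tab$`F value`[1]; omniP <- tab$`Pr(>F)`[1]
  pw <- pairwise.t.test(values, g, p.adjust.method = "none", pool.sd = TRUE)
  praw <- pw$p.value
  pairs <- which(!is.na(praw), arr.ind = TRUE)
  pRaw <- praw[pairs]
  names(pRaw) <- paste(rownames(praw)[pairs[, 1]],
                       colnames(praw)[pairs[, 2]], sep = "_vs_")
  pCor <- pmin(pRaw * length(pRaw), 1)
  cmp <- data.frame(pair = names(pRaw), pRaw = unname(pRaw),
                    pCorrected = unname(pCor), stringsAsFactors = FALSE)
  new("GroupComparison", test = "anova", comparisons = cmp,
      correction = "bonferroni",
      significantVsBoth = !is.na(omniP) && omniP < alpha, alpha = alpha,
      details = list(F = omniF, p = omniP))
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s, %s correction, alpha = %g)\n",
              object@test, object@correction, object@alpha))
  if (!is.null(object@details$p))
    cat(sprintf("  omnibus: F = %.4g, p = %.4g\n", object@details$F,
                object@details$p))
  print(object@comparisons)
  cat("  significant:", object@significantVsBoth, "\n")
})
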