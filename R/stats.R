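# Group comparison layer: Anderson-Darling-gated test selection (t-test /
# one-way ANOVA when all groups look normal, pairwise Kolmogorov-Smirnov
# otherwise), significance stars, and Pearson correlation with line fit.

#' Significance stars for a p value
#'
#' Step function: ns (p >= 0.05), * (< 0.05), ** (< 0.01), *** (< 0.001),
#' **** (< 0.0001).
#'
#' @param p p value(s)
#' @return character vector of star codes
#' @examples
#' significanceStars(c(0.2, 0.03, 0.0002))
#' @export
significanceStars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Compare groups with normality-gated test selection
#'
#' Each group is tested for normality (Anderson-Darling, alpha = 0.05).  If
#' every group passes, a parametric test is used: Welch t-test for two
#' groups, one-way ANOVA for more.  Otherwise the nonparametric
#' Kolmogorov-Smirnov test is applied (pairwise for more than two groups;
#' the reported statistic/p is the largest-statistic pair).
#'
#' @param groups named list of numeric vectors (each n >= 3)
#' @param alpha normality alpha
#' @return list: test_name, statistic, p_value, group_ns, stars, normal
#'   (per-group normality verdicts), pairwise (data.frame for pairwise KS,
#'   else NULL)
#' @export
compareGroups <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- vapply(groups, length, 1L)
  if (any(ns < 3)) stop("every group needs at least n = 3")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  normal <- vapply(groups, function(g) {
    if (length(unique(g)) < 4) return(FALSE)  # AD needs spread
    nortest::ad.test(g)$p.value >= alpha
  }, TRUE)
  pairwise <- NULL
  if (all(normal)) {
    if (length(groups) == 2) {
      tt <- t.test(groups[[1]], groups[[2]])
      test_name <- "t_test"; statistic <- unname(tt$statistic)
      p_value <- tt$p.value
    } else {
      df <- data.frame(v = unlist(groups),
                       g = factor(rep(names(groups), ns)))
      av <- anova(aov(v ~ g, data = df))
      test_name <- "anova"; statistic <- av$`F value`[1]
      p_value <- av$`Pr(>F)`[1]
    }
  } else {
    test_name <- "ks_test"
    prs <- utils::combn(length(groups), 2)
    pw <- apply(prs, 2, function(ij) {
      ks <- suppressWarnings(ks.test(groups[[ij[1]]], groups[[ij[2]]]))
      c(statistic = unname(ks$statistic), p = ks$p.value)
    })
    pairwise <- data.frame(a = names(groups)[prs[1, ]],
                           b = names(groups)[prs[2, ]],
                           statistic = pw["statistic", ],
                           p_value = pw["p", ])
    k <- which.max(pairwise$statistic)
    statistic <- pairwise$statistic[k]
    p_value <- pairwise$p_value[k]
  }
  list(test_name = test_name, statistic = statistic, p_value = p_value,
       group_ns = ns, stars = significanceStars(p_value), normal = normal,
       pairwise = pairwise)
}

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation and the fitted line used to draw it; r is
#' invariant under affine rescaling of either variable.
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance)
#' @return list: r, slope, intercept, n
#' @examples
#' pearsonFit(1:10, 2 * (1:10) + 3)
#' @export
pearsonFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  fit <- lm(y ~ x)
  list(r = unname(cor(x, y)), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = length(x))
}
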