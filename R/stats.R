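## Group statistics: the thin comparison stage over channel-level
## plasticity measures. Welch's unpaired t-test for two groups; two-way
## ANOVA with Sidak- or Tukey-adjusted pairwise post-hoc comparisons for
## group x interval (or group x layer) designs.

#' Welch's unpaired t-test
#'
#' Two-sided unpaired t-test with Welch's correction
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param a,b numeric samples (each n >= 2 with positive variance).
#' @param labelA,labelB group labels for the report.
#' @return one-row data.frame: `comparison`, `statistic` (`welch_t`),
#'   `estimate` (mean difference), `value` (t), `df`, `p_value`,
#'   `adjusted`.
#' @examples
#' welchT(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
welchT <- function(a, b, labelA = "a", labelB = "b") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    ## identical degenerate samples: no evidence of a difference
    return(data.frame(comparison = paste(labelA, "vs", labelB),
                      statistic = "welch_t", estimate = 0, value = 0,
                      df = length(a) + length(b) - 2, p_value = 1,
                      adjusted = FALSE))
  }
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples are degenerate (zero variance)")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(comparison = paste(labelA, "vs", labelB),
             statistic = "welch_t",
             estimate = unname(diff(rev(tt$estimate))),
             value = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, adjusted = FALSE)
}

#' Two-way ANOVA with post-hoc multiple comparisons
#'
#' Fits `response ~ A * B`, reports the omnibus F tests, and runs
#' pairwise comparisons of factor `A` within each level of `B`, adjusted
#' by Sidak's or Tukey's method (via estimated marginal means).
#'
#' @param data data.frame with the response and two factor columns.
#' @param response,factorA,factorB column names.
#' @param method `"sidak"` or `"tukey"`.
#' @return list with `omnibus` (term, df, sum_sq, F, p) and `pairwise`
#'   (contrast, level of B, estimate, p adjusted and raw, method). When
#'   the response has no variance at all, a list with `flag =
#'   "no variance"` is returned instead.
#' @export
twoWayAnovaPosthoc <- function(data, response, factorA, factorB,
                               method = c("sidak", "tukey")) {
  method <- match.arg(method)
  stopifnot(all(c(response, factorA, factorB) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factorA]]), B = factor(data[[factorB]]))
  d <- d[is.finite(d$y), ]
  if (nlevels(droplevels(d$A)) < 2L || nlevels(droplevels(d$B)) < 2L)
    stop("need at least 2 levels per factor")
  cellN <- table(d$A, d$B)
  if (any(cellN == 0L))
    stop(sprintf("empty design cell: %s",
                 paste(which(cellN == 0L, arr.ind = TRUE)[1L, ],
                       collapse = " x ")))
  if (stats::var(d$y) == 0)
    return(list(flag = "no variance", omnibus = NULL, pairwise = NULL))
  fit <- stats::aov(y ~ A * B, data = d)
  sm <- summary(fit)[[1L]]
  omnibus <- data.frame(term = trimws(rownames(sm)),
                        df = sm$Df, sum_sq = sm$`Sum Sq`,
                        F = sm$`F value`, p_value = sm$`Pr(>F)`)
  emm <- emmeans::emmeans(fit, specs = "A", by = "B")
  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = method))
  pwRaw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "none"))
  pairwise <- data.frame(contrast = as.character(pw$contrast),
                         B = as.character(pw$B),
                         estimate = pw$estimate, se = pw$SE, df = pw$df,
                         p_adjusted = pw$p.value,
                         p_raw = pwRaw$p.value,
                         method = method)
  names(pairwise)[names(pairwise) == "B"] <- factorB
  list(omnibus = omnibus, pairwise = pairwise)
}
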