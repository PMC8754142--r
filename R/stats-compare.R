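#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' The study's group comparison for biomass at chosen regrowth time points:
#' a one-way analysis of variance across culture types (or weeks), followed
#' by Tukey honestly-significant-difference tests for every pair, with
#' adjusted p values from the studentized-range distribution. The degenerate
#' case of zero variance everywhere with equal means is reported as "no
#' difference" (all adjusted p = 1) rather than NaN.
#'
#' @param data data frame with a `group` column (factor or character) and a
#'   `value` column (biomass in cells, or lag in hours).
#' @return List with `anova` (one row: `f`, `df_between`, `df_within`, `p`)
#'   and `tukey` (one row per pair: `pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @examples
#' d <- data.frame(group = rep(c("Q", "NQ", "mixed"), each = 4),
#'                 value = c(rnorm(4, 10), rnorm(4, 12), rnorm(4, 11)))
#' anova_tukey(d)
#' @export
anova_tukey <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("group", "value") %in% names(data))) {
    stop("need 'group' and 'value' columns", call. = FALSE)
  }
  data$group <- factor(data$group)
  counts <- table(data$group)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L)) stop("every group needs at least 2 replicates",
                             call. = FALSE)

  pairs <- utils::combn(levels(data$group), 2L)
  pair_labels <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  group_means <- tapply(data$value, data$group, mean)
  diffs <- group_means[pairs[2L, ]] - group_means[pairs[1L, ]]

  if (stats::var(data$value) == 0) {
    # all observations identical: no evidence of any difference
    return(list(
      anova = data.frame(f = NA_real_, df_between = length(counts) - 1L,
                         df_within = nrow(data) - length(counts), p = 1),
      tukey = data.frame(pair = pair_labels, diff = as.numeric(diffs),
                         lwr = 0, upr = 0, p_adj = 1)))
  }

  fit <- aov(value ~ group, data = data)
  tab <- summary(fit)[[1L]]
  hsd <- TukeyHSD(fit)$group
  # TukeyHSD orders pairs as combn does, labelled "b-a"
  list(
    anova = data.frame(f = tab[["F value"]][1L],
                       df_between = tab[["Df"]][1L],
                       df_within = tab[["Df"]][2L],
                       p = tab[["Pr(>F)"]][1L]),
    tukey = data.frame(pair = rownames(hsd),
                       diff = hsd[, "diff"],
                       lwr = hsd[, "lwr"],
                       upr = hsd[, "upr"],
                       p_adj = hsd[, "p adj"],
                       row.names = NULL))
}

#' Two-sided t test on lag lengths
#'
#' Compares lag-phase lengths (or any two replicate samples) with a
#' two-sample, two-sided t test. Welch's unequal-variance form is the
#' default; `var_equal = TRUE` gives the pooled-variance test. `NA` values
#' (unobserved lags) are dropped and counted. When both samples are constant
#' the test statistic is undefined; equal constants are reported as t = 0,
#' p = 1 and different constants as infinite t, p = 0.
#'
#' @param a,b numeric vectors, at least 2 non-missing values each.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return Data frame with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `n_dropped`.
#' @examples
#' compare_lags_ttest(c(1.5, 1.6, 1.4), c(2.1, 2.3, 2.2))
#' @export
compare_lags_ttest <- function(a, b, var_equal = FALSE) {
  n_dropped <- sum(is.na(a)) + sum(is.na(b))
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observed values", call. = FALSE)
  }
  base <- data.frame(mean_a = mean(a), mean_b = mean(b),
                     n_a = length(a), n_b = length(b),
                     n_dropped = n_dropped)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(cbind(data.frame(t = 0, df = length(a) + length(b) - 2L, p = 1),
                   base))
    }
    return(cbind(data.frame(t = sign(mean(a) - mean(b)) * Inf,
                            df = length(a) + length(b) - 2L, p = 0),
                 base))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  cbind(data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value), base)
}
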