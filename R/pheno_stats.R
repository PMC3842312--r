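# Phenotype-level statistics: Shapiro-Wilk normality gating, median-split
# dichotomization, and Bonferroni-corrected directed NEO comparisons.

#' NEO measures used throughout, with the hypothesised direction for the
#' high-Ekappa group (-1 = lower, +1 = higher)
#' @export
NEO_DIRECTIONS <- c(neuroticism = -1, extraversion = 1, agreeableness = 1,
                    warmth = 1, positive_emotion = 1, tender_mindedness = 1)

#' Normality gate: regression vs. dichotomization
#'
#' Shapiro-Wilk test of normality; variables that do not deviate from
#' normality (p >= 0.05) are analysed by regression, deviating ones are
#' dichotomized by median split.
#'
#' @param values numeric vector, n >= 8, not constant.
#' @return a `gate_decision`: `shapiro_p`, `decision` ("regression" or
#'   "dichotomize").
#' @export
normality_gate <- function(values) {
  stop_if(length(values) < 8, "need at least 8 values")
  stop_if(sd(values) == 0, "constant input")
  p <- shapiro.test(values)$p.value
  structure(list(shapiro_p = p,
                 decision = if (p >= 0.05) "regression" else "dichotomize"),
            class = "gate_decision")
}

#' Median-split dichotomization
#'
#' Values strictly above the sample median are labelled "high", all others
#' (strictly below, or tied with the median) "low". With an even number of
#' distinct values this yields equal halves.
#'
#' @param values numeric vector (>= 3 values, not all equal).
#' @return factor with levels "low", "high", one label per input value.
#' @export
median_split <- function(values) {
  stop_if(length(values) < 3, "need at least 3 values")
  stop_if(max(values) == min(values), "all values equal")
  med <- median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Directed NEO group comparisons with Bonferroni correction
#'
#' For each of the six NEO measures, a one-sided two-sample t test of the
#' high- vs. low-Ekappa group in the hypothesised direction (lower
#' neuroticism, higher extraversion, agreeableness, warmth, positive
#' emotion and tender-mindedness in the high group). The corrected
#' one-sided significance level is `alpha / 6 * 2` (0.017 at alpha = .05).
#'
#' @param pheno data.frame with the six NEO columns (see
#'   [NEO_DIRECTIONS]).
#' @param labels factor from [median_split()] (levels "low", "high").
#' @param alpha nominal familywise level (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame: measure, direction, t, df, p_one_sided,
#'   alpha_corrected, significant.
#' @export
compare_neo_groups <- function(pheno, labels, alpha = 0.05,
                               var_equal = TRUE) {
  measures <- names(NEO_DIRECTIONS)
  missing_cols <- setdiff(measures, names(pheno))
  stop_if(length(missing_cols) > 0,
          paste("missing NEO columns:", paste(missing_cols, collapse = ", ")))
  labels <- factor(labels, levels = c("low", "high"))
  stop_if(any(table(labels) < 2), "both groups need at least 2 subjects")
  bad <- !stats::complete.cases(pheno[measures])
  stop_if(any(bad), paste("missing scores for subjects:",
                          paste(which(bad), collapse = ", ")))
  alpha_corr <- alpha / 6 * 2
  rows <- lapply(measures, function(m) {
    dir <- NEO_DIRECTIONS[[m]]
    alt <- if (dir > 0) "greater" else "less"
    tt <- t.test(pheno[[m]][labels == "high"], pheno[[m]][labels == "low"],
                 alternative = alt, var.equal = var_equal)
    data.frame(measure = m, direction = if (dir > 0) "high>low" else "high<low",
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_one_sided = tt$p.value, alpha_corrected = alpha_corr,
               significant = tt$p.value < alpha_corr)
  })
  do.call(rbind, rows)
}
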