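# Group-level comparison of per-volume metrics: one-way ANOVA with Tukey's
# HSD post hoc test, the muscle volume being the unit of analysis.

#' Compare a metric across muscle groups
#'
#' One-way analysis of variance over per-volume metric values followed by
#' Tukey's honestly-significant-difference post hoc test, with group means
#' and standard errors (SD / sqrt(n), n = volumes per group).
#'
#' @param values Numeric vector of per-volume metric values.
#' @param groups Factor or character vector of group labels, same length.
#' @param alpha Family-wise significance level for flagging pairs.
#' @return A `myo_group_comparison`: list with `summary` (per-group n, mean,
#'   se), `F`, `df`, `p_value`, `tukey` (pairwise differences, confidence
#'   bounds, adjusted p, significance flag) and `alpha`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups)) stop_myo("values and groups differ in length")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups[ok]))
  n_per <- table(groups)
  if (nlevels(groups) < 2L) stop_myo("need at least 2 groups, got %d", nlevels(groups))
  if (any(n_per < 2L)) {
    stop_myo("singleton group(s): %s — each group needs >= 2 volumes for inference",
             paste(names(n_per)[n_per < 2L], collapse = ", "))
  }
  wvar <- tapply(values, groups, stats::var)
  if (all(wvar == 0)) {
    stop_myo("all groups have zero within-group variance; ANOVA is undefined")
  }

  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  Fval <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tukey <- data.frame(
    pair = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE
  )
  rownames(tukey) <- NULL

  summary_tab <- data.frame(
    group = levels(groups),
    n = as.integer(n_per),
    mean = as.numeric(tapply(values, groups, mean)),
    se = as.numeric(tapply(values, groups, stats::sd)) / sqrt(as.integer(n_per)),
    stringsAsFactors = FALSE
  )
  structure(list(
    summary = summary_tab,
    F = Fval, df = c(an[["Df"]][1L], an[["Df"]][2L]),
    p_value = pval, tukey = tukey, alpha = alpha
  ), class = "myo_group_comparison")
}

#' @export
print.myo_group_comparison <- function(x, ...) {
  cat("<myo_group_comparison> one-way ANOVA + Tukey HSD\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g (alpha = %g)\n",
              x$df[1L], x$df[2L], x$F, x$p_value, x$alpha))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-16s n = %d, mean = %.3f +/- %.3f (SE)\n",
                x$summary$group[i], x$summary$n[i], x$summary$mean[i], x$summary$se[i]))
  }
  sig <- x$tukey[x$tukey$significant, ]
  if (nrow(sig) > 0L) {
    cat("  significant pairs:", paste(sig$pair, collapse = ", "), "\n")
  } else {
    cat("  no significant pairwise differences\n")
  }
  invisible(x)
}
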