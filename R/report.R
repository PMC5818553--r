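#' Grouped summary of a kinetics table
#'
#' Aggregates a measurement column by grouping keys at two grains: bouton
#' grain pools all boutons; NMJ grain first averages boutons within each
#' terminal, then summarizes across NMJs. Cells report mean, SD, SEM, n
#' (boutons) and N (NMJs), the "value +/- SD (n, N)" convention.
#'
#' @param ktab Data frame (e.g. from [kinetics_table()]) with an
#'   \code{nmj_id} column.
#' @param value Name of the measurement column.
#' @param by Character vector of grouping columns (e.g. \code{c("type",
#'   "frequency_hz")}).
#' @param na_rm Drop NA measurements (censored values) before averaging.
#' @return Data frame of class \code{grouped_summary} with one row per
#'   group per grain.
#' @export
aggregate_kinetics <- function(ktab, value = "max_dff",
                               by = c("type", "frequency_hz"),
                               na_rm = TRUE) {
  stopifnot(value %in% names(ktab), all(by %in% names(ktab)),
            "nmj_id" %in% names(ktab), nrow(ktab) > 0)
  if (na_rm) ktab <- ktab[!is.na(ktab[[value]]), , drop = FALSE]
  key <- interaction(ktab[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(ktab, key), function(d) {
    v <- d[[value]]
    nmj_means <- tapply(v, d$nmj_id, mean)
    base <- d[1, by, drop = FALSE]
    rbind(
      cbind(base, data.frame(grain = "bouton", mean = mean(v),
                             sd = stats::sd(v),
                             sem = stats::sd(v) / sqrt(length(v)),
                             n = length(v), N = length(nmj_means))),
      cbind(base, data.frame(grain = "NMJ", mean = mean(nmj_means),
                             sd = stats::sd(nmj_means),
                             sem = stats::sd(nmj_means) /
                               sqrt(length(nmj_means)),
                             n = length(v), N = length(nmj_means))))
  }))
  rownames(out) <- NULL
  class(out) <- c("grouped_summary", "data.frame")
  out
}

#' Bonferroni adjustment
#'
#' @param p Raw p value(s).
#' @param m Number of comparisons in the declared family.
#' @return \code{pmin(1, p * m)}.
#' @export
bonferroni_adjust <- function(p, m) pmin(1, p * m)

#' Significance stars
#'
#' @param p Adjusted p value(s).
#' @return "***" below 0.001, "**" below 0.01, "*" below 0.05, "" otherwise.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Run a family of group comparisons
#'
#' Delegates the base statistic to standard routines — Kruskal-Wallis
#' (\code{kruskal.test}), Student's t (\code{t.test}), or one-way ANOVA
#' followed by Fisher's LSD (pairwise t tests on the pooled residual
#' variance, unadjusted) — and applies a Bonferroni correction across the
#' declared comparison family (adjusted p = min(1, m x raw p), m = number
#' of comparisons).
#'
#' @param data Data frame with a \code{value} column and a \code{group}
#'   column.
#' @param comparisons List of length-2 character vectors naming the group
#'   pairs in the family; for \code{kruskal_wallis_bonferroni} and
#'   \code{anova_fisher_lsd} the omnibus test uses all groups present and
#'   the pairs are tested post hoc.
#' @param test One of "kruskal_wallis_bonferroni", "t_test",
#'   "t_test_bonferroni", "anova_fisher_lsd".
#' @param value,group Column names.
#' @return Data frame of class \code{test_result}: comparison, raw p,
#'   adjusted p, stars, test, plus any omnibus p as an attribute.
#'   Degenerate comparisons (a group with fewer than 2 observations) are
#'   skipped with a reason.
#' @export
run_group_tests <- function(data, comparisons,
                            test = c("kruskal_wallis_bonferroni", "t_test",
                                     "t_test_bonferroni",
                                     "anova_fisher_lsd"),
                            value = "value", group = "group") {
  test <- match.arg(test)
  stopifnot(value %in% names(data), group %in% names(data))
  v <- data[[value]]; g <- as.character(data[[group]])
  m <- length(comparisons)
  adjust <- test %in% c("kruskal_wallis_bonferroni", "t_test_bonferroni")

  omnibus_p <- NA_real_
  pooled <- NULL
  if (test == "anova_fisher_lsd") {
    fit <- stats::aov(v ~ factor(g))
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pooled <- list(mse = stats::deviance(fit) / stats::df.residual(fit),
                   df = stats::df.residual(fit))
  } else if (test == "kruskal_wallis_bonferroni") {
    omnibus_p <- stats::kruskal.test(v, factor(g))$p.value
  }

  rows <- lapply(comparisons, function(cmp) {
    a <- v[g == cmp[1]]; b <- v[g == cmp[2]]
    lbl <- paste(cmp, collapse = " vs ")
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(comparison = lbl, p_raw = NA_real_,
                        p_adjusted = NA_real_, stars = "",
                        skipped = "group with < 2 observations"))
    p <- switch(test,
      t_test = , t_test_bonferroni = stats::t.test(a, b)$p.value,
      kruskal_wallis_bonferroni =
        stats::kruskal.test(list(a, b))$p.value,
      anova_fisher_lsd = {
        # Fisher's LSD: t on the pooled ANOVA residual variance
        se <- sqrt(pooled$mse * (1 / length(a) + 1 / length(b)))
        2 * stats::pt(-abs((mean(a) - mean(b)) / se), pooled$df)
      })
    padj <- if (adjust) bonferroni_adjust(p, m) else p
    data.frame(comparison = lbl, p_raw = p, p_adjusted = padj,
               stars = signif_stars(padj), skipped = "")
  })
  out <- do.call(rbind, rows)
  out$test <- test
  attr(out, "omnibus_p") <- omnibus_p
  attr(out, "n_comparisons") <- m
  class(out) <- c("test_result", "data.frame")
  out
}

#' Render a grouped summary as formatted table cells
#'
#' Machine CSV plus the human convention "mean +/- SD (n, N)", 2 decimals,
#' with significance stars appended when a matching test result is given.
#'
#' @param summary A \code{grouped_summary} (one grain).
#' @param tests Optional \code{test_result}; stars of a comparison whose
#'   label contains the group's first key value are appended.
#' @param digits Decimals for the human cells.
#' @return The summary data frame with an added \code{cell} column.
#' @export
render_tables <- function(summary, tests = NULL, digits = 2) {
  cells <- sprintf(paste0("%.", digits, "f ± %.", digits, "f (%d, %d)"),
                   summary$mean, summary$sd, summary$n, summary$N)
  if (!is.null(tests) && nrow(tests) > 0) {
    keycol <- names(summary)[1]
    for (i in seq_len(nrow(summary))) {
      hit <- grepl(as.character(summary[[keycol]][i]), tests$comparison,
                   fixed = TRUE)
      if (any(hit) && any(tests$stars[hit] != ""))
        cells[i] <- paste0(cells[i], tests$stars[hit][tests$stars[hit] != ""][1])
    }
  }
  summary$cell <- cells
  summary
}
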