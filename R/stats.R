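#' Correlation and simple linear regression between an index and a covariate
#'
#' Computes Pearson's r (optionally on log10 of `y`, for indices analyzed on a
#' log scale), Spearman's rank correlation with average-rank tie handling, and
#' an ordinary least-squares fit with its coefficient of determination and 95%
#' confidence band of the mean response.
#'
#' @param x numeric covariate (e.g. tissue fraction in percent).
#' @param y numeric response (e.g. E_low); must be positive when
#'   `log_y = TRUE`.
#' @param log_y analyze `log10(y)` (default `FALSE`).
#' @return An object of class `correlation_result`: list with `r`, `r_s`,
#'   `r2`, `slope`, `intercept`, `ci_band` (data frame `x`, `fit`, `lwr`,
#'   `upr`), `n`, `p_pearson`, `p_spearman`, `log_y`.
#' @export
correlate <- function(x, y, log_y = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    abort_lungfot("need at least 3 paired observations", "lungfot_stats_error")
  if (log_y) {
    if (any(y <= 0))
      abort_lungfot("log scale requires positive y", "lungfot_stats_error")
    yy <- log10(y)
  } else yy <- y
  if (stats::sd(x) == 0 || stats::sd(yy) == 0)
    abort_lungfot("zero variance in x or y", "lungfot_stats_error")
  pe <- stats::cor.test(x, yy, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  fit <- stats::lm(yy ~ x)
  xs <- seq(min(x), max(x), length.out = 50)
  band <- stats::predict(fit, newdata = data.frame(x = xs),
                         interval = "confidence", level = 0.95)
  structure(list(r = unname(pe$estimate), r_s = unname(sp$estimate),
                 r2 = summary(fit)$r.squared,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci_band = data.frame(x = xs, fit = band[, "fit"],
                                      lwr = band[, "lwr"], upr = band[, "upr"]),
                 n = length(x), p_pearson = pe$p.value, p_spearman = sp$p.value,
                 log_y = log_y),
            class = "correlation_result")
}

#' Factorial group comparison with Bonferroni or Tukey-Kramer adjustment
#'
#' Two-factor path: F tests for both main effects and their interaction
#' (Type-II sums of squares, appropriate for the unbalanced group sizes),
#' plus Bonferroni-adjusted pairwise comparisons of the first factor's levels.
#' One-factor path: one-way ANOVA with Tukey-Kramer post hoc contrasts
#' (studentized-range based, valid for unequal group sizes).
#'
#' @param data a data frame.
#' @param response name of the response column.
#' @param factors character vector of one or two factor column names. The
#'   first factor is the grouping of primary interest (pairwise comparisons
#'   are computed for its levels).
#' @param method post hoc adjustment for the one-way path or the pairwise
#'   comparisons: `"bonferroni"` (default for two factors) or `"tukey"`
#'   (default for one factor).
#' @param block optional name of a subject/block column for repeated-measures
#'   layouts in which the second factor varies within subject (e.g. frequency
#'   or PEEP measured repeatedly on each animal). The first factor is then
#'   tested against between-subject variation and the second factor and the
#'   interaction against within-subject variation (split-plot strata).
#' @return An object of class `group_comparison`: list with `anova_table`
#'   (factor effects and F statistics), `pairwise` (data frame with raw and
#'   adjusted p-values), `group_stats` (mean and sample SD per level of the
#'   first factor), `method`.
#' @export
compare_groups <- function(data, response, factors,
                           method = if (length(factors) == 1) "tukey"
                                    else "bonferroni",
                           block = NULL) {
  stopifnot(length(factors) %in% 1:2,
            all(c(response, factors, block) %in% names(data)))
  d <- data
  for (f in c(factors, block)) d[[f]] <- factor(d[[f]])
  y <- d[[response]]

  if (length(factors) == 2 && !is.null(block)) {
    form <- stats::as.formula(paste(
      response, "~", factors[1], "*", factors[2], "+ Error(", block, ")"))
    fit <- stats::aov(form, data = d)
    anova_table <- do.call(rbind, lapply(summary(fit), function(stratum) {
      an <- stratum[[1]]
      data.frame(term = trimws(rownames(an)),
                 sum_sq = an[["Sum Sq"]], df = an[["Df"]],
                 F_value = an[["F value"]], p = an[["Pr(>F)"]],
                 stringsAsFactors = FALSE)
    }))
    rownames(anova_table) <- NULL
    anova_table <- anova_table[anova_table$term != "Residuals", ]
  } else if (length(factors) == 2) {
    n_cell <- table(d[[factors[1]]], d[[factors[2]]])
    if (any(n_cell < 1))
      abort_lungfot("every factor-level cell needs at least one observation",
                    "lungfot_stats_error")
    form <- stats::as.formula(
      paste(response, "~", factors[1], "*", factors[2]))
    fit <- stats::lm(form, data = d)
    an <- car::Anova(fit, type = 2)
    anova_table <- data.frame(term = rownames(an),
                              sum_sq = an[["Sum Sq"]], df = an[["Df"]],
                              F_value = an[["F value"]], p = an[["Pr(>F)"]],
                              stringsAsFactors = FALSE)
  } else {
    form <- stats::as.formula(paste(response, "~", factors[1]))
    fit <- stats::aov(form, data = d)
    an <- summary(fit)[[1]]
    anova_table <- data.frame(term = trimws(rownames(an)),
                              sum_sq = an[["Sum Sq"]], df = an[["Df"]],
                              F_value = an[["F value"]], p = an[["Pr(>F)"]],
                              stringsAsFactors = FALSE)
  }

  f1 <- d[[factors[1]]]
  if (method == "tukey") {
    if (length(factors) == 1) {
      tk <- stats::TukeyHSD(fit)[[factors[1]]]
    } else {
      tk <- stats::TukeyHSD(stats::aov(
        stats::as.formula(paste(response, "~", factors[1])), data = d))[[factors[1]]]
    }
    pairwise <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                           p_adj = tk[, "p adj"], row.names = NULL,
                           stringsAsFactors = FALSE)
  } else {
    lev <- levels(f1)
    cmb <- utils::combn(lev, 2)
    raw <- apply(cmb, 2, function(pair) {
      stats::t.test(y[f1 == pair[1]], y[f1 == pair[2]],
                    var.equal = TRUE)$p.value
    })
    diffs <- apply(cmb, 2, function(pair)
      mean(y[f1 == pair[2]]) - mean(y[f1 == pair[1]]))
    pairwise <- data.frame(
      contrast = paste(cmb[2, ], cmb[1, ], sep = "-"), diff = diffs,
      p_raw = raw, p_adj = stats::p.adjust(raw, "bonferroni"),
      stringsAsFactors = FALSE)
  }

  gs <- do.call(rbind, lapply(split(y, f1), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  gs <- cbind(level = rownames(gs), gs)
  rownames(gs) <- NULL

  structure(list(anova_table = anova_table, pairwise = pairwise,
                 group_stats = gs, method = method),
            class = "group_comparison")
}

#' Correlation between ordinal rejection grade and a heterogeneity index
#'
#' Grades are encoded ordinally (A0 = 0, A1 = 1, A2 = 2, A3 = 3). Pearson's r
#' is computed against log10 of the index (the index is analyzed on a log
#' scale); Spearman's rank correlation is computed on the raw index, making it
#' invariant to any strictly monotone transform.
#'
#' @param index_table data frame with columns `grade_num` and the index column.
#' @param index name of the index column (default `"E_het"`).
#' @return A `correlation_result` (see [correlate()]), with `r` from the
#'   log10 index and `r_s` from the raw index.
#' @export
grade_correlation <- function(index_table, index = "E_het") {
  stopifnot(all(c("grade_num", index) %in% names(index_table)))
  g <- index_table$grade_num
  v <- index_table[[index]]
  if (length(unique(g)) < 2)
    abort_lungfot("need at least two distinct grades", "lungfot_stats_error")
  if (any(v <= 0))
    abort_lungfot("index must be positive for log-scale correlation",
                  "lungfot_stats_error")
  correlate(g, v, log_y = TRUE)
}
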