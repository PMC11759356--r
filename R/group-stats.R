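#' Two-way ANCOVA of a value against group and a covariate
#'
#' Fits `value ~ group + covariate + group:covariate` and reports F-tests
#' for the main effect of group, the main effect of the covariate, and
#' the interaction, using Type II sums of squares by default (main
#' effects adjusted for each other; appropriate for unbalanced groups;
#' Type I is available for strict sequential decomposition). Per-group R
#' squared is the squared Pearson correlation of value and covariate
#' within each group. Uncorrected p-values are reported together with the
#' Bonferroni family-wise threshold for annotation when `n_family` is
#' given; they are not re-thresholded silently.
#'
#' @param data Data frame containing the analysis columns.
#' @param value,group,covariate Column names (strings).
#' @param ss_type 2 (default) or 1.
#' @param n_family Optional family size for the annotated FWE threshold.
#' @param alpha Family-wise level for the annotation (default 0.05).
#' @return One-row tibble: `value`, `covariate`, `p_group`, `p_covariate`,
#'   `p_interaction`, F statistics, per-group R2 (`R2_<group>`), group
#'   means and sems, `fwe_threshold` (NA when no family given), `flag`.
#' @export
ancova <- function(data, value, group, covariate, ss_type = 2,
                   n_family = NULL, alpha = 0.05) {
  abort_if(!all(c(value, group, covariate) %in% names(data)),
           "value, group and covariate must name columns of data")
  d <- data.frame(y = data[[value]], g = factor(data[[group]]),
                  x = data[[covariate]])
  abort_if(any(!is.finite(d$y)) || any(!is.finite(d$x)),
           "value and covariate must be finite")
  lv <- levels(d$g)
  abort_if(length(lv) != 2, "group must have exactly 2 levels")
  abort_if(any(table(d$g) < 3), "need >= 3 observations per group")

  flag <- ""
  sing <- vapply(lv, function(l) var(d$x[d$g == l]) == 0, logical(1))
  if (any(sing)) flag <- "constant covariate within a group"

  fit <- lm(y ~ g * x, data = d)
  tab <- anova_table(fit, ss_type)
  pick <- function(term, col) {
    i <- match(term, rownames(tab))
    if (is.na(i)) NA_real_ else tab[i, col]
  }
  p_int <- pick("g:x", "p")
  if (any(sing)) p_int <- NA_real_

  r2 <- vapply(lv, function(l) {
    xs <- d$x[d$g == l]; ys <- d$y[d$g == l]
    if (var(xs) == 0 || var(ys) == 0) return(NA_real_)
    cor(xs, ys)^2
  }, numeric(1))
  means <- vapply(lv, function(l) mean(d$y[d$g == l]), numeric(1))
  sems <- vapply(lv, function(l) {
    yy <- d$y[d$g == l]; sd(yy) / sqrt(length(yy))
  }, numeric(1))

  out <- tibble::tibble(
    value = value, covariate = covariate,
    p_group = pick("g", "p"), p_covariate = pick("x", "p"),
    p_interaction = p_int,
    F_group = pick("g", "F"), F_covariate = pick("x", "F"),
    F_interaction = if (any(sing)) NA_real_ else pick("g:x", "F"),
    fwe_threshold = if (is.null(n_family)) NA_real_
                    else fwe_threshold(alpha, n_family),
    flag = flag
  )
  for (i in seq_along(lv)) {
    out[[paste0("R2_", lv[i])]] <- unname(r2[i])
    out[[paste0("mean_", lv[i])]] <- unname(means[i])
    out[[paste0("sem_", lv[i])]] <- unname(sems[i])
  }
  out
}

# F table for the three effects, Type I (sequential) or Type II.
anova_table <- function(fit, ss_type) {
  if (ss_type == 1) {
    a <- stats::anova(fit)
    tab <- data.frame(F = a$`F value`, p = a$`Pr(>F)`,
                      row.names = rownames(a))
    return(tab[rownames(tab) != "Residuals", , drop = FALSE])
  }
  abort_if(ss_type != 2, "ss_type must be 1 or 2")
  if (requireNamespace("car", quietly = TRUE)) {
    a <- car::Anova(fit, type = 2)
    tab <- data.frame(F = a$`F value`, p = a$`Pr(>F)`,
                      row.names = rownames(a))
    return(tab[rownames(tab) != "Residuals", , drop = FALSE])
  }
  # fallback: Type II by model comparison
  d <- fit$model
  full <- lm(y ~ g * x, data = d)
  no_int <- lm(y ~ g + x, data = d)
  no_g <- lm(y ~ x, data = d)
  no_x <- lm(y ~ g, data = d)
  # Type II: each term adjusted for the others, F against the full
  # model's residual mean square
  rss_full <- sum(residuals(full)^2); df_full <- full$df.residual
  ss_g <- sum(residuals(no_g)^2) - sum(residuals(no_int)^2)
  ss_x <- sum(residuals(no_x)^2) - sum(residuals(no_int)^2)
  ss_i <- sum(residuals(no_int)^2) - rss_full
  Fs <- c(ss_g, ss_x, ss_i) / (rss_full / df_full)
  ps <- pf(Fs, 1, df_full, lower.tail = FALSE)
  data.frame(F = Fs, p = ps, row.names = c("g", "x", "g:x"))
}

#' Pearson correlation with degenerate-input flagging
#'
#' @param x,y Numeric vectors of equal length (>= 3 pairs).
#' @return Tibble: `r`, `n`, `p`, `flag`.
#' @export
correlate <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  abort_if(length(x) < 3, "need >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    return(tibble::tibble(r = NA_real_, n = length(x), p = NA_real_,
                          flag = "zero variance"))
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), n = length(x), p = ct$p.value,
                 flag = "")
}

#' Welch two-group comparison
#'
#' Two-sample Welch T-test (two-tailed) with group means and standard
#' errors, e.g. for contrasts such as medication subgroups.
#'
#' @param data Data frame.
#' @param value,group Column names; `group` must have exactly 2 levels.
#' @return One-row tibble: `T`, `df`, `p`, per-group `mean_*`, `sem_*`,
#'   `flag`.
#' @export
two_group_compare <- function(data, value, group) {
  d <- data.frame(y = data[[value]], g = factor(data[[group]]))
  lv <- levels(d$g)
  abort_if(length(lv) != 2, "group must have exactly 2 levels")
  abort_if(any(table(d$g) < 2), "need >= 2 observations per group")
  y1 <- d$y[d$g == lv[1]]; y2 <- d$y[d$g == lv[2]]
  if (var(y1) == 0 && var(y2) == 0) {
    out <- tibble::tibble(T = NA_real_, df = NA_real_, p = NA_real_,
                          flag = "zero variance in both groups")
  } else {
    tt <- t.test(y1, y2)
    out <- tibble::tibble(T = unname(tt$statistic),
                          df = unname(tt$parameter),
                          p = tt$p.value, flag = "")
  }
  out[[paste0("mean_", lv[1])]] <- mean(y1)
  out[[paste0("sem_", lv[1])]] <- sd(y1) / sqrt(length(y1))
  out[[paste0("mean_", lv[2])]] <- mean(y2)
  out[[paste0("sem_", lv[2])]] <- sd(y2) / sqrt(length(y2))
  out
}
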