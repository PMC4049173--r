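# Group-level statistics: pooled two-sample t (from summaries or raw
# samples), paired t, Pearson chi-squared without continuity correction,
# Spearman/Pearson correlation, one-way ANOVA with post hoc tests, drug
# wash-in effect, f-I slope, per-lobule aggregation.

new_group_comparison <- function(statistic, value, df, p, groups = NULL,
                                 method = NULL, extra = NULL) {
  structure(c(list(statistic = statistic, value = value, df = df, p = p,
                   groups = groups, method = method), extra),
            class = "group_comparison")
}

#' Summarize a sample for summary-based tests
#'
#' @param mean,sd,n Group mean, sample SD and size.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  check_number(mean, "mean", stop_fun = stop_invalid_input)
  check_number(sd, "sd", lower = 0, stop_fun = stop_invalid_input)
  check_number(n, "n", lower = 2, stop_fun = stop_invalid_input)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(x, name) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x)) {
    if (length(x) < 2L) {
      stop_invalid_input(sprintf("`%s` must contain at least 2 observations", name))
    }
    return(group_summary(mean(x), sd(x), length(x)))
  }
  stop_invalid_input(sprintf(
    "`%s` must be a numeric sample or a group_summary", name))
}

#' Pooled-variance two-sample Student t test
#'
#' Classical unpaired Student t with the pooled variance estimate and
#' `df = n_a + n_b - 2`. Accepts raw samples or `(mean, sd, n)` summaries
#' ([group_summary()]); raw samples give exactly the same result as their
#' summaries.
#'
#' @param a,b Numeric samples or [group_summary()] objects.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (alternative on `mean(a) - mean(b)`).
#' @return A `group_comparison` with the t value, df and p.
#' @export
two_sample_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  sa <- as_group_summary(a, "a")
  sb <- as_group_summary(b, "b")
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  tval <- if (se == 0) {
    if (sa$mean == sb$mean) 0 else sign(sa$mean - sb$mean) * Inf
  } else {
    (sa$mean - sb$mean) / se
  }
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(tval), df),
    greater = pt(tval, df, lower.tail = FALSE),
    less = pt(tval, df))
  new_group_comparison("t", tval, df, p,
                       groups = list(a = unclass(sa), b = unclass(sb)),
                       method = paste0("pooled two-sample t, ", alternative),
                       extra = list(degenerate = !is.finite(tval)))
}

#' Paired Student t test
#'
#' t on the pairwise differences `before - after`, `df = n - 1`.
#'
#' @param before,after Equal-length paired samples, n >= 2.
#' @param alternative As in [two_sample_t()].
#' @return A `group_comparison`; `degenerate` is `TRUE` when all
#'   differences are identical and non-zero (infinite t).
#' @export
paired_t <- function(before, after,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(before) || !is.numeric(after) ||
      length(before) != length(after)) {
    stop_invalid_input("`before` and `after` must be numeric and of equal length")
  }
  if (length(before) < 2L) {
    stop_invalid_input("paired t needs at least 2 pairs")
  }
  d <- before - after
  n <- length(d)
  sd_d <- sd(d)
  tval <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / (sd_d / sqrt(n))
  }
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(tval), n - 1),
    greater = pt(tval, n - 1, lower.tail = FALSE),
    less = pt(tval, n - 1))
  new_group_comparison("t", tval, n - 1, p,
                       groups = list(mean_difference = mean(d), sd_difference = sd_d, n = n),
                       method = paste0("paired t, ", alternative),
                       extra = list(degenerate = !is.finite(tval)))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' `sum((O - E)^2 / E)` with expected counts from the margins, df = 1,
#' without continuity correction. Invariant under transposition.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A `group_comparison` with the chi-squared value and p.
#' @export
pearson_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)) || anyNA(tab)) {
    stop_invalid_input("`table` must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_invalid_input("`table` has a zero margin; chi-squared is undefined")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  new_group_comparison("chi2", chi2, 1L, pchisq(chi2, 1L, lower.tail = FALSE),
                       groups = list(observed = tab, expected = expected),
                       method = "Pearson chi-squared, no continuity correction")
}

#' Spearman or Pearson correlation
#'
#' Rank (average ranks for ties) or product-moment correlation with a
#' two-sided p value (t approximation), delegated to [stats::cor.test()].
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `group_comparison` with statistic `rho` or `r`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L) {
    stop_invalid_input("`x` and `y` must be equal-length numeric vectors, n >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_undefined_metric("correlation is undefined for constant input")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  new_group_comparison(if (method == "spearman") "rho" else "r",
                       unname(ct$estimate),
                       if (method == "pearson") unname(ct$parameter) else length(x) - 2L,
                       ct$p.value,
                       groups = list(n = length(x)),
                       method = ct$method)
}

#' One-way ANOVA with post hoc pairwise comparisons
#'
#' F test across groups via [stats::aov()], optionally followed by Tukey
#' HSD or Bonferroni-adjusted pairwise t tests. With two groups,
#' `F == t^2` of the pooled [two_sample_t()] exactly.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2
#'   observations each).
#' @param posthoc `"none"`, `"tukey"` or `"bonferroni"`.
#' @return A `group_comparison` with the F value, df pair, p and, when
#'   requested, a `posthoc` data frame of pairwise comparisons.
#' @export
one_way_anova <- function(groups, posthoc = c("none", "tukey", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  if (!is.list(groups) || length(groups) < 2L) {
    stop_invalid_input("`groups` must be a list of at least 2 numeric vectors")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop_invalid_input("every group needs at least 2 observations")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  dat <- data.frame(value = values, group = fac)
  fit <- aov(value ~ group, data = dat)
  tab <- anova(fit)
  fval <- tab[["F value"]][1L]
  degenerate <- !is.finite(fval)
  ph <- NULL
  if (posthoc == "tukey" && !degenerate) {
    tk <- TukeyHSD(fit)$group
    ph <- data.frame(comparison = rownames(tk),
                     difference = tk[, "diff"],
                     p_adjusted = tk[, "p adj"],
                     row.names = NULL)
  } else if (posthoc == "bonferroni" && !degenerate) {
    pw <- pairwise.t.test(dat$value, dat$group, p.adjust.method = "bonferroni")
    pp <- pw$p.value
    idx <- which(!is.na(pp), arr.ind = TRUE)
    ph <- data.frame(
      comparison = paste(rownames(pp)[idx[, 1L]], colnames(pp)[idx[, 2L]],
                         sep = "-"),
      p_adjusted = pp[idx], row.names = NULL)
  }
  new_group_comparison("F", fval,
                       c(tab$Df[1L], tab$Df[2L]),
                       tab[["Pr(>F)"]][1L],
                       groups = lapply(groups, function(g) {
                         list(mean = mean(g), sd = sd(g), n = length(g))
                       }),
                       method = paste0("one-way ANOVA",
                                       if (posthoc != "none") paste0(" + ", posthoc)),
                       extra = list(posthoc = ph, degenerate = degenerate))
}

#' Drug wash-in effect on firing rate
#'
#' Percent rate reduction between a 2-min pre-drug baseline and the fixed
#' post-drug window 5-7 min after the drug reached the chamber:
#' `100 * (pre - post) / pre` with `pre` the mean rate over
#' `[onset - 120, onset)` s and `post` over `[onset + 300, onset + 420)` s.
#'
#' @param x A [spike_train_recording()] (simple spike train is used), a
#'   numeric vector of spike times, or a data frame with columns `time_s`
#'   and `rate_hz`.
#' @param drug_onset_s Time the drug reached the chamber (s from start).
#' @param duration Recording duration (s); required when `x` is a plain
#'   numeric vector, taken from the recording otherwise.
#' @return A list with `percent_reduction`, `pre_hz` and `post_hz`.
#' @export
washin_effect <- function(x, drug_onset_s, duration = NULL) {
  check_number(drug_onset_s, "drug_onset_s", lower = 0,
               stop_fun = stop_invalid_input)
  pre_win <- c(drug_onset_s - 120, drug_onset_s)
  post_win <- c(drug_onset_s + 300, drug_onset_s + 420)
  if (inherits(x, "spike_train_recording")) {
    duration <- x$duration
    x <- x$ss_times
  }
  if (is.data.frame(x)) {
    if (!all(c("time_s", "rate_hz") %in% names(x))) {
      stop_invalid_input("rate series must have columns time_s and rate_hz")
    }
    if (pre_win[1L] < min(x$time_s) - 1e-9 || post_win[2L] > max(x$time_s) + 1e-9) {
      stop_undefined_metric(
        "rate series does not cover [onset - 120 s, onset + 420 s]")
    }
    pre <- mean(x$rate_hz[x$time_s >= pre_win[1L] & x$time_s < pre_win[2L]])
    post <- mean(x$rate_hz[x$time_s >= post_win[1L] & x$time_s < post_win[2L]])
  } else if (is.numeric(x)) {
    if (is.null(duration)) {
      stop_invalid_input("`duration` is required with a plain spike-time vector")
    }
    if (pre_win[1L] < 0 || post_win[2L] > duration + 1e-9) {
      stop_undefined_metric(
        "recording does not cover [onset - 120 s, onset + 420 s]")
    }
    pre <- sum(x >= pre_win[1L] & x < pre_win[2L]) / 120
    post <- sum(x >= post_win[1L] & x < post_win[2L]) / 120
  } else {
    stop_invalid_input("`x` must be a recording, spike times, or a rate series")
  }
  if (!is.finite(pre) || pre <= 0) {
    stop_undefined_metric("pre-drug rate is zero; wash-in effect undefined")
  }
  list(percent_reduction = 100 * (pre - post) / pre,
       pre_hz = pre, post_hz = post)
}

#' Slope of the f-I (input-output) curve
#'
#' Ordinary least-squares slope of firing rate against injected current
#' over the full tested range.
#'
#' @param currents_nA Injected currents (nA), at least 3 distinct values.
#' @param rates_hz Response rates (spikes/s), same length.
#' @return A list with `slope_spk_per_nA`, `intercept_hz` and `n`.
#' @export
fi_slope <- function(currents_nA, rates_hz) {
  if (!is.numeric(currents_nA) || !is.numeric(rates_hz) ||
      length(currents_nA) != length(rates_hz) || length(currents_nA) < 3L) {
    stop_invalid_input("need at least 3 paired (current, rate) points")
  }
  if (sd(currents_nA) == 0) {
    stop_invalid_input("currents are constant; slope is undefined")
  }
  fit <- lm(rates_hz ~ currents_nA)
  list(slope_spk_per_nA = unname(coef(fit)[2L]),
       intercept_hz = unname(coef(fit)[1L]),
       n = length(currents_nA))
}

#' Canonical lobule labels
#'
#' Vermal lobules I-X plus the hemispheric subdivisions used when
#' correlating activity with zebrin staining intensity.
#' @return Character vector of labels.
#' @export
lobule_vocabulary <- function() {
  c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
    "HIV&V-Sim", "CrI-II", "PM", "Cop-PF", "Flocc")
}

#' Aggregate per-cell metrics by lobule
#'
#' Per-lobule mean, SD and n of simple spike rate, climbing fiber pause and
#' mean CV2, joined with the normalized zebrin staining intensity when an
#' intensity table is supplied (see [normalize_intensity()]); the result
#' feeds [correlate()]. Lobule labels are matched case-insensitively
#' against [lobule_vocabulary()] (extended by the intensity table's
#' labels); unmatched cells are excluded with a warning.
#'
#' @param metrics A [cohort_metrics()] data frame with a `lobule` column.
#' @param intensity Optional normalized intensity table with columns
#'   `lobule` and `intensity`.
#' @return A data frame with one row per lobule.
#' @export
aggregate_by_lobule <- function(metrics, intensity = NULL) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop_invalid_input("`metrics` must be a non-empty data frame")
  }
  vocab <- lobule_vocabulary()
  if (!is.null(intensity)) vocab <- union(vocab, intensity$lobule)
  match_idx <- match(tolower(metrics$lobule), tolower(vocab))
  if (any(is.na(match_idx))) {
    warning(sprintf("%d cells with unmapped lobule labels excluded",
                    sum(is.na(match_idx))), call. = FALSE)
  }
  metrics <- metrics[!is.na(match_idx), , drop = FALSE]
  if (nrow(metrics) == 0L) stop_invalid_input("no cells with mapped lobules")
  metrics$lobule <- vocab[match_idx[!is.na(match_idx)]]
  agg <- do.call(rbind, lapply(split(metrics, metrics$lobule), function(d) {
    data.frame(lobule = d$lobule[1L],
               n = nrow(d),
               mean_ss_rate = mean(d$ss_rate),
               sd_ss_rate = sd(d$ss_rate),
               mean_cf_pause_ms = mean(d$cf_pause_ms, na.rm = TRUE),
               mean_cv2 = mean(d$ss_mean_cv2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (!is.null(intensity)) {
    agg$intensity <- intensity$intensity[
      match(tolower(agg$lobule), tolower(intensity$lobule))]
  }
  agg
}

#' @export
print.group_comparison <- function(x, ...) {
  df_txt <- paste(x$df, collapse = ", ")
  cat(sprintf("<group_comparison> %s = %.4g, df = %s, p = %.4g\n",
              x$statistic, x$value, df_txt, x$p))
  if (!is.null(x$method)) cat("  method:", x$method, "\n")
  invisible(x)
}
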