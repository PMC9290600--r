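# --- method-validation statistics ---------------------------------------------

#' Paired method-comparison measurements
#'
#' @param x Comparator values.
#' @param y Candidate values.
#' @param sample_id Optional identifiers.
#' @param analyte,units Labels.
#' @param excluded Logical exclusion mask (invalidated results).
#' @param reason Exclusion reasons.
#' @return Object of class \code{paired_measurements}.
#' @export
paired_measurements <- function(x, y, sample_id = seq_along(x),
                                analyte = "", units = "",
                                excluded = rep(FALSE, length(x)),
                                reason = rep("", length(x))) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  structure(data.frame(sample_id = sample_id, x = x, y = y,
                       excluded = excluded, reason = reason,
                       stringsAsFactors = FALSE),
            analyte = analyte, units = units,
            class = c("paired_measurements", "data.frame"))
}

#' Passing-Bablok method-comparison regression
#'
#' Non-parametric regression on all pairwise slopes S_ij = (y_j - y_i) /
#' (x_j - x_i), i < j, x_i != x_j, with slopes equal to -1 excluded. The
#' slope estimate is the shifted median of the ordered slopes with offset
#' K = #\{S_ij < -1\}; the intercept is median(y - slope * x). Confidence
#' intervals use the classical rank-based normal approximation of the
#' pairwise-slope order statistics; intercept bounds reuse the slope bounds.
#'
#' @param pairs A \code{\link{paired_measurements}} object, or anything
#'   data-frame-like with columns x, y (and optionally excluded).
#' @param alpha Two-sided confidence level is 1 - alpha.
#' @return Object of class \code{method_comparison}: slope, slope_ci,
#'   intercept, intercept_ci, r, n, plus the median bias fields when
#'   computed via \code{\link{median_bias}}.
#' @export
passing_bablok <- function(pairs, alpha = 0.05) {
  d <- as.data.frame(pairs)
  if (!is.null(d$excluded)) d <- d[!d$excluded, , drop = FALSE]
  x <- d$x; y <- d$y
  n <- length(x)
  if (n < 3) stopf("Passing-Bablok requires >= 3 included pairs (got %d)", n)
  if (length(unique(x)) < 2) stopf("all x values identical; no regression")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  S <- dy[dx != 0] / dx[dx != 0]
  S <- S[!is.na(S) & S != -1]
  if (!length(S)) stopf("no valid pairwise slopes")
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  med_at <- function(off) {
    # shifted median of the ordered slopes
    if (N %% 2 == 1) S[clampi((N + 1) / 2 + off, N)]
    else mean(S[c(clampi(N / 2 + off, N), clampi(N / 2 + 1 + off, N))])
  }
  slope <- med_at(K)
  w <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  slope_ci <- c(S[clampi(M1 + K, N)], S[clampi(M2 + K, N)])
  intercept <- median(y - slope * x)
  intercept_ci <- c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x))
  structure(list(slope = slope, slope_ci = slope_ci,
                 intercept = intercept, intercept_ci = intercept_ci,
                 r = cor(x, y), n = n, alpha = alpha,
                 analyte = attr(pairs, "analyte") %||% "",
                 units = attr(pairs, "units") %||% ""),
            class = "method_comparison")
}

clampi <- function(i, n) min(max(as.integer(i), 1L), n)

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Passing-Bablok %s (n = %d)\n",
              if (nzchar(x$analyte)) x$analyte else "regression", x$n))
  cat(sprintf("  slope     %.4f  (%.4f, %.4f)\n", x$slope,
              x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f  (%.4f, %.4f)\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  r         %.4f\n", x$r))
  if (!is.null(x$bias))
    cat(sprintf("  bias      %.4g (%s)\n", x$bias, x$bias_mode))
  invisible(x)
}

#' Median-of-differences bias
#'
#' Bias between two methods as the median of differences, absolute
#' (median(y - x)) or relative (median(100 * (y - x) / x), in percent),
#' according to the nature of the analyte.
#'
#' @param pairs \code{\link{paired_measurements}} or data frame with x, y.
#' @param mode "absolute" or "relative".
#' @return Median bias (percent in relative mode).
#' @export
median_bias <- function(pairs, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  d <- as.data.frame(pairs)
  if (!is.null(d$excluded)) d <- d[!d$excluded, , drop = FALSE]
  if (!nrow(d)) stopf("at least one included pair is required")
  if (mode == "absolute") return(median(d$y - d$x))
  zero <- which(d$x == 0)
  if (length(zero))
    stopf("relative bias undefined: x = 0 for pair(s) %s",
          paste(d$sample_id[zero] %||% zero, collapse = ", "))
  median(100 * (d$y - d$x) / d$x)
}

#' Pooled within-sample standard deviation
#'
#' Repeatability pooled over samples: sqrt(sum((n_i - 1) s_i^2) /
#' sum(n_i - 1)). With a single sample this is the ordinary SD.
#'
#' @param values Replicate values.
#' @param sample Parallel sample identifiers.
#' @return List: pooled_sd, mean (grand mean), cv_pct, n_samples,
#'   n_replicates.
#' @export
pooled_sd <- function(values, sample = rep(1, length(values))) {
  sp <- split(values, sample)
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 2)) stopf("every sample needs >= 2 replicates")
  vs <- vapply(sp, var, numeric(1))
  ps <- sqrt(sum((ns - 1) * vs) / sum(ns - 1))
  m <- mean(values)
  list(pooled_sd = ps, mean = m, cv_pct = 100 * ps / m,
       n_samples = length(sp), n_replicates = length(values))
}

#' Repeatability table in the style of a pooled-SD precision study
#'
#' Groups replicate runs by measurand and target-range label and emits one
#' row per group: sample count, replicate count, mean and pooled SD.
#'
#' @param replicates data.frame with columns measurand, sample_id, value and
#'   optionally range_label, units.
#' @return data.frame, one row per measurand x range.
#' @export
repeatability_table <- function(replicates) {
  need <- c("measurand", "sample_id", "value")
  if (!all(need %in% names(replicates)))
    stopf("replicates must have columns %s", paste(need, collapse = ", "))
  if (is.null(replicates$range_label)) replicates$range_label <- ""
  groups <- unique(replicates[, c("measurand", "range_label")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- replicates[replicates$measurand == groups$measurand[i] &
                      replicates$range_label == groups$range_label[i], ]
    ps <- pooled_sd(g$value, g$sample_id)
    data.frame(measurand = groups$measurand[i],
               range = groups$range_label[i],
               n_samples = ps$n_samples, n_replicates = ps$n_replicates,
               mean = ps$mean, pooled_sd = ps$pooled_sd,
               cv_pct = ps$cv_pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nested reproducibility variance components
#'
#' Balanced nested ANOVA for the multi-site precision design (sites >
#' devices within site > days > runs > replicates), by the method of moments
#' on the nested mean squares. Negative solutions are truncated to zero and
#' noted. The total SD is the square root of the component sum.
#'
#' @param records data.frame with columns site, device, day, run, value
#'   (replicates are the rows within a run).
#' @return Object of class \code{reproducibility_components}: data.frame
#'   \code{components} (stratum, variance, sd, variance_raw = the untruncated
#'   method-of-moments solution, truncated), \code{total_sd}, \code{design}.
#' @export
reproducibility_components <- function(records) {
  need <- c("site", "device", "day", "run", "value")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  key <- function(...) interaction(..., drop = FALSE)
  # balance checks: identical replicate counts in every run, runs per day...
  records$.site <- factor(records$site)
  records$.dev <- key(records$site, records$device)
  records$.day <- key(records$site, records$device, records$day)
  records$.run <- key(records$site, records$device, records$day, records$run)
  a <- nlevels(records$.site)
  nb <- unique(tapply(records$device, records$site,
                      function(d) length(unique(d))))
  nc <- unique(tapply(records$day, records$.dev,
                      function(d) length(unique(d))))
  nd <- unique(tapply(records$run, records$.day,
                      function(d) length(unique(d))))
  ne <- unique(as.vector(table(records$.run)))
  if (length(nb) != 1 || length(nc) != 1 || length(nd) != 1 || length(ne) != 1)
    stopf("unbalanced design: only the fully balanced nested layout is supported")
  b <- as.vector(nb); cc <- as.vector(nc); d <- as.vector(nd); e <- as.vector(ne)
  y <- records$value
  gm <- mean(y)
  m_run <- tapply(y, records$.run, mean)
  m_day <- tapply(y, records$.day, mean)
  m_dev <- tapply(y, records$.dev, mean)
  m_site <- tapply(y, records$.site, mean)
  # nested sums of squares
  ss_rep <- sum((y - m_run[as.character(records$.run)])^2)
  agg <- unique(records[, c(".site", ".dev", ".day", ".run")])
  agg$m_run <- as.numeric(m_run[as.character(agg$.run)])
  agg$m_day <- as.numeric(m_day[as.character(agg$.day)])
  agg$m_dev <- as.numeric(m_dev[as.character(agg$.dev)])
  agg$m_site <- as.numeric(m_site[as.character(agg$.site)])
  ss_run <- e * sum((agg$m_run - agg$m_day)^2)
  agg_day <- unique(agg[, c(".site", ".dev", ".day", "m_day", "m_dev", "m_site")])
  ss_day <- d * e * sum((agg_day$m_day - agg_day$m_dev)^2)
  agg_dev <- unique(agg_day[, c(".site", ".dev", "m_dev", "m_site")])
  ss_dev <- cc * d * e * sum((agg_dev$m_dev - agg_dev$m_site)^2)
  agg_site <- unique(agg_dev[, c(".site", "m_site")])
  ss_site <- b * cc * d * e * sum((agg_site$m_site - gm)^2)
  df <- c(site = a - 1, device = a * (b - 1), day = a * b * (cc - 1),
          run = a * b * cc * (d - 1), replicate = a * b * cc * d * (e - 1))
  ms <- c(site = if (df[["site"]] > 0) ss_site / df[["site"]] else NA,
          device = if (df[["device"]] > 0) ss_dev / df[["device"]] else NA,
          day = ss_day / df[["day"]], run = ss_run / df[["run"]],
          replicate = ss_rep / df[["replicate"]])
  raw <- c(replicate = ms[["replicate"]],
           run = (ms[["run"]] - ms[["replicate"]]) / e,
           day = (ms[["day"]] - ms[["run"]]) / (d * e),
           device = if (is.na(ms[["device"]])) 0
                    else (ms[["device"]] - ms[["day"]]) / (cc * d * e),
           site = if (is.na(ms[["site"]])) 0
                  else (ms[["site"]] - ms[["device"]]) / (b * cc * d * e))
  comp <- pmax(raw, 0)
  out <- data.frame(stratum = names(comp), variance = as.numeric(comp),
                    sd = sqrt(as.numeric(comp)),
                    variance_raw = as.numeric(raw),   # unbiased MoM solution
                    truncated = raw < 0, stringsAsFactors = FALSE)
  structure(list(components = out, total_sd = sqrt(sum(comp)),
                 design = c(sites = a, devices = b, days = cc, runs = d,
                            replicates = e)),
            class = "reproducibility_components")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles; endpoints are proportions
#' (round only at display).
#'
#' @param successes,n Counts, 0 <= successes <= n, n >= 1.
#' @param alpha Two-sided level (default 95\% interval).
#' @return c(lower, upper) proportions.
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (n < 1 || successes < 0 || successes > n || successes != round(successes))
    stopf("invalid counts: %s of %s", successes, n)
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes,
                                            n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1,
                                            n - successes)
  c(lower = lower, upper = upper)
}

#' Flagging agreement statistics with exact binomial intervals
#'
#' Sensitivity (positive percent agreement), specificity (negative percent
#' agreement) and overall agreement from a 2x2 flag-vs-reference table, each
#' with its exact Clopper-Pearson interval.
#'
#' @param tp,fn,tn,fp Agreement counts (tp + fn positives, tn + fp negatives).
#' @param alpha Two-sided level.
#' @return data.frame: statistic, estimate, lower, upper (proportions),
#'   successes, n.
#' @export
binomial_agreement <- function(tp, fn, tn, fp, alpha = 0.05) {
  if (any(c(tp, fn, tn, fp) < 0)) stopf("counts must be non-negative")
  pos <- tp + fn; neg <- tn + fp
  if (pos == 0 || neg == 0) stopf("both margins must be non-empty")
  rows <- list(c("sensitivity", tp, pos),
               c("specificity", tn, neg),
               c("overall_agreement", tp + tn, pos + neg))
  do.call(rbind, lapply(rows, function(r) {
    s <- as.numeric(r[2]); n <- as.numeric(r[3])
    ci <- clopper_pearson(s, n, alpha)
    data.frame(statistic = r[1], estimate = s / n,
               lower = ci[["lower"]], upper = ci[["upper"]],
               successes = s, n = n, stringsAsFactors = FALSE)
  }))
}

#' Two-examiner differential comparison (Ruemke-style)
#'
#' For each cell class, the two examiners' 200-cell differential counts are
#' compared by the exact conditional two-proportion test (hypergeometric
#' conditioning on the combined count, the two-sided Fisher construction):
#' the examiners agree on a class when the test is not significant at
#' \code{alpha}. The examiners agree overall when no class disagrees.
#'
#' @param diff_a,diff_b Named per-class counts, each summing to
#'   \code{n_cells}.
#' @param n_cells Cells counted per differential (default 200).
#' @param alpha Significance level per class.
#' @return Object of class \code{rumke_comparison}: data.frame per class
#'   (count_a, count_b, p_value, agree) and \code{agree} overall.
#' @export
rumke_compare <- function(diff_a, diff_b, n_cells = 200, alpha = 0.05) {
  if (sum(diff_a) != n_cells || sum(diff_b) != n_cells)
    stopf("both differentials must sum to n_cells = %d", n_cells)
  classes <- union(names(diff_a), names(diff_b))
  if (is.null(classes)) classes <- seq_along(diff_a)
  get0n <- function(v, k) { x <- v[k]; ifelse(is.na(x), 0, x) }
  rows <- lapply(classes, function(k) {
    x1 <- as.numeric(get0n(diff_a, k)); x2 <- as.numeric(get0n(diff_b, k))
    p <- cond_binom_p(x1, x2, n_cells)
    data.frame(class = k, count_a = x1, count_b = x2, p_value = p,
               agree = p >= alpha, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(classes = tab, agree = all(tab$agree), alpha = alpha,
                 n_cells = n_cells),
            class = "rumke_comparison")
}

# Exact conditional two-proportion p-value: given t = x1 + x2 from two
# binomials with n trials each and equal success probability, x1 is
# hypergeometric(2n, n, t); two-sided p sums all outcomes no more probable
# than the observed one.
cond_binom_p <- function(x1, x2, n) {
  t <- x1 + x2
  ks <- max(0, t - n):min(t, n)
  pr <- dhyper(ks, n, n, t)
  p_obs <- dhyper(x1, n, n, t)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Arbitrated agreement across examiners
#'
#' Implements the examination protocol: the first two examiners are compared;
#' when they disagree, a third examiner arbitrates and any agreeing pair is
#' accepted; with no agreeing pair, the sample is discarded.
#'
#' @param differentials List of >= 2 named count vectors (same n_cells).
#' @param n_cells,alpha Passed to \code{\link{rumke_compare}}.
#' @return List: \code{verdict} ("agree" or "discard"), \code{pair} (indices
#'   of the agreeing pair or NULL), \code{comparisons}.
#' @export
rumke_arbitrate <- function(differentials, n_cells = 200, alpha = 0.05) {
  m <- length(differentials)
  if (m < 2) stopf("at least two differentials are required")
  comps <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      cmp <- rumke_compare(differentials[[i]], differentials[[j]],
                           n_cells, alpha)
      comps[[paste(i, j)]] <- cmp
      if (cmp$agree)
        return(list(verdict = "agree", pair = c(i, j), comparisons = comps))
    }
  }
  list(verdict = "discard", pair = NULL, comparisons = comps)
}

#' Matrix comparison across specimen types
#'
#' Pair-averaged Passing-Bablok per analyte: replicate measurements of each
#' specimen are averaged within matrix (e.g., capillary vs venous) before
#' regression, mirroring the paired-collection study design. Unpaired
#' specimens are excluded with a log entry.
#'
#' @param data data.frame with columns specimen_id, analyte, matrix,
#'   replicate, value.
#' @param x_matrix,y_matrix Which matrix is the comparator (x) and which the
#'   candidate (y).
#' @param bias_mode Named character vector analyte -> "absolute"/"relative";
#'   unnamed default applies to all (concentrations are conventionally
#'   relative, percentages absolute).
#' @param alpha Two-sided CI level.
#' @return data.frame, one row per analyte, in the layout of a matrix-study
#'   table: N, means/min/max per matrix, slope + CI, intercept + CI, r, bias;
#'   attribute \code{exclusions} lists dropped specimens.
#' @export
matrix_comparison <- function(data, x_matrix, y_matrix,
                              bias_mode = "relative", alpha = 0.05) {
  need <- c("specimen_id", "analyte", "matrix", "value")
  if (!all(need %in% names(data)))
    stopf("data must have columns %s", paste(need, collapse = ", "))
  data <- data[data$matrix %in% c(x_matrix, y_matrix), , drop = FALSE]
  exclusions <- character(0)
  rows <- list()
  for (an in unique(data$analyte)) {
    d <- data[data$analyte == an, , drop = FALSE]
    avg <- aggregate(value ~ specimen_id + matrix, d, mean)
    xs <- avg[avg$matrix == x_matrix, ]
    ys <- avg[avg$matrix == y_matrix, ]
    ids <- intersect(xs$specimen_id, ys$specimen_id)
    dropped <- setdiff(union(xs$specimen_id, ys$specimen_id), ids)
    if (length(dropped))
      exclusions <- c(exclusions, sprintf("%s: unpaired specimen %s excluded",
                                          an, paste(dropped, collapse = ", ")))
    x <- xs$value[match(ids, xs$specimen_id)]
    y <- ys$value[match(ids, ys$specimen_id)]
    pm <- paired_measurements(x, y, sample_id = ids, analyte = an)
    pb <- passing_bablok(pm, alpha)
    mode <- if (length(bias_mode) > 1 || !is.null(names(bias_mode)))
      (bias_mode[[an]] %||% "relative") else bias_mode
    rows[[an]] <- data.frame(
      analyte = an, n = pb$n,
      x_mean = mean(x), x_min = min(x), x_max = max(x),
      y_mean = mean(y), y_min = min(y), y_max = max(y),
      slope = pb$slope, slope_lo = pb$slope_ci[1], slope_hi = pb$slope_ci[2],
      intercept = pb$intercept, intercept_lo = pb$intercept_ci[1],
      intercept_hi = pb$intercept_ci[2], r = pb$r,
      bias = median_bias(pm, mode), bias_mode = mode,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}
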