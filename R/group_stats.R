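# Cohort-level comparisons. Per-segment summaries (mean kappa, low-IT
# fraction, significant periodogram power) are stacked into a long-format
# cohort table and compared between states of consciousness by a
# repeated-measures ANOVA: state and subject as fixed effects, segments as
# replicates, sequential sums of squares on the observed cells.

#' Build a long-format cohort table from segment summaries
#'
#' @param summaries Data.frame of segment summaries (rows from
#'   [kappa_summary()], optionally with a `significant_power` column added
#'   by the periodicity step).
#' @param metrics Metric columns to keep (default: those of
#'   `kappa_avg`, `low_it_fraction`, `significant_power` that are present).
#' @return A `cohort_table` data.frame with columns `subject_id`, `state`,
#'   `segment_id`, `delta_t_s`, `metric_name`, `metric_value` and unique
#'   (subject, state, segment, delta_t, metric) keys.
#' @export
cohort_table <- function(summaries,
                         metrics = intersect(
                           c("kappa_avg", "low_it_fraction",
                             "significant_power"),
                           names(summaries))) {
  df <- as.data.frame(summaries)
  need <- c("subject_id", "state", "segment_id", "delta_t_s")
  miss <- setdiff(c(need, metrics), names(df))
  if (length(miss))
    stop_param("summaries lack column(s): %s", paste(miss, collapse = ", "))
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(df[need], metric_name = m, metric_value = df[[m]],
               stringsAsFactors = FALSE)
  }))
  key <- do.call(paste, c(long[c(need, "metric_name")], sep = "\r"))
  if (anyDuplicated(key))
    stop_param("duplicate (subject, state, segment, delta_t, metric) keys")
  rownames(long) <- NULL
  class(long) <- c("cohort_table", "data.frame")
  long
}

#' Two-state repeated-measures ANOVA on one metric
#'
#' Restricts the cohort table to two states, one time interval and one
#' metric, and decomposes segment-level values by sequential fixed-effects
#' sums of squares: state first (df = 1), then subject
#' (df = n_subjects - 1), with the remainder as error
#' (df = N - 1 - 1 - (n_subjects - 1)). The F statistic is
#' `(SS_state / 1) / (SS_error / df_error)`. Subjects present in only one
#' of the two states are retained (unbalanced cells enter the sequential
#' decomposition as observed) and reported in a message.
#'
#' @param table A [cohort_table()].
#' @param state_a,state_b The two state labels to compare.
#' @param delta_t_s Time interval selecting the rows.
#' @param metric Metric name selecting the rows.
#' @return An `anova_result` (one-row data.frame) with columns
#'   `state_a`, `state_b`, `delta_t_s`, `metric`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `f_stat`, `df_num`, `df_den`, `p_raw`,
#'   `p_adjusted` (`NA` until [bonferroni()]).
#' @export
rm_anova <- function(table, state_a, state_b, delta_t_s, metric) {
  df <- as.data.frame(table)
  sel <- df$state %in% c(state_a, state_b) &
    abs(df$delta_t_s - delta_t_s) < 1e-12 & df$metric_name == metric
  df <- df[sel, , drop = FALSE]
  for (s in c(state_a, state_b))
    if (!any(df$state == s))
      stop_param("state '%s' has no data at dt=%g for metric %s",
                 s, delta_t_s, metric)
  both <- intersect(unique(df$subject_id[df$state == state_a]),
                    unique(df$subject_id[df$state == state_b]))
  if (length(both) < 2L)
    stop_param("need >= 2 subjects observed in both states, got %d",
               length(both))
  lone <- setdiff(unique(df$subject_id), both)
  if (length(lone))
    message("rm_anova: subject(s) ", paste(lone, collapse = ", "),
            " observed in only one state; retained in the decomposition")
  y <- df$metric_value
  state <- factor(df$state, levels = c(state_a, state_b))
  subject <- factor(df$subject_id)
  n <- length(y)
  n_subj <- nlevels(subject)
  # sequential (Type-I) SS via nested linear fits: state first, then subject
  rss0 <- sum((y - mean(y))^2)
  fit1 <- stats::lm(y ~ state)
  fit2 <- stats::lm(y ~ state + subject)
  ss_state <- max(0, rss0 - sum(stats::resid(fit1)^2))
  ss_error <- sum(stats::resid(fit2)^2)
  df_den <- n - 1L - 1L - (n_subj - 1L)
  if (df_den < 1L)
    stop_param("no error degrees of freedom (N=%d, %d subjects)", n, n_subj)
  tol <- 1e-12 * (sum(y^2) + 1)  # numerically-zero sums of squares
  if (ss_error <= tol) {
    # no residual variation: identical cells give F = 0, p = 1; a perfectly
    # clean state effect gives F = Inf, p = 0
    f_stat <- if (ss_state <= tol) 0 else Inf
  } else {
    f_stat <- (ss_state / 1) / (ss_error / df_den)
  }
  p_raw <- stats::pf(f_stat, 1, df_den, lower.tail = FALSE)
  ya <- y[state == state_a]; yb <- y[state == state_b]
  out <- data.frame(
    state_a = state_a, state_b = state_b, delta_t_s = delta_t_s,
    metric = metric,
    mean_a = mean(ya), sd_a = stats::sd(ya), n_a = length(ya),
    mean_b = mean(yb), sd_b = stats::sd(yb), n_b = length(yb),
    f_stat = f_stat, df_num = 1L, df_den = df_den,
    p_raw = p_raw, p_adjusted = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Bonferroni correction over a family of comparisons
#'
#' @param results An `anova_result` data.frame (one or more rows).
#' @param m Family size; `"auto"` (default) uses the number of rows.
#' @return `results` with `p_adjusted = min(1, m * p_raw)`.
#' @export
bonferroni <- function(results, m = "auto") {
  df <- as.data.frame(results)
  if (identical(m, "auto")) m <- nrow(df)
  m <- as.numeric(m)
  if (m < 1) stop_param("Bonferroni family size must be >= 1")
  df$p_adjusted <- pmin(1, m * df$p_raw)
  class(df) <- class(results)
  df
}

#' All pairwise state comparisons against a baseline
#'
#' Runs [rm_anova()] for every (other state, time interval, metric) cell
#' and applies the Bonferroni correction within each (state pair, metric)
#' family — i.e. across the time intervals, the default family of size
#' `length(delta_ts)`. Cells whose ANOVA fails (e.g. a state missing at one
#' interval) are reported as `NA` rows and the remaining cells proceed.
#'
#' @param table A [cohort_table()].
#' @param baseline_state The reference state label.
#' @param other_states States to compare against the baseline (default: all
#'   non-baseline states in the table).
#' @param delta_ts Time intervals (default: those present).
#' @param metrics Metrics (default: those present).
#' @param bonferroni_m Family size override; `"auto"` uses the number of
#'   intervals in each (pair, metric) family.
#' @return A data.frame with one row per (other state, interval, metric).
#' @export
compare_all <- function(table, baseline_state, other_states = NULL,
                        delta_ts = NULL, metrics = NULL,
                        bonferroni_m = "auto") {
  df <- as.data.frame(table)
  if (!any(df$state == baseline_state))
    stop_param("baseline state '%s' not present", baseline_state)
  if (is.null(other_states))
    other_states <- setdiff(unique(df$state), baseline_state)
  if (is.null(delta_ts)) delta_ts <- sort(unique(df$delta_t_s))
  if (is.null(metrics)) metrics <- unique(df$metric_name)
  fam <- list()
  for (st in other_states) for (m in metrics) {
    rows <- lapply(delta_ts, function(dt) {
      tryCatch(rm_anova(table, baseline_state, st, dt, m),
               error = function(e) {
                 warning(sprintf("comparison %s vs %s, dt=%g, %s failed: %s",
                                 baseline_state, st, dt, m,
                                 conditionMessage(e)), call. = FALSE)
                 out <- data.frame(
                   state_a = baseline_state, state_b = st, delta_t_s = dt,
                   metric = m, mean_a = NA_real_, sd_a = NA_real_,
                   n_a = NA_integer_, mean_b = NA_real_, sd_b = NA_real_,
                   n_b = NA_integer_, f_stat = NA_real_, df_num = NA_integer_,
                   df_den = NA_integer_, p_raw = NA_real_,
                   p_adjusted = NA_real_, stringsAsFactors = FALSE)
                 class(out) <- c("anova_result", "data.frame")
                 out
               })
    })
    block <- do.call(rbind, rows)
    m_fam <- if (identical(bonferroni_m, "auto")) length(delta_ts) else
      bonferroni_m
    block <- bonferroni(block, m = m_fam)
    fam[[length(fam) + 1L]] <- block
  }
  if (length(fam) == 0L) {
    out <- data.frame(
      state_a = character(0), state_b = character(0), delta_t_s = numeric(0),
      metric = character(0), mean_a = numeric(0), sd_a = numeric(0),
      n_a = integer(0), mean_b = numeric(0), sd_b = numeric(0),
      n_b = integer(0), f_stat = numeric(0), df_num = integer(0),
      df_den = integer(0), p_raw = numeric(0), p_adjusted = numeric(0),
      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, fam)
  rownames(out) <- NULL
  out
}

#' Group means and standard deviations per state
#'
#' The descriptive half of the comparison tables: per (state, interval,
#' metric), the mean and SD of segment-level values.
#'
#' @param table A [cohort_table()].
#' @return A data.frame with columns `state`, `delta_t_s`, `metric_name`,
#'   `mean`, `sd`, `n_segments`.
#' @export
state_means <- function(table) {
  df <- as.data.frame(table)
  agg <- stats::aggregate(
    metric_value ~ state + delta_t_s + metric_name, data = df,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- data.frame(agg[c("state", "delta_t_s", "metric_name")],
                    mean = agg$metric_value[, "mean"],
                    sd = agg$metric_value[, "sd"],
                    n_segments = agg$metric_value[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$metric_name, out$delta_t_s, out$state), ]
}
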