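star_label <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Paired two-sample t-test with significance stars
#'
#' The test used to compare consecutive time points and conditions:
#' differences `d_i = x_i - y_i`, statistic `t = mean(d) / (sd(d)/sqrt(n))`
#' with the n-1 standard deviation, two-sided p-value from the Student t
#' distribution with `df = n - 1`. Stars follow the usual convention
#' (`*` for p < 0.05, `**` for p < 0.01).
#'
#' Degenerate pairings are flagged rather than erroring: zero-variance
#' differences with a non-zero mean give an infinite t and p = 0
#' (`flag = "zero_sd_nonzero_mean"`); all-zero differences give p = 1
#' (`flag = "zero_sd_zero_mean"`).
#'
#' @param x,y Equal-length numeric vectors (n >= 2), paired by index.
#' @return A one-row tibble: `t`, `df`, `p`, `stars`, `flag`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 3, 5))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  d <- x - y
  df <- n - 1L
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) != 0) {
      return(tibble::tibble(t = Inf * sign(mean(d)), df = df, p = 0,
                            stars = "**", flag = "zero_sd_nonzero_mean"))
    }
    return(tibble::tibble(t = NA_real_, df = df, p = 1,
                          stars = "", flag = "zero_sd_zero_mean"))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(t = t_stat, df = df, p = p, stars = star_label(p),
                 flag = "")
}

#' Consecutive time-point tests on a DD1 time course
#'
#' One paired t-test per adjacent time-point pair of a condition,
#' replicates paired by index (vial 1 with vial 1, ...), reported in time
#' order — the analysis behind "significantly higher than the previous
#' data point" statements.
#'
#' @param reps Replicate-level DD1 values as returned by
#'   [dd_replicates()] (columns `condition_id`, `time_s`, `replicate`,
#'   `dd1`), for a single condition.
#' @param bonferroni Apply a Bonferroni correction across the adjacent
#'   pairs (default `FALSE`, matching uncorrected reporting).
#' @return A tibble with one row per adjacent pair: `condition_id`,
#'   `time_a`, `time_b`, `t`, `df`, `p`, `stars`, `flag`.
#' @export
consecutive_timepoint_tests <- function(reps, bonferroni = FALSE) {
  stopifnot(all(c("condition_id", "time_s", "replicate", "dd1") %in% names(reps)))
  if (length(unique(reps$condition_id)) != 1)
    stop("supply one condition at a time")
  times <- sort(unique(reps$time_s))
  if (length(times) < 2) stop("need at least 2 time points")
  counts <- table(reps$time_s)
  if (length(unique(as.integer(counts))) != 1)
    stop("unequal replicate counts across time points")
  out <- vector("list", length(times) - 1L)
  for (i in seq_len(length(times) - 1L)) {
    a <- dplyr::filter(reps, .data$time_s == times[i]) |>
      dplyr::arrange(.data$replicate)
    b <- dplyr::filter(reps, .data$time_s == times[i + 1]) |>
      dplyr::arrange(.data$replicate)
    res <- paired_t_test(b$dd1, a$dd1)
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(condition_id = reps$condition_id[1],
                     time_a = times[i], time_b = times[i + 1]), res)
  }
  res <- dplyr::bind_rows(out)
  if (bonferroni) {
    res$p <- pmin(res$p * nrow(res), 1)
    res$stars <- star_label(res$p)
  }
  res
}
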