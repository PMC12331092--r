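#' Two-sided Mann-Whitney U test
#'
#' Used to compare pooled per-frame distance distributions between
#' simulation conditions (e.g. switch-gate distances with and without the
#' bound phosphopeptide). The exact null distribution is used when
#' `min(n1, n2) <= 10` and there are no ties; otherwise the normal
#' approximation with continuity and tie correction is used. The reported U
#' is the statistic for sample `x`.
#'
#' @param x,y numeric samples (each non-empty)
#' @return object of class `mwu_result`: `statistic` (U for x), `p_value`
#'   (two-sided), `method` ("exact" or "normal-approximation"), `n1`, `n2`
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal-approximation",
                 n1 = length(x), n2 = length(y)),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("<mann-whitney U> U = %g, p = %.4g (%s; n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Tukey boxplot summary
#'
#' Quartiles by linear interpolation of the empirical distribution,
#' whiskers at the most extreme data within 1.5 x IQR of the quartiles,
#' points beyond the whiskers flagged as outliers — the construction used
#' for distance-distribution boxplots.
#'
#' @param values numeric sample, n >= 1
#' @return object of class `box_summary`: `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`
#' @export
box_summary <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = sort(values[!inside]), n = length(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("<box_summary> n = %d: [%.3g | %.3g [%.3g] %.3g | %.3g], %d outlier(s)\n",
              x$n, x$whisker_low, x$q1, x$median, x$q3, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

# ---- HDX-MS differential uptake ------------------------------------------

hdx_required_cols <- c("peptide_start", "peptide_end", "state",
                       "timepoint_s", "replicate", "uptake_Da")

#' Read an HDX uptake table
#'
#' Expected CSV columns: `peptide_start`, `peptide_end`, `state`,
#' `timepoint_s`, `replicate`, `uptake_Da` (deuterium uptake in Dalton).
#'
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_hdx_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_hdx(df)
}

validate_hdx <- function(df) {
  missing <- setdiff(hdx_required_cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("HDX table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(df$uptake_Da < 0)) stop("uptake_Da must be non-negative")
  # soft sanity check: replicate-mean uptake should not decrease with time
  mu <- stats::aggregate(uptake_Da ~ peptide_start + peptide_end + state +
                           timepoint_s, data = df, FUN = mean)
  mu <- mu[order(mu$timepoint_s), ]
  dec <- stats::aggregate(uptake_Da ~ peptide_start + peptide_end + state,
                          data = mu, FUN = function(u) any(diff(u) < -1e-9))
  if (any(dec$uptake_Da))
    warning("replicate-mean uptake decreases with time for some peptide/state")
  df
}

#' Differential HDX comparison between two states
#'
#' For every peptide and exchange timepoint, computes the uptake difference
#' delta = mean(state_b) - mean(state_a) and a two-sample pooled-variance
#' Student t test across replicates. A difference is called significant only
#' if BOTH p < alpha AND |delta| >= delta_floor; the 0.2 Da floor reflects
#' the practical resolution of centroid-based uptake measurements, so a
#' statistically small-variance but sub-resolution difference is never
#' called.
#'
#' @param data HDX table (see [read_hdx_csv()])
#' @param state_a,state_b state labels; delta is `state_b - state_a`
#' @param delta_floor minimum absolute difference in Da (default 0.2)
#' @param alpha significance level for the t test (default 0.05)
#' @param p_adjust p-value adjustment method across rows (default "none";
#'   "BH" available)
#' @return data.frame of class `hdx_comparison`: one row per peptide x
#'   timepoint with `delta_Da`, `p_value`, `significant`
#' @export
hdx_compare <- function(data, state_a, state_b, delta_floor = 0.2,
                        alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  data <- validate_hdx(data)
  for (s in c(state_a, state_b))
    if (!s %in% data$state) stop(sprintf("state '%s' absent from HDX table", s))
  key <- unique(data[, c("peptide_start", "peptide_end", "timepoint_s")])
  key <- key[order(key$peptide_start, key$peptide_end, key$timepoint_s), ]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    pick <- function(s) data$uptake_Da[
      data$peptide_start == k$peptide_start &
      data$peptide_end == k$peptide_end &
      data$timepoint_s == k$timepoint_s & data$state == s]
    ua <- pick(state_a); ub <- pick(state_b)
    if (length(ua) < 2L || length(ub) < 2L)
      stop(sprintf(
        "peptide %d-%d, t = %gs: need >= 2 replicates per state (found %d/%d)",
        k$peptide_start, k$peptide_end, k$timepoint_s, length(ua), length(ub)))
    delta <- mean(ub) - mean(ua)
    pv <- if (stats::sd(c(ua, ub)) == 0) 1
          else stats::t.test(ub, ua, var.equal = TRUE)$p.value
    data.frame(peptide_start = k$peptide_start, peptide_end = k$peptide_end,
               timepoint_s = k$timepoint_s,
               mean_a = mean(ua), mean_b = mean(ub),
               delta_Da = delta, p_value = pv)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha & abs(out$delta_Da) >= delta_floor
  attr(out, "delta_floor") <- delta_floor
  attr(out, "alpha") <- alpha
  attr(out, "states") <- c(state_a, state_b)
  class(out) <- c("hdx_comparison", "data.frame")
  out
}

#' Classify peptides by the direction of significant HDX change
#'
#' `"increased"` if a peptide has at least one significant positive
#' timepoint and no significant negative one (more exchange in state B,
#' i.e. locally more dynamic/exposed); `"decreased"` for the symmetric case;
#' `"ns"` with no significant timepoint; `"mixed"` otherwise.
#'
#' @param comparison a [hdx_compare()] result
#' @return data.frame with one row per peptide and its `peptide_class`
#' @export
hdx_classify_regions <- function(comparison) {
  stopifnot(inherits(comparison, "hdx_comparison") ||
            all(c("peptide_start", "peptide_end", "delta_Da", "significant")
                %in% names(comparison)))
  key <- unique(comparison[, c("peptide_start", "peptide_end")])
  key <- key[order(key$peptide_start, key$peptide_end), ]
  cls <- vapply(seq_len(nrow(key)), function(i) {
    rows <- comparison[comparison$peptide_start == key$peptide_start[i] &
                       comparison$peptide_end == key$peptide_end[i], ]
    pos <- any(rows$significant & rows$delta_Da > 0)
    neg <- any(rows$significant & rows$delta_Da < 0)
    if (pos && !neg) "increased"
    else if (neg && !pos) "decreased"
    else if (!pos && !neg) "ns"
    else "mixed"
  }, character(1))
  data.frame(peptide_start = key$peptide_start, peptide_end = key$peptide_end,
             peptide_class = cls, row.names = NULL)
}
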