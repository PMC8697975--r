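#' Degrees of freedom of the one-way layout
#'
#' For K groups with sizes n_i and N = sum(n_i) observations, the
#' between-group and within-group degrees of freedom are K - 1 and N - K.
#' With the study layout of four conditions of 72 trials each this is
#' (3, 284).
#'
#' @param group_sizes integer vector of group sizes (all >= 1, K >= 2).
#' @return named integer vector `c(df_between, df_within)`.
#' @export
group_dof <- function(group_sizes) {
  group_sizes <- as.integer(group_sizes)
  K <- length(group_sizes)
  if (K < 2L)
    stop_ftfa("need at least two groups", class = "ftfa_needs_two_groups_error")
  if (any(group_sizes < 1L))
    stop_ftfa("every group needs at least one observation",
              class = "ftfa_argument_error")
  N <- sum(group_sizes)
  if (N - K < 1L)
    stop_ftfa("insufficient replication: N - K must be >= 1",
              class = "ftfa_insufficient_replication_error")
  c(df_between = K - 1L, df_within = N - K)
}

check_grouped_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop_ftfa("need at least two groups", class = "ftfa_needs_two_groups_error")
  if (any(vapply(samples, length, 1L) < 1L))
    stop_ftfa("every group needs at least one sample", class = "ftfa_argument_error")
  invisible(samples)
}

#' Between-group variance (mean square) at one pixel
#'
#' `sum_i n_i * (mean_i - grand_mean)^2 / (K - 1)`: the variance of the
#' group means around the grand mean, weighted by group size. Zero exactly
#' when all group means coincide.
#'
#' @param samples list (one element per group) of numeric vectors of
#'   per-trial values at one pixel.
#' @return non-negative scalar.
#' @export
between_group_variance <- function(samples) {
  check_grouped_samples(samples)
  n_i <- vapply(samples, length, 1L)
  m_i <- vapply(samples, mean, 1)
  gm <- sum(n_i * m_i) / sum(n_i)
  sum(n_i * (m_i - gm)^2) / (length(samples) - 1L)
}

#' Within-group variance (mean square) at one pixel
#'
#' `sum_i sum_j (Y_ij - mean_i)^2 / (N - K)`: the pooled variance of the
#' samples around their own group means. Zero exactly when every group is
#' constant.
#'
#' @inheritParams between_group_variance
#' @return non-negative scalar.
#' @export
within_group_variance <- function(samples) {
  check_grouped_samples(samples)
  K <- length(samples)
  N <- sum(vapply(samples, length, 1L))
  if (N - K < 1L)
    stop_ftfa("insufficient replication: all groups are singletons",
              class = "ftfa_insufficient_replication_error")
  ss <- sum(vapply(samples, function(y) sum((y - mean(y))^2), 1))
  ss / (N - K)
}

#' One-way ANOVA F-value at one pixel
#'
#' The ratio between-group variance / within-group variance. Degenerate
#' conventions (documented, not errors): if the within-group variance is 0
#' and the between-group variance is positive the result is `Inf` (always
#' significant); if both are 0 (all samples identical) the result is 0.
#'
#' @inheritParams between_group_variance
#' @return non-negative scalar (possibly `Inf`).
#' @export
f_value <- function(samples) {
  b <- between_group_variance(samples)
  w <- within_group_variance(samples)
  if (w == 0) return(if (b > 0) Inf else 0)
  b / w
}

#' F-map: per-pixel ANOVA F across condition groups
#'
#' Applies the one-way F-statistic independently at every (channel,
#' frequency, time) pixel of a trial-wise TFR, using each pixel's per-trial
#' values as the ANOVA samples and the condition groups as the factor. By
#' convention the input is baseline-normalized power
#' ([baseline_normalize()]); raw power is accepted as well.
#'
#' @param tfr a `tfr_set` (trials x channels x freqs x times).
#' @param groups a `grouped_trials` partition of the trials (K >= 2 groups,
#'   each non-empty, N - K >= 1).
#' @return an object of class `ftf_map`: `f_values` (channels x freqs x
#'   times), `df_between`, `df_within`, `group_sizes`, `freqs`, `time_axis`,
#'   `channel_labels`, `montage`, `coi`.
#' @export
ftf_map <- function(tfr, groups) {
  stopifnot(inherits(tfr, "tfr_set"))
  d <- dim(tfr$power)
  n_trials <- d[1]
  idx_all <- unlist(groups, use.names = FALSE)
  if (any(idx_all < 1L | idx_all > n_trials))
    stop_ftfa("group references absent trial index", class = "ftfa_index_error")
  if (anyDuplicated(idx_all))
    stop_ftfa("trial assigned to more than one group", class = "ftfa_argument_error")
  n_i <- vapply(groups, length, 1L)
  dof <- group_dof(n_i)   # validates K >= 2, N - K >= 1
  K <- length(groups)
  P <- prod(d[2:4])
  Y <- tfr$power
  dim(Y) <- c(n_trials, P)                     # trials are the first dim
  ss_b <- numeric(P)
  ss_w <- numeric(P)
  gm <- colSums(Y[idx_all, , drop = FALSE]) / sum(n_i)
  for (g in seq_len(K)) {
    Yg <- Y[groups[[g]], , drop = FALSE]
    m_g <- colMeans(Yg)
    ss_b <- ss_b + n_i[g] * (m_g - gm)^2
    ss_w <- ss_w + colSums(sweep(Yg, 2L, m_g)^2)
  }
  b <- ss_b / dof[["df_between"]]
  w <- ss_w / dof[["df_within"]]
  f <- b / w
  f[w == 0 & b > 0] <- Inf
  f[w == 0 & b == 0] <- 0
  dim(f) <- d[2:4]
  structure(list(
    f_values = f,
    df_between = dof[["df_between"]], df_within = dof[["df_within"]],
    group_sizes = n_i, freqs = tfr$freqs, time_axis = tfr$time_axis,
    channel_labels = tfr$channel_labels, montage = tfr$montage,
    baseline_mode = tfr$baseline_mode, coi = tfr$coi),
    class = "ftf_map")
}

#' @export
print.ftf_map <- function(x, ...) {
  d <- dim(x$f_values)
  cat(sprintf("<ftf_map> %d channel(s) x %d freqs x %d times, df = (%d, %d)\n",
              d[1], d[2], d[3], x$df_between, x$df_within))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Upper-tail critical value of the F distribution
#'
#' The quantile q with `P(F_{df1, df2} > q) = alpha`. For the study layout
#' (alpha = 0.01, df 3 and 284) this is 3.851286.
#'
#' @param alpha upper-tail probability in (0, 1).
#' @param df_between,df_within degrees of freedom (>= 1).
#' @return scalar critical value.
#' @export
critical_f <- function(alpha, df_between, df_within) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_ftfa("alpha must be in (0, 1)", class = "ftfa_argument_error")
  if (df_between < 1 || df_within < 1)
    stop_ftfa("degrees of freedom must be >= 1", class = "ftfa_argument_error")
  qf(alpha, df_between, df_within, lower.tail = FALSE)
}

#' Significance mask for an F-map
#'
#' Thresholds an F-map at significance level `alpha`. `correction = "none"`
#' reproduces the single fixed-threshold comparison (pixel significant iff
#' `F > critical_f(alpha, df1, df2)`); `"bonferroni"` divides alpha by the
#' number of tested pixels; `"bh-fdr"` applies the Benjamini-Hochberg
#' step-up on per-pixel upper-tail p-values. Mass-univariate testing over
#' many pixels inflates family-wise error, which is why the corrections are
#' offered even though the uncorrected threshold is the default.
#'
#' @param map an `ftf_map`.
#' @param alpha significance level (default 0.01).
#' @param correction one of `"none"` (default), `"bonferroni"`, `"bh-fdr"`.
#' @return list with `mask` (logical array, same shape as the F-values),
#'   `threshold` (the F cutoff actually applied; for `"bh-fdr"` the smallest
#'   significant F, or `Inf` if nothing is significant), `alpha`,
#'   `correction`, and `n_tests`.
#' @export
significance_mask <- function(map, alpha = 0.01,
                              correction = c("none", "bonferroni", "bh-fdr")) {
  stopifnot(inherits(map, "ftf_map"))
  correction <- match.arg(correction)
  f <- map$f_values
  n_tests <- length(f)
  if (correction == "none") {
    thr <- critical_f(alpha, map$df_between, map$df_within)
    mask <- f > thr
  } else if (correction == "bonferroni") {
    thr <- critical_f(alpha / n_tests, map$df_between, map$df_within)
    mask <- f > thr
  } else {
    p <- pf(f, map$df_between, map$df_within, lower.tail = FALSE)
    mask <- array(p.adjust(p, method = "BH") <= alpha, dim = dim(f))
    thr <- if (any(mask)) min(f[mask]) else Inf
  }
  list(mask = mask, threshold = thr, alpha = alpha, correction = correction,
       n_tests = n_tests)
}

#' Element-wise mean of aligned F-maps
#'
#' Arithmetic mean of several F-maps with identical axes (e.g. per-subject
#' maps averaged for a grand map). Note that a mean of F-values no longer
#' follows an F distribution: on averaged maps a critical-value line is an
#' annotation, not an inferential threshold.
#'
#' @param maps list of `ftf_map` objects sharing channels, freqs and times.
#' @return an `ftf_map` whose `f_values` is the element-wise mean; the DOF
#'   metadata of the first map is retained with an `averaged_n` field.
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stop_ftfa("no maps to average", class = "ftfa_argument_error")
  if (inherits(maps, "ftf_map")) maps <- list(maps)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m$f_values), dim(ref$f_values)) ||
        !isTRUE(all.equal(m$freqs, ref$freqs)) ||
        !isTRUE(all.equal(m$time_axis, ref$time_axis)))
      stop_ftfa("maps have mismatched axes", class = "ftfa_axis_mismatch_error")
  }
  out <- ref
  out$f_values <- Reduce(`+`, lapply(maps, `[[`, "f_values")) / length(maps)
  out$averaged_n <- length(maps)
  out
}

#' Band-limited F-value topography over time windows
#'
#' For each requested time window and each channel, the mean F over the
#' frequency rows in `[f_lo, f_hi]` (band edges inclusive on the frequency
#' grid: 17-27 Hz on a 1 Hz grid averages 11 rows) and the time samples in
#' the window — the scalp-map view of an F-map in a rhythm band.
#'
#' @param map an `ftf_map`.
#' @param f_lo,f_hi band edges in Hz (inclusive).
#' @param windows list of numeric length-2 time windows (seconds, half-open
#'   `[t0, t1)` on the time axis).
#' @param montage data frame `label, x, y` covering the map's channels;
#'   defaults to the montage carried by the map.
#' @return list of `topography` objects, one per window, each with
#'   `channel_values` (named numeric), `positions`, `band`, `window`.
#' @export
band_topography <- function(map, f_lo, f_hi, windows, montage = NULL) {
  stopifnot(inherits(map, "ftf_map"))
  if (is.numeric(windows) && length(windows) == 2L) windows <- list(windows)
  montage <- validate_montage(montage %||% map$montage %||%
    stop_ftfa("no montage available", class = "ftfa_montage_error"))
  missing <- setdiff(map$channel_labels, montage$label)
  if (length(missing))
    stop_ftfa("montage lacks positions for channel(s): ",
              paste(missing, collapse = ", "), class = "ftfa_montage_error")
  fsel <- which(map$freqs >= f_lo & map$freqs <= f_hi)
  if (!length(fsel))
    stop_ftfa("empty frequency band after intersection with the grid",
              class = "ftfa_empty_selection_error")
  lapply(windows, function(w) {
    tsel <- which(map$time_axis >= w[1] & map$time_axis < w[2])
    if (!length(tsel))
      stop_ftfa(sprintf("empty time window [%g, %g)", w[1], w[2]),
                class = "ftfa_empty_selection_error")
    vals <- apply(map$f_values[, fsel, tsel, drop = FALSE], 1L, mean)
    names(vals) <- map$channel_labels
    pos <- montage[match(map$channel_labels, montage$label), ]
    structure(list(channel_values = vals, positions = pos,
                   band = c(f_lo, f_hi), window = as.numeric(w)),
              class = "topography")
  })
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography> band %g-%g Hz, window [%g, %g) s, %d channel(s)\n",
              x$band[1], x$band[2], x$window[1], x$window[2],
              length(x$channel_values)))
  print(round(x$channel_values, 3))
  invisible(x)
}
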