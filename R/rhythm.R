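#' Fisher chi-square combination of p-values
#'
#' Combines k p-values into one test via `X = -2 * sum(log(p))`, referred to
#' the upper tail of a chi-square distribution with `2k` degrees of freedom.
#' The combination is monotone: decreasing any input p never increases the
#' combined p. Inputs of exactly 0 are clamped to the smallest positive
#' representable value with a warning.
#'
#' @param p numeric vector of p-values in `(0, 1]` (k >= 1).
#' @param df degrees of freedom; default `2 * length(p)`.
#' @return The combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' fisher_combine(0.5)  # k = 1 identity
#' @export
fisher_combine <- function(p, df = 2 * length(p)) {
  if (length(p) < 1) stop("at least one p-value required", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = df, lower.tail = FALSE)
}

#' Rhythm-engine configuration
#'
#' Collects the tunable parameters of the periodicity engine. Defaults match
#' a 6 h sampling interval over a 30 h span: JTK candidate periods of 2-6
#' sampling intervals, a 12-48 h Lomb-Scargle scan, period groups 12/18/24/30 h
#' each +/- 3 h (half the time resolution), and significance thresholds of
#' 0.005 (stringent) and 0.05 (relaxed).
#'
#' @param periods_jtk JTK candidate periods (hours).
#' @param jtk_lag_step lag-scan step in hours (`NULL` = sampling interval).
#' @param ls_period_range Lomb-Scargle period range (hours).
#' @param ls_oversampling Lomb-Scargle frequency oversampling factor.
#' @param period_groups centers of the reported period groups (hours).
#' @param group_halfwidth half-width of each period group (hours).
#' @param p_strong stringent significance threshold on the combined p.
#' @param p_relaxed relaxed significance threshold on the combined p.
#' @param replicate_strategy `"replicates"` (default): per replicate the JTK
#'   and LS p-values are Fisher-combined (4 df), then combined across the k
#'   replicates with 2k df. `"methods"`: replicates are stacked as repeated
#'   time points, each method yields one p-value and the two are
#'   Fisher-combined with 4 df.
#' @return A `rhythm_config` list.
#' @export
rhythm_config <- function(periods_jtk = c(12, 18, 24, 30, 36),
                          jtk_lag_step = NULL,
                          ls_period_range = c(12, 48),
                          ls_oversampling = 10,
                          period_groups = c(12, 18, 24, 30),
                          group_halfwidth = 3,
                          p_strong = 0.005,
                          p_relaxed = 0.05,
                          replicate_strategy = c("replicates", "methods")) {
  structure(list(
    periods_jtk = periods_jtk, jtk_lag_step = jtk_lag_step,
    ls_period_range = ls_period_range, ls_oversampling = ls_oversampling,
    period_groups = period_groups, group_halfwidth = group_halfwidth,
    p_strong = p_strong, p_relaxed = p_relaxed,
    replicate_strategy = match.arg(replicate_strategy)
  ), class = "rhythm_config")
}

#' Assign a fitted period to a period group
#'
#' A mean period is assigned to group g in `groups` when `|period - g|` is at
#' most `halfwidth`; values outside every window get no group (`NA`). With the
#' default 12/18/24/30 h centers and 3 h half-width, windows touch at exact
#' midpoints (15, 21, 27 h), which are assigned to the lower center.
#'
#' @param period_mean fitted mean period in hours (may be `NA`).
#' @param groups group centers.
#' @param halfwidth window half-width in hours.
#' @return The group center, or `NA_real_` for no group.
#' @examples
#' assign_period_group(13.4)  # 12
#' assign_period_group(33.5)  # NA (outside 30 +/- 3)
#' @export
assign_period_group <- function(period_mean, groups = c(12, 18, 24, 30),
                                halfwidth = 3) {
  if (is.na(period_mean)) return(NA_real_)
  d <- abs(period_mean - groups)
  i <- which.min(d)  # ties resolve to the lower center
  if (d[i] > halfwidth + 1e-9) return(NA_real_)
  groups[i]
}

#' Assign a fitted phase to a phase quadrant
#'
#' The phase of the first maximum, expressed as an angle `2*pi*phase_h/period`,
#' is snapped to the nearest of the four quadrants 0, pi/2, pi, -pi/2
#' (= 3*pi/2). For the 12 h period group, sampled at 6 h resolution, the two
#' quadrature phases are unresolvable (see [jtk_cycle()]), so only 0 and pi
#' are reported.
#'
#' @param phase_h phase in hours, `0 <= phase_h < period` (may be `NA`).
#' @param period period in hours.
#' @param period_group the assigned period group (used to restrict the 12 h
#'   group to 0/pi); `NA` applies no restriction.
#' @return One of `"0"`, `"pi/2"`, `"pi"`, `"-pi/2"`, or `"none"`.
#' @examples
#' assign_phase_group(6, 24)   # "pi/2"
#' assign_phase_group(12, 24)  # "pi"
#' @export
assign_phase_group <- function(phase_h, period, period_group = NA_real_) {
  if (is.na(phase_h) || is.na(period)) return("none")
  ang <- (2 * pi * phase_h / period) %% (2 * pi)
  centers <- c(0, pi / 2, pi, 3 * pi / 2)
  labels <- c("0", "pi/2", "pi", "-pi/2")
  if (!is.na(period_group) && period_group == 12) {
    centers <- c(0, pi)
    labels <- c("0", "pi")
  }
  d <- abs(ang - centers)
  d <- pmin(d, 2 * pi - d)  # circular distance
  labels[which.min(d)]
}

#' Z-score normalization of a series
#'
#' `(x - mean(x)) / sd(x)`; a constant series maps to all zeros.
#'
#' @param x numeric vector (>= 2 values).
#' @return The normalized vector.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2) stop("zscore_normalize requires >= 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Least-squares cosine fit at a fixed period on (times, values):
# x ~ base + A * cos(2*pi*(t - phase)/P). Returns amplitude, phase of first
# maximum in [0, P), and base level.
cosine_fit <- function(values, times_h, period) {
  ct <- cos(2 * pi * times_h / period)
  st <- sin(2 * pi * times_h / period)
  fit <- stats::lm.fit(cbind(1, ct, st), values)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  phase_h <- if (amplitude == 0) 0 else (period * atan2(b[3], b[2]) / (2 * pi)) %% period
  list(amplitude = unname(amplitude), phase_h = unname(phase_h),
       base = unname(b[1]))
}

#' Meta-fit: combined JTK + Lomb-Scargle rhythm detection with replicates
#'
#' Runs the two detection methods on a replicated series and combines their
#' evidence by Fisher's method. Under the default `"replicates"` strategy,
#' each replicate's `{p_jtk, p_ls}` pair is combined first (4 df), then the k
#' per-replicate p-values are combined with 2k df. Under `"methods"`, the
#' replicates are stacked as repeated time points and the two method p-values
#' are combined with 4 df. The reported method periods are means across
#' replicates, the mean period is the mean of the JTK and LS periods, and
#' amplitude/phase come from a post-hoc least-squares cosine fit at the mean
#' period on the replicate-averaged values, with the phase reported as the
#' time of the first maximum in `[0, period_mean)`.
#'
#' @param series numeric matrix (replicates in rows, time points in columns)
#'   or a vector for a single replicate.
#' @param grid a [time_grid()] whose `times_h` match the columns.
#' @param config a [rhythm_config()].
#' @param series_id identifier carried into the result.
#' @return A one-row tibble with fields `series_id`, `p_jtk`, `p_ls`,
#'   `p_combined`, `period_jtk`, `period_ls`, `period_mean`, `phase_h`,
#'   `amplitude`, `base`, `period_group` (numeric, `NA` = none),
#'   `phase_group`.
#' @export
meta_fit <- function(series, grid, config = rhythm_config(),
                     series_id = NA_character_) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  if (!is.matrix(series) || !is.numeric(series)) {
    stop("series must be a numeric matrix (replicates x time points)",
         call. = FALSE)
  }
  times <- grid$times_h
  if (ncol(series) != length(times)) {
    stop("series columns must match grid times", call. = FALSE)
  }
  R <- nrow(series)

  run_jtk <- function(v, t) {
    jtk_cycle(v, t, periods = config$periods_jtk,
              lag_step = config$jtk_lag_step)
  }
  run_ls <- function(v, t) {
    lomb_scargle(v, t, period_range = config$ls_period_range,
                 oversampling = config$ls_oversampling)
  }

  if (config$replicate_strategy == "replicates") {
    jtk <- lapply(seq_len(R), function(r) run_jtk(series[r, ], times))
    ls <- lapply(seq_len(R), function(r) run_ls(series[r, ], times))
    p_rep <- vapply(seq_len(R), function(r) {
      fisher_combine(c(jtk[[r]]$p, ls[[r]]$p))
    }, numeric(1))
    p_combined <- fisher_combine(p_rep, df = 2 * R)
    p_jtk_all <- vapply(jtk, `[[`, numeric(1), "p")
    p_ls_all <- vapply(ls, `[[`, numeric(1), "p")
    p_jtk <- fisher_combine(p_jtk_all, df = 2 * R)
    p_ls <- fisher_combine(p_ls_all, df = 2 * R)
    per_jtk_all <- vapply(jtk, `[[`, numeric(1), "period")
    per_ls_all <- vapply(ls, `[[`, numeric(1), "period")
  } else {
    ord <- order(rep(times, each = R))
    t_stack <- rep(times, each = R)[ord]
    v_stack <- as.vector(series)[ord]  # column-major: replicates within CT
    jtk1 <- run_jtk(v_stack, t_stack)
    ls1 <- run_ls(v_stack, t_stack)
    p_jtk <- jtk1$p
    p_ls <- ls1$p
    p_combined <- fisher_combine(c(p_jtk, p_ls))
    per_jtk_all <- jtk1$period
    per_ls_all <- ls1$period
  }

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  period_jtk <- mean_or_na(per_jtk_all)
  period_ls <- mean_or_na(per_ls_all)
  period_mean <- mean_or_na(c(period_jtk, period_ls))

  if (!is.na(period_mean)) {
    cf <- cosine_fit(colMeans(series), times, period_mean)
  } else {
    cf <- list(amplitude = NA_real_, phase_h = NA_real_, base = mean(series))
  }
  pg <- assign_period_group(period_mean, groups = config$period_groups,
                            halfwidth = config$group_halfwidth)
  tibble::tibble(
    series_id = series_id,
    p_jtk = p_jtk, p_ls = p_ls, p_combined = p_combined,
    period_jtk = period_jtk, period_ls = period_ls, period_mean = period_mean,
    phase_h = cf$phase_h, amplitude = cf$amplitude, base = cf$base,
    period_group = pg,
    phase_group = assign_phase_group(cf$phase_h, period_mean, pg)
  )
}

period_group_label <- function(g) ifelse(is.na(g), "none",
                                         format(g, trim = TRUE))

#' Fit rhythms to every variable LAD border
#'
#' Convenience wrapper applying [meta_fit()] to each (lad_id, side) series of
#' a border-series table (see [border_series()]), using the replicate
#' structure of the grid.
#'
#' @param series border-series tibble (`lad_id`, `side`, `ct`, `replicate`,
#'   `time_h`, `value`).
#' @param grid a [time_grid()].
#' @param config a [rhythm_config()].
#' @return A tibble of [meta_fit()] rows with `lad_id` and `side` columns;
#'   `series_id` is `"<lad_id>:<side>"`.
#' @export
fit_border_rhythms <- function(series, grid, config = rhythm_config()) {
  keys <- unique(series[, c("lad_id", "side")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- series[series$lad_id == keys$lad_id[i] & series$side == keys$side[i], ]
    m <- series_to_matrix(sub, grid)
    cbind(tibble::tibble(lad_id = keys$lad_id[i], side = keys$side[i]),
          meta_fit(m, grid, config,
                   series_id = paste0(keys$lad_id[i], ":", keys$side[i])))
  })
  out <- do.call(rbind, rows)
  tibble::as_tibble(out)
}

# Long border/expression series -> replicates x time points matrix on the grid.
series_to_matrix <- function(sub, grid) {
  m <- matrix(NA_real_, nrow = length(grid$replicates),
              ncol = length(grid$ct_labels),
              dimnames = list(grid$replicates, grid$ct_labels))
  i <- match(sub$replicate, grid$replicates)
  j <- match(sub$ct, grid$ct_labels)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- sub$value[ok]
  if (anyNA(m)) {
    stop("incomplete series: every (CT, replicate) cell needs a value",
         call. = FALSE)
  }
  m
}
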