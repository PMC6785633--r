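#' Random permutations of the circadian time order
#'
#' Draws `n` distinct permutations of the CT order, none equal to the
#' identity, to be applied globally (the same permutations for every LAD
#' border) in the randomization test. Replicate pairing within each CT is
#' preserved: only the CT labels are reordered.
#'
#' @param grid a [time_grid()] with at least 3 CTs.
#' @param n number of permutations (default 3).
#' @param seed integer seed; the same seed yields the same permutations.
#' @return A list of `n` integer permutation vectors of
#'   `seq_along(grid$ct_labels)`.
#' @export
shuffle_ct_orders <- function(grid, n = 3, seed = 1) {
  k <- length(grid$ct_labels)
  if (k < 3) stop("randomization requires >= 3 CTs", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  available <- factorial(k) - 1
  if (n > available) {
    stop(sprintf("only %d non-identity permutations exist for %d CTs",
                 available, k), call. = FALSE)
  }
  withr::with_seed(seed, {
    perms <- list()
    seen <- character()
    tries <- 0
    while (length(perms) < n) {
      tries <- tries + 1
      if (tries > 100000) stop("failed to draw distinct permutations",
                               call. = FALSE)
      p <- sample.int(k)
      key <- paste(p, collapse = ",")
      if (identical(p, seq_len(k)) || key %in% seen) next
      seen <- c(seen, key)
      perms[[length(perms) + 1]] <- p
    }
    perms
  })
}

# Core verdict rule: experimental periodicity is considered imposed by the
# CT order when it differs from the outcome of at least `min_discordant`
# randomized orders. "Different" compares period-group labels (including
# significant -> none transitions). A non-significant experimental series
# has no periodicity to validate and never passes.
verdict_from_groups <- function(experimental_group, shuffle_groups,
                                min_discordant = 2) {
  exp_lab <- period_group_label(experimental_group)
  sh_lab <- vapply(shuffle_groups, period_group_label, character(1))
  n_discordant <- sum(sh_lab != exp_lab)
  passes <- exp_lab != "none" && n_discordant >= min_discordant
  list(n_discordant = n_discordant, passes = passes)
}

#' Randomization verdict for one border series
#'
#' Re-fits a border series under each shuffled CT order and compares the
#' resulting period groups with the experimental one. The significant period
#' group (combined p below `threshold`) of each fit is recorded, `"none"`
#' otherwise. The verdict passes when the experimental series is itself
#' significant and at least `min_discordant` shuffled orders disagree with
#' its group, indicating that the periodicity is imposed by the order of CTs
#' rather than by random lamin-chromatin interactions. The permuted series
#' contain exactly the same values as the original, only in a different CT
#' order, and the verdict is deterministic given the permutations.
#'
#' @param series replicates x time points matrix (or vector) of one border
#'   series.
#' @param grid a [time_grid()].
#' @param permutations list of CT-order permutations from
#'   [shuffle_ct_orders()].
#' @param config a [rhythm_config()].
#' @param threshold significance threshold for calling a period group
#'   (default the relaxed threshold of `config`).
#' @param min_discordant shuffles that must disagree (default 2).
#' @param series_id identifier carried into the result.
#' @return A one-row tibble: `series_id`, `experimental_group`,
#'   `shuffle_groups` (comma-separated labels), `n_shuffles`,
#'   `n_discordant`, `passes`, `p_combined`.
#' @export
randomization_verdict <- function(series, grid, permutations,
                                  config = rhythm_config(),
                                  threshold = config$p_relaxed,
                                  min_discordant = 2,
                                  series_id = NA_character_) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  significant_group <- function(fit) {
    if (fit$p_combined < threshold) fit$period_group else NA_real_
  }
  exp_fit <- meta_fit(series, grid, config, series_id = series_id)
  exp_group <- significant_group(exp_fit)
  sh_groups <- vapply(permutations, function(p) {
    significant_group(meta_fit(series[, p, drop = FALSE], grid, config))
  }, numeric(1))
  v <- verdict_from_groups(exp_group, as.list(sh_groups), min_discordant)
  tibble::tibble(
    series_id = series_id,
    experimental_group = period_group_label(exp_group),
    shuffle_groups = paste(vapply(sh_groups, period_group_label,
                                  character(1)), collapse = ","),
    n_shuffles = length(permutations),
    n_discordant = v$n_discordant,
    passes = v$passes,
    p_combined = exp_fit$p_combined
  )
}

#' Randomization test over all significant LAD borders
#'
#' Applies [randomization_verdict()] with one global set of CT-order
#' permutations to each (lad_id, side) series of a border-series table.
#'
#' @param series border-series tibble (see [border_series()]).
#' @param grid a [time_grid()].
#' @param config a [rhythm_config()].
#' @param n_shuffles number of shuffled CT orders (default 3).
#' @param seed seed for [shuffle_ct_orders()].
#' @param threshold significance threshold for the period-group calls.
#' @param min_discordant shuffles that must disagree for a pass.
#' @return A tibble of verdicts with `lad_id` and `side` columns.
#' @export
randomize_borders <- function(series, grid, config = rhythm_config(),
                              n_shuffles = 3, seed = 1,
                              threshold = config$p_relaxed,
                              min_discordant = 2) {
  perms <- shuffle_ct_orders(grid, n = n_shuffles, seed = seed)
  keys <- unique(series[, c("lad_id", "side")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- series[series$lad_id == keys$lad_id[i] & series$side == keys$side[i], ]
    m <- series_to_matrix(sub, grid)
    cbind(tibble::tibble(lad_id = keys$lad_id[i], side = keys$side[i]),
          randomization_verdict(m, grid, perms, config, threshold,
                                min_discordant,
                                series_id = paste0(keys$lad_id[i], ":",
                                                   keys$side[i])))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
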