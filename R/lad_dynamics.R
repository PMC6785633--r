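#' Circadian time grid
#'
#' Describes the sampling design of the time course: ordered circadian time
#' (CT) labels, their times in hours, and the replicate labels present at
#' each CT. The default grid is CT0..CT30 at 6 h spacing with two biological
#' replicates, the design used for LAD time courses. A non-synchronized (NS)
#' sample, when present, lives outside the grid and is excluded from rhythm
#' fitting.
#'
#' @param ct_labels ordered CT names.
#' @param times_h hours for each CT; must be strictly increasing.
#' @param replicates replicate labels (shared by all CTs).
#' @return A `time_grid` list with elements `ct_labels`, `times_h`,
#'   `replicates`.
#' @examples
#' time_grid()
#' @export
time_grid <- function(ct_labels = paste0("CT", seq(0, 30, by = 6)),
                      times_h = seq(0, 30, by = 6),
                      replicates = c("r1", "r2")) {
  if (length(ct_labels) != length(times_h)) {
    stop("ct_labels and times_h must have the same length", call. = FALSE)
  }
  if (any(diff(times_h) <= 0)) {
    stop("times_h must be strictly increasing", call. = FALSE)
  }
  if (anyDuplicated(ct_labels)) stop("duplicated CT labels", call. = FALSE)
  structure(list(ct_labels = as.character(ct_labels),
                 times_h = as.numeric(times_h),
                 replicates = as.character(replicates)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d CTs (%s h), replicates: %s\n",
              length(x$ct_labels), paste(x$times_h, collapse = ", "),
              paste(x$replicates, collapse = ", ")))
  invisible(x)
}

sample_name <- function(ct, rep) paste(ct, rep, sep = "_")

grid_samples <- function(grid) {
  as.vector(t(outer(grid$ct_labels, grid$replicates, sample_name)))
}

check_lad_sets <- function(lad_sets, grid = NULL) {
  if (!is.list(lad_sets) || is.null(names(lad_sets)) ||
      any(!nzchar(names(lad_sets)))) {
    stop("lad_sets must be a named list of lad_set objects (\"<CT>_<rep>\")",
         call. = FALSE)
  }
  for (nm in names(lad_sets)) assert_lad_set(lad_sets[[nm]], nm)
  if (!is.null(grid)) {
    missing <- setdiff(grid_samples(grid), names(lad_sets))
    if (length(missing) > 0) {
      stop("lad_sets missing samples: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(lad_sets)
}

#' Maximal LAD footprints (cov_max) across the time course
#'
#' The maximal coverage (cov_max) of a LAD is the union of its coverage
#' across all replicates and CTs. Each merged region of the genome-wide
#' union becomes one cov_max record with a reference value of 1 for border
#' standardization; records are disjoint by construction and identifiers are
#' assigned in (chrom, start) order.
#'
#' @param lad_sets named list of `lad_set` objects, one per (CT, replicate);
#'   an NS (non-synchronized) sample should not be included.
#' @return A tibble with columns `lad_id`, `chrom`, `start`, `end`,
#'   `length_bp`, ordered by (chrom, start).
#' @export
compute_covmax <- function(lad_sets) {
  check_lad_sets(lad_sets)
  if (length(lad_sets) == 0) stop("at least one sample required", call. = FALSE)
  all_iv <- do.call(rbind, lapply(lad_sets, function(s) {
    tibble::tibble(chrom = s$chrom, start = s$start, end = s$end)
  }))
  u <- normalize_lads(lad_set(all_iv$chrom, all_iv$start, all_iv$end,
                              label = "cov_max"))
  ord <- order(u$chrom, u$start)
  u <- u[ord, ]
  tibble::tibble(
    lad_id = sprintf("LAD%04d", seq_len(nrow(u))),
    chrom = u$chrom, start = u$start, end = u$end,
    length_bp = u$end - u$start
  )
}

covmax_granges <- function(covmax, seqlevels = NULL) {
  lv <- unique(c(seqlevels, covmax$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(covmax$chrom, levels = lv),
    ranges = IRanges::IRanges(start = covmax$start + 1, end = covmax$end)
  )
}

#' Standardized 5'/3' LAD border series
#'
#' For each cov_max record and each (CT, replicate) sample, locates the
#' sample's LAD fragments inside the cov_max region `[S, E)` of length `L`
#' and standardizes the two borders to `[0, 1]`: with `a` the leftmost
#' fragment start and `b` the rightmost fragment end,
#' `rel5 = 1 - (a - S)/L` and `rel3 = 1 - (E - b)/L`. A value of 1 means the
#' border reaches the cov_max limit, 0 means the LAD is absent from that
#' sample. Internal splits or fusions between `a` and `b` are deliberately
#' ignored: only the outermost extremities enter the series. 5' is the lower
#' genomic coordinate (reference-strand convention; LADs are unstranded).
#'
#' @param covmax tibble from [compute_covmax()].
#' @param lad_sets named list of `lad_set` objects (`"<CT>_<rep>"`).
#' @param grid a [time_grid()]; only samples on the grid are used.
#' @return A tibble with columns `lad_id`, `side` (`"5p"`/`"3p"`), `ct`,
#'   `replicate`, `time_h`, `value`.
#' @export
border_series <- function(covmax, lad_sets, grid) {
  check_lad_sets(lad_sets, grid)
  cm_gr <- covmax_granges(covmax)
  out <- vector("list", length(grid$ct_labels) * length(grid$replicates))
  k <- 0
  for (i in seq_along(grid$ct_labels)) {
    for (rep in grid$replicates) {
      ct <- grid$ct_labels[i]
      s <- lad_sets[[sample_name(ct, rep)]]
      a <- rep(NA_real_, nrow(covmax))
      b <- rep(NA_real_, nrow(covmax))
      if (nrow(s) > 0) {
        s_gr <- as_granges(s, seqlevels = covmax$chrom)
        ov <- GenomicRanges::findOverlaps(s_gr, cm_gr)
        if (length(ov) > 0) {
          qh <- S4Vectors::queryHits(ov)
          sh <- S4Vectors::subjectHits(ov)
          frag_s <- s$start[qh]
          frag_e <- s$end[qh]
          outside <- frag_s < covmax$start[sh] | frag_e > covmax$end[sh]
          if (any(outside)) {
            stop(sprintf(
              "sample %s has a fragment outside its cov_max region (%s:%s-%s)",
              sample_name(ct, rep), s$chrom[qh[which(outside)[1]]],
              frag_s[which(outside)[1]], frag_e[which(outside)[1]]),
              call. = FALSE)
          }
          a_min <- tapply(frag_s, sh, min)
          b_max <- tapply(frag_e, sh, max)
          ids <- as.integer(names(a_min))
          a[ids] <- as.numeric(a_min)
          b[ids] <- as.numeric(b_max)
        }
      }
      L <- covmax$length_bp
      rel5 <- ifelse(is.na(a), 0, 1 - (a - covmax$start) / L)
      rel3 <- ifelse(is.na(b), 0, 1 - (covmax$end - b) / L)
      k <- k + 1
      out[[k]] <- tibble::tibble(
        lad_id = rep(covmax$lad_id, 2),
        side = rep(c("5p", "3p"), each = nrow(covmax)),
        ct = ct, replicate = rep, time_h = grid$times_h[i],
        value = c(rel5, rel3)
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$lad_id, covmax$lad_id), res$side == "3p",
            res$time_h, res$replicate), ]
}

#' Decompose LAD gains and losses between two samples
#'
#' Compares a reference and a comparison interval set (typically the
#' replicate intersects of the non-synchronized sample and CT0). Gained
#' regions (`comparison \ reference`) are classified `stand-alone` when the
#' comparison LAD containing them has no overlap with the reference (a LAD
#' formed de novo) and `extension` otherwise; lost regions
#' (`reference \ comparison`) are `stand-alone` when the reference LAD
#' containing them vanished entirely, and `shortening` otherwise. A gained
#' region merely book-ended to a reference LAD counts as an extension.
#'
#' @param reference,comparison normalized `lad_set` objects.
#' @return A tibble with columns `chrom`, `start`, `end`, `direction`
#'   (`gained`/`lost`), `mode` (`stand-alone`/`extension`/`shortening`),
#'   `bp`.
#' @export
classify_gain_loss <- function(reference, comparison) {
  assert_lad_set(reference, "reference")
  assert_lad_set(comparison, "comparison")
  reference <- normalize_lads(reference)
  comparison <- normalize_lads(comparison)

  one_direction <- function(from, against, direction, touched_mode) {
    regions <- subtract_lads(against, from)
    if (nrow(regions) == 0) return(NULL)
    lv <- unique(c(against$chrom, from$chrom))
    reg_gr <- as_granges(regions, seqlevels = lv)
    own_gr <- as_granges(against, seqlevels = lv)
    other_gr <- as_granges(from, seqlevels = lv)
    ov <- GenomicRanges::findOverlaps(reg_gr, own_gr, type = "within")
    container <- rep(NA_integer_, nrow(regions))
    container[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    if (anyNA(container)) {
      stop("internal error: differential region not contained in a LAD",
           call. = FALSE)
    }
    # overlap of containing LADs with the other sample: >0 bp => not stand-alone
    touched <- GenomicRanges::countOverlaps(own_gr, other_gr) > 0
    tibble::tibble(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      direction = direction,
      mode = ifelse(touched[container], touched_mode, "stand-alone"),
      bp = regions$end - regions$start
    )
  }

  out <- rbind(
    one_direction(reference, comparison, "gained", "extension"),
    one_direction(comparison, reference, "lost", "shortening")
  )
  if (is.null(out)) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), direction = character(),
                          mode = character(), bp = numeric())
  }
  out
}

#' Summarize gain/loss bp totals per (direction, mode)
#'
#' @param gl tibble from [classify_gain_loss()].
#' @return Tibble with `direction`, `mode`, `bp`.
#' @export
gain_loss_summary <- function(gl) {
  if (nrow(gl) == 0) {
    return(tibble::tibble(direction = character(), mode = character(),
                          bp = numeric()))
  }
  agg <- stats::aggregate(bp ~ direction + mode, data = as.data.frame(gl), sum)
  tibble::as_tibble(agg[order(agg$direction, agg$mode), ])
}

#' Descriptive LAD statistics per sample
#'
#' Per interval set: total genome coverage in bp, LAD count, and median LAD
#' size. Empty sets report a count of 0 and `NA` median.
#'
#' @param lad_sets named list of normalized `lad_set` objects (typically the
#'   replicate intersects at each CT).
#' @return Tibble with `sample`, `n_lads`, `coverage_bp`, `median_size_bp`.
#' @export
lad_stats <- function(lad_sets) {
  check_lad_sets(lad_sets)
  rows <- lapply(names(lad_sets), function(nm) {
    s <- lad_sets[[nm]]
    sizes <- s$end - s$start
    tibble::tibble(
      sample = nm, n_lads = nrow(s), coverage_bp = coverage_bp(s),
      median_size_bp = if (nrow(s) == 0) NA_real_ else stats::median(sizes)
    )
  })
  do.call(rbind, rows)
}

#' Replicate intersects of LAD calls at each CT
#'
#' LADs are analyzed at each time point as the base-pair intersect between
#' replicates, which suppresses replicate-private calls.
#'
#' @param lad_sets named list of `lad_set` objects (`"<CT>_<rep>"`).
#' @param grid a [time_grid()].
#' @param cts CT labels to intersect; defaults to the grid's CTs. Extra
#'   labels (e.g. `"NS"`) may be given if the corresponding samples exist.
#' @return Named list of normalized `lad_set` objects, one per CT.
#' @export
replicate_intersects <- function(lad_sets, grid, cts = grid$ct_labels) {
  check_lad_sets(lad_sets)
  out <- lapply(cts, function(ct) {
    sets <- lapply(grid$replicates, function(r) {
      nm <- sample_name(ct, r)
      if (is.null(lad_sets[[nm]])) {
        stop("missing sample for replicate intersect: ", nm, call. = FALSE)
      }
      normalize_lads(lad_sets[[nm]])
    })
    Reduce(function(a, b) intersect_lads(a, b, label = ct), sets)
  })
  names(out) <- cts
  out
}

#' Select variable LAD borders
#'
#' Restricts border series to those with appreciable variation across the
#' time course, the set that is worth submitting to rhythm detection. The
#' variability criterion is a minimum standard deviation of the standardized
#' border values over all (CT, replicate) observations; the default keeps
#' every border that varies at all (`sd > min_sd` with `min_sd = 0`).
#'
#' @param series border-series tibble from [border_series()].
#' @param min_sd minimum standard deviation (strict) of `value` per
#'   (lad_id, side).
#' @return The filtered series tibble.
#' @export
filter_variable_borders <- function(series, min_sd = 0) {
  key <- paste(series$lad_id, series$side)
  sds <- tapply(series$value, key, stats::sd)
  keep_keys <- names(sds)[!is.na(sds) & sds > min_sd]
  series[key %in% keep_keys, ]
}
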