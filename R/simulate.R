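## Synthetic-data module: toy genomes, LAD time courses with injected border
## rhythms, and FPKM matrices with known labels. All generators take explicit
## seeds and are deterministic.

round_half_up <- function(x) floor(x + 0.5)

#' Generate a toy genome with base LADs and stranded genes
#'
#' Lays out non-overlapping base LADs on each chromosome and places genes
#' with recorded ground-truth positions: `inside` a LAD, `near` a LAD border
#' (within `near_window_bp`, outside every LAD), or `far` (at least
#' `far_min_bp` from every LAD). To guarantee feasible placement, LADs are
#' confined to the first 60% of each chromosome and far genes to the distal
#' region beyond `far_min_bp` of the last LAD.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_lads total number of base LADs (distributed across chromosomes).
#' @param n_genes total number of genes.
#' @param seed integer seed.
#' @param lad_size_range LAD size range in bp (sizes drawn uniformly).
#' @param gene_size_range gene size range in bp.
#' @param near_window_bp window that defines "near" placements.
#' @param far_min_bp minimum distance of "far" genes from any LAD.
#' @param placement_weights relative numbers of inside/near/far genes.
#' @return A list: `genome` (tibble `chrom`, `length`), `base_lads` (tibble
#'   `lad_id`, `chrom`, `start`, `end`, `length_bp`), `genes` (tibble
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, `placement`).
#' @export
generate_genome <- function(n_chroms = 2, chrom_length = 6e7, n_lads = 20,
                            n_genes = 90, seed = 1,
                            lad_size_range = c(2e5, 8e5),
                            gene_size_range = c(5e3, 5e4),
                            near_window_bp = 2.5e6, far_min_bp = 5e6,
                            placement_weights = c(inside = 1, near = 1,
                                                  far = 1)) {
  chroms <- paste0("chr", seq_len(n_chroms))
  lad_zone_end <- round(0.6 * chrom_length)
  per_chrom <- diff(round(seq(0, n_lads, length.out = n_chroms + 1)))
  withr::with_seed(seed, {
    lad_rows <- list()
    for (ci in seq_len(n_chroms)) {
      k <- per_chrom[ci]
      if (k == 0) next
      sizes <- round(stats::runif(k, lad_size_range[1], lad_size_range[2]))
      if (sum(sizes) + (k + 1) * 1e4 > lad_zone_end) {
        stop("infeasible packing: requested LAD bp exceeds available genome",
             call. = FALSE)
      }
      free <- lad_zone_end - sum(sizes)
      cuts <- sort(stats::runif(k, 0, 1))
      gaps <- round(diff(c(0, cuts)) * free)
      starts <- cumsum(gaps) + cumsum(c(0, sizes[-k]))
      lad_rows[[ci]] <- tibble::tibble(chrom = chroms[ci], start = starts,
                                       end = starts + sizes)
    }
    if (length(lad_rows) > 0) {
      base <- do.call(rbind, lad_rows)
      base <- base[order(base$chrom, base$start), ]
      base_lads <- tibble::tibble(
        lad_id = sprintf("LAD%04d", seq_len(nrow(base))),
        chrom = base$chrom, start = base$start, end = base$end,
        length_bp = base$end - base$start
      )
    } else {
      base_lads <- tibble::tibble(lad_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  length_bp = numeric())
    }

    w <- placement_weights / sum(placement_weights)
    n_inside <- if (nrow(base_lads) == 0) 0 else round(n_genes * w[["inside"]])
    n_near <- if (nrow(base_lads) == 0) 0 else round(n_genes * w[["near"]])
    n_far <- n_genes - n_inside - n_near

    overlaps_lad <- function(chrom, s, e, margin = 0) {
      any(base_lads$chrom == chrom & base_lads$start - margin < e &
            base_lads$end + margin > s)
    }
    place <- function(kind) {
      width <- round(stats::runif(1, gene_size_range[1], gene_size_range[2]))
      for (try in 1:200) {
        if (kind == "inside") {
          cand <- base_lads[base_lads$length_bp > width + 2, ]
          if (nrow(cand) == 0) break
          L <- cand[sample.int(nrow(cand), 1), ]
          s <- L$start + round(stats::runif(1, 1, L$length_bp - width - 1))
          return(c(L$chrom, s, s + width))
        } else if (kind == "near") {
          L <- base_lads[sample.int(nrow(base_lads), 1), ]
          off <- round(stats::runif(1, 1, near_window_bp - width - 1))
          s <- if (stats::runif(1) < 0.5) L$start - off - width else L$end + off
          if (s < 0 || s + width > chrom_length) next
          if (!overlaps_lad(L$chrom, s, s + width)) return(c(L$chrom, s, s + width))
        } else {
          chrom <- chroms[sample.int(n_chroms, 1)]
          zone_lo <- if (any(base_lads$chrom == chrom)) {
            max(base_lads$end[base_lads$chrom == chrom]) + far_min_bp
          } else 0
          if (zone_lo + width >= chrom_length) next
          s <- round(stats::runif(1, zone_lo, chrom_length - width - 1))
          if (!overlaps_lad(chrom, s, s + width, margin = far_min_bp)) {
            return(c(chrom, s, s + width))
          }
        }
      }
      stop("failed to place a '", kind, "' gene; genome too crowded",
           call. = FALSE)
    }
    kinds <- rep(c("inside", "near", "far"), c(n_inside, n_near, n_far))
    placed <- lapply(kinds, place)
    strand <- sample(c("+", "-"), length(kinds), replace = TRUE)
    genes <- tibble::tibble(
      gene_id = sprintf("gene%04d", seq_along(kinds)),
      chrom = vapply(placed, `[[`, character(1), 1),
      start = as.numeric(vapply(placed, `[[`, character(1), 2)),
      end = as.numeric(vapply(placed, `[[`, character(1), 3)),
      strand = strand,
      placement = kinds
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    genes <- genes[order(genes$chrom, genes$start), ]
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss",
                       "placement")]
    list(
      genome = tibble::tibble(chrom = chroms, length = chrom_length),
      base_lads = base_lads,
      genes = genes
    )
  })
}

#' Border-dynamics specifications for a set of base LADs
#'
#' One row per (LAD, side) describing how that border's standardized relative
#' length evolves: `constant` (fixed at `baseline`), `noise` (baseline plus
#' Gaussian noise), or `cosine`
#' (`rel(t) = clamp(baseline + amplitude*cos(2*pi*(t - phase)/period) + eps, 0, 1)`).
#' An optional per-LAD gate makes the whole LAD appear and disappear: the LAD
#' is absent at CTs where `cos(2*pi*(t - gate_phase)/gate_period)` falls
#' below `gate_threshold`.
#'
#' `default_lad_scenario()` builds a study-like mixture: a fraction of LADs
#' carry a cosine 5' border (periods cycling through `periods`, amplitude
#' 0.4, baseline 0.5, replicate noise sd 0.05) with the 3' border fixed at
#' the cov_max limit, a fraction carry pure-noise borders, a fraction are
#' fully constant, and a small fraction appear/disappear under a 24 h gate.
#'
#' @param base_lads base-LAD tibble from [generate_genome()].
#' @param periodic_fraction,noise_fraction,gate_fraction mixture fractions
#'   (the remainder is constant LADs).
#' @param periods periods injected into cosine borders, recycled.
#' @param amplitude,baseline,noise_sd cosine-border parameters.
#' @param seed seed used to assign phases.
#' @return A list with `sides` (tibble `lad_id`, `side`, `mode`, `baseline`,
#'   `period_h`, `phase_h`, `amplitude`, `noise_sd`) and `gates` (tibble
#'   `lad_id`, `gate_mode`, `gate_period_h`, `gate_phase_h`,
#'   `gate_threshold`).
#' @export
default_lad_scenario <- function(base_lads, periodic_fraction = 0.5,
                                 noise_fraction = 0.2, gate_fraction = 0.1,
                                 periods = c(12, 18, 24, 30),
                                 amplitude = 0.4, baseline = 0.5,
                                 noise_sd = 0.05, seed = 1) {
  n <- nrow(base_lads)
  n_per <- round(n * periodic_fraction)
  n_noise <- round(n * noise_fraction)
  n_gate <- round(n * gate_fraction)
  kind <- rep("constant", n)
  if (n_per > 0) kind[seq_len(n_per)] <- "cosine"
  if (n_noise > 0) kind[n_per + seq_len(n_noise)] <- "noise"
  if (n_gate > 0) kind[n_per + n_noise + seq_len(n_gate)] <- "gate"
  withr::with_seed(seed, {
    phases <- sample(c(0, 6, 12, 18), n, replace = TRUE)
  })
  per_cycle <- rep_len(periods, max(n_per, 1))
  sides <- list()
  gates <- list()
  for (i in seq_len(n)) {
    id <- base_lads$lad_id[i]
    if (kind[i] == "cosine") {
      sides[[length(sides) + 1]] <- tibble::tibble(
        lad_id = id, side = c("5p", "3p"),
        mode = c("cosine", "constant"),
        baseline = c(baseline, 1), period_h = c(per_cycle[i], NA),
        phase_h = c(phases[i], NA), amplitude = c(amplitude, 0),
        noise_sd = c(noise_sd, 0))
    } else if (kind[i] == "noise") {
      sides[[length(sides) + 1]] <- tibble::tibble(
        lad_id = id, side = c("5p", "3p"),
        mode = c("noise", "constant"),
        baseline = c(baseline, 1), period_h = NA_real_,
        phase_h = NA_real_, amplitude = 0, noise_sd = c(noise_sd, 0))
    } else {
      sides[[length(sides) + 1]] <- tibble::tibble(
        lad_id = id, side = c("5p", "3p"), mode = "constant",
        baseline = 1, period_h = NA_real_, phase_h = NA_real_,
        amplitude = 0, noise_sd = 0)
    }
    gates[[length(gates) + 1]] <- tibble::tibble(
      lad_id = id,
      gate_mode = if (kind[i] == "gate") "appear-disappear" else "always",
      gate_period_h = 24, gate_phase_h = phases[i], gate_threshold = 0)
  }
  list(sides = do.call(rbind, sides), gates = do.call(rbind, gates))
}

rel_value <- function(mode, baseline, period_h, phase_h, amplitude, t, eps) {
  v <- switch(mode,
    constant = baseline,
    noise = baseline + eps,
    cosine = baseline + amplitude * cos(2 * pi * (t - phase_h) / period_h) + eps,
    stop("unknown border mode: ", mode, call. = FALSE)
  )
  v
}

#' Generate a LAD time course with injected border dynamics
#'
#' Realizes the standardized relative border lengths prescribed by a
#' scenario (see [default_lad_scenario()]) for every (CT, replicate),
#' converts them back to genomic coordinates within each base (cov_max)
#' region by rounding half-up to whole bp, and emits one `lad_set` per
#' sample. Replicate noise is drawn independently per replicate and side.
#' Values are clamped to `[0, 1]` (clamping events are counted) and a LAD is
#' absent from a sample when its realized fragment is empty
#' (`rel5 + rel3 <= 1`) or its gate is closed. Optionally an NS
#' (non-synchronized) sample outside the grid is emitted, in which a random
#' fraction of LADs is missing and the rest are retracted, for gain/loss
#' analysis.
#'
#' @param base_lads base-LAD tibble (`lad_id`, `chrom`, `start`, `end`,
#'   `length_bp`).
#' @param scenario list with `sides` and `gates` tibbles
#'   (see [default_lad_scenario()]).
#' @param grid a [time_grid()] with >= 4 CTs.
#' @param n_replicates replicates per CT.
#' @param seed integer seed.
#' @param ns_sample emit `NS_<rep>` samples outside the grid.
#' @param ns_drop_fraction fraction of LADs absent from NS.
#' @return A list: `lad_sets` (named list of `lad_set`, `"<CT>_<rep>"` plus
#'   optional `"NS_<rep>"`), `truth` (tibble `lad_id`, `side`, `ct`,
#'   `replicate`, `time_h`, `rel`, plus the injected spec columns),
#'   `n_clamped` (count of clamped draws).
#' @export
generate_lad_timecourse <- function(base_lads, scenario, grid,
                                    n_replicates = 2, seed = 1,
                                    ns_sample = FALSE,
                                    ns_drop_fraction = 0.3) {
  if (length(grid$ct_labels) < 4) stop("grid must have >= 4 CTs", call. = FALSE)
  reps <- if (length(grid$replicates) == n_replicates) grid$replicates else
    paste0("r", seq_len(n_replicates))
  sides <- scenario$sides
  gates <- scenario$gates
  n_clamped <- 0L
  truth_rows <- list()
  sets <- list()
  withr::with_seed(seed, {
    for (ci in seq_along(grid$ct_labels)) {
      ct <- grid$ct_labels[ci]
      t <- grid$times_h[ci]
      for (r in reps) {
        rows_s <- numeric(0); rows_e <- numeric(0); rows_c <- character(0)
        for (i in seq_len(nrow(base_lads))) {
          id <- base_lads$lad_id[i]
          g <- gates[gates$lad_id == id, ]
          open <- TRUE
          if (nrow(g) == 1 && g$gate_mode == "appear-disappear") {
            open <- cos(2 * pi * (t - g$gate_phase_h) / g$gate_period_h) >=
              g$gate_threshold
          }
          sp5 <- sides[sides$lad_id == id & sides$side == "5p", ]
          sp3 <- sides[sides$lad_id == id & sides$side == "3p", ]
          eps5 <- if (sp5$noise_sd > 0) stats::rnorm(1, 0, sp5$noise_sd) else 0
          eps3 <- if (sp3$noise_sd > 0) stats::rnorm(1, 0, sp3$noise_sd) else 0
          rel5 <- rel_value(sp5$mode, sp5$baseline, sp5$period_h, sp5$phase_h,
                            sp5$amplitude, t, eps5)
          rel3 <- rel_value(sp3$mode, sp3$baseline, sp3$period_h, sp3$phase_h,
                            sp3$amplitude, t, eps3)
          if (rel5 < 0 || rel5 > 1) { rel5 <- min(max(rel5, 0), 1); n_clamped <- n_clamped + 1L }
          if (rel3 < 0 || rel3 > 1) { rel3 <- min(max(rel3, 0), 1); n_clamped <- n_clamped + 1L }
          if (!open) { rel5 <- 0; rel3 <- 0 }
          L <- base_lads$length_bp[i]
          s <- base_lads$start[i] + round_half_up((1 - rel5) * L)
          e <- base_lads$end[i] - round_half_up((1 - rel3) * L)
          present <- open && rel5 > 0 && rel3 > 0 && s < e
          if (present) {
            rows_c <- c(rows_c, base_lads$chrom[i])
            rows_s <- c(rows_s, s); rows_e <- c(rows_e, e)
          }
          truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
            lad_id = id, side = c("5p", "3p"), ct = ct, replicate = r,
            time_h = t, rel = if (present) c(rel5, rel3) else c(0, 0),
            mode = c(sp5$mode, sp3$mode),
            period_h = c(sp5$period_h, sp3$period_h),
            phase_h = c(sp5$phase_h, sp3$phase_h),
            amplitude = c(sp5$amplitude, sp3$amplitude),
            noise_sd = c(sp5$noise_sd, sp3$noise_sd))
        }
        sets[[sample_name(ct, r)]] <- lad_set(rows_c, rows_s, rows_e,
                                              label = sample_name(ct, r))
      }
    }
    if (ns_sample) {
      drop <- stats::runif(nrow(base_lads)) < ns_drop_fraction
      for (r in reps) {
        keep <- base_lads[!drop, ]
        retract <- round_half_up(stats::runif(nrow(keep), 0, 0.2) * keep$length_bp)
        sets[[sample_name("NS", r)]] <- lad_set(
          keep$chrom, keep$start + retract, keep$end, label = sample_name("NS", r))
      }
    }
  })
  list(lad_sets = sets, truth = do.call(rbind, truth_rows),
       n_clamped = n_clamped)
}

#' Expression specifications for a set of genes
#'
#' One row per gene: class `periodic` (cosine with the given period, phase,
#' amplitude and base), `noise` (base plus Gaussian noise, no rhythm) or
#' `constant`. `default_expression_scenario()` assigns classes in the given
#' fractions, cycling injected periods through `periods`, with an
#' amplitude:noise ratio of 4:1.
#'
#' @param genes gene tibble from [generate_genome()].
#' @param periodic_fraction,noise_fraction class fractions (remainder
#'   constant).
#' @param periods injected periods, recycled over periodic genes.
#' @param base mean FPKM level.
#' @param amplitude cosine amplitude (FPKM).
#' @param noise_sd replicate noise sd (FPKM).
#' @param seed seed used to assign phases.
#' @return A tibble `gene_id`, `class`, `period_h`, `phase_h`, `amplitude`,
#'   `base`, `noise_sd`.
#' @export
default_expression_scenario <- function(genes, periodic_fraction = 0.4,
                                        noise_fraction = 0.3,
                                        periods = c(12, 18, 24, 30),
                                        base = 10, amplitude = 4,
                                        noise_sd = 1, seed = 1) {
  n <- nrow(genes)
  n_per <- round(n * periodic_fraction)
  n_noise <- round(n * noise_fraction)
  cls <- rep("constant", n)
  if (n_per > 0) cls[seq_len(n_per)] <- "periodic"
  if (n_noise > 0) cls[n_per + seq_len(n_noise)] <- "noise"
  withr::with_seed(seed, {
    phases <- sample(c(0, 6, 12, 18), n, replace = TRUE)
  })
  tibble::tibble(
    gene_id = genes$gene_id, class = cls,
    period_h = ifelse(cls == "periodic", rep_len(periods, n), NA_real_),
    phase_h = ifelse(cls == "periodic", phases, NA_real_),
    amplitude = ifelse(cls == "periodic", amplitude, 0),
    base = base,
    noise_sd = ifelse(cls == "constant", 0, noise_sd)
  )
}

#' Generate an FPKM expression time course with known rhythm labels
#'
#' Periodic genes follow
#' `FPKM(t) = max(0, base + amplitude*cos(2*pi*(t - phase)/period) + eps)`;
#' noise genes are base plus Gaussian noise; constant genes are flat.
#' Negative draws are truncated at 0 and counted.
#'
#' @param specs expression-spec tibble (see
#'   [default_expression_scenario()]).
#' @param grid a [time_grid()] with >= 4 CTs.
#' @param n_replicates replicates per CT.
#' @param seed integer seed.
#' @return A list: `fpkm` (genes x samples matrix, columns `<CT>_<rep>`),
#'   `truth` (the spec tibble), `n_truncated` (negative draws truncated).
#' @export
generate_expression_timecourse <- function(specs, grid, n_replicates = 3,
                                           seed = 1) {
  if (length(grid$ct_labels) < 4) stop("grid must have >= 4 CTs", call. = FALSE)
  reps <- if (length(grid$replicates) == n_replicates) grid$replicates else
    paste0("r", seq_len(n_replicates))
  samples <- as.vector(t(outer(grid$ct_labels, reps, sample_name)))
  m <- matrix(0, nrow = nrow(specs), ncol = length(samples),
              dimnames = list(specs$gene_id, samples))
  n_trunc <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      for (ci in seq_along(grid$ct_labels)) {
        t <- grid$times_h[ci]
        mu <- switch(sp$class,
          periodic = sp$base + sp$amplitude *
            cos(2 * pi * (t - sp$phase_h) / sp$period_h),
          noise = sp$base,
          constant = sp$base,
          stop("unknown expression class: ", sp$class, call. = FALSE))
        for (ri in seq_along(reps)) {
          eps <- if (sp$noise_sd > 0) stats::rnorm(1, 0, sp$noise_sd) else 0
          v <- mu + eps
          if (v < 0) { v <- 0; n_trunc <- n_trunc + 1L }
          m[i, sample_name(grid$ct_labels[ci], reps[ri])] <- v
        }
      }
    }
  })
  list(fpkm = m, truth = specs, n_truncated = n_trunc)
}

#' Write an FPKM matrix as TSV
#'
#' @param fpkm genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(fpkm, path) {
  df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene annotations as BED6
#'
#' @param genes gene tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  df <- data.frame(
    chrom = genes$chrom,
    start = format(genes$start, scientific = FALSE, trim = TRUE),
    end = format(genes$end, scientific = FALSE, trim = TRUE),
    name = genes$gene_id, score = 0, strand = genes$strand,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
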