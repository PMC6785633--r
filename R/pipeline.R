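#' Default pipeline configuration
#'
#' Assembles the full configuration of the analysis chain: the circadian
#' time grid (CT0..CT30 at 6 h, two LAD replicates, three expression
#' replicates), synthetic-data scenario parameters, rhythm-engine options,
#' randomization options, significance thresholds (stringent 0.005, relaxed
#' 0.05), the gene-capture window (2.5 Mb) and the CTs used for
#' distance-variation analysis. All stochastic stages derive their seeds
#' from `seed`.
#'
#' @param seed master integer seed.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(ct_labels = paste0("CT", seq(0, 30, 6)),
                times_h = seq(0, 30, 6),
                replicates = c("r1", "r2")),
    expression_replicates = 3,
    simulate = list(
      n_chroms = 2, chrom_length = 6e7, n_lads = 20, n_genes = 90,
      periodic_fraction = 0.5, noise_fraction = 0.2, gate_fraction = 0.1,
      periods = c(12, 18, 24, 30), amplitude = 0.4, baseline = 0.5,
      noise_sd = 0.05, ns_sample = TRUE,
      expression = list(periodic_fraction = 0.4, noise_fraction = 0.3,
                        base = 10, amplitude = 4, noise_sd = 1)
    ),
    inputs = NULL,  # list(lad_dir=, genes=, fpkm=) to analyze real files
    rhythm = list(periods_jtk = c(12, 18, 24, 30, 36),
                  ls_period_range = c(12, 48), ls_oversampling = 10,
                  period_groups = c(12, 18, 24, 30), group_halfwidth = 3,
                  replicate_strategy = "replicates"),
    randomization = list(n_shuffles = 3, min_discordant = 2),
    thresholds = list(strong = 0.005, relaxed = 0.05),
    min_border_sd = 0,
    window_bp = 2.5e6,
    distance_cts = c("CT0", "CT12", "CT24")
  )
}

#' Load a YAML configuration, merged over the defaults
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @return A configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

config_grid <- function(config) {
  time_grid(config$grid$ct_labels, config$grid$times_h,
            config$grid$replicates)
}

config_rhythm <- function(config) {
  rc <- config$rhythm
  rhythm_config(
    periods_jtk = rc$periods_jtk,
    ls_period_range = rc$ls_period_range,
    ls_oversampling = rc$ls_oversampling,
    period_groups = rc$period_groups,
    group_halfwidth = rc$group_halfwidth,
    p_strong = config$thresholds$strong,
    p_relaxed = config$thresholds$relaxed,
    replicate_strategy = rc$replicate_strategy
  )
}

write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

pipeline_stages <- c("simulate", "lads", "rhythm", "randomize", "genedist",
                     "expression", "report")

#' Run the LAD periodicity pipeline
#'
#' Executes the analysis chain stage by stage, writing one subdirectory of
#' TSV outputs per stage plus a machine-readable run manifest. With the
#' default configuration the `simulate` stage generates the inputs (toy
#' genome, LAD time course with injected rhythms, FPKM matrix); with
#' `config$inputs` set, LAD BED files (`<CT>_<rep>.bed`, optional
#' `NS_<rep>.bed`), a BED6 gene file and an FPKM TSV are read instead and
#' the `simulate` stage is skipped. Outputs are deterministic: identical
#' configuration and seeds give byte-identical files, and no stage mutates
#' its inputs.
#'
#' Stages: `simulate` (synthetic inputs + truth tables), `lads` (replicate
#' intersects, Jaccard indices, per-CT LAD stats, cov_max, border series,
#' NS->CT0 gain/loss), `rhythm` (variable-border rhythm fits), `randomize`
#' (CT-order randomization verdicts for significant borders), `genedist`
#' (TSS membership and gene-to-nearest-LAD distances per CT, distance
#' variation), `expression` (periodic/non-periodic gene classification,
#' periodic genes in LADs), `report` (joined summary tables).
#'
#' @param config configuration list (see [default_config()],
#'   [load_config()]).
#' @param outdir output directory (created if needed).
#' @param stages stages to run, in order; later stages need the state of
#'   earlier ones within the same call.
#' @return Invisibly, the final state (a list of intermediate objects).
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = pipeline_stages) {
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "\nvalid stages: ", paste(pipeline_stages, collapse = ", "),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  state <- list(config = config, grid = config_grid(config),
                rhythm_config = config_rhythm(config))
  for (st in stages) {
    sdir <- file.path(outdir, st)
    dir.create(sdir, showWarnings = FALSE)
    state <- switch(st,
      simulate = stage_simulate(state, sdir),
      lads = stage_lads(state, sdir),
      rhythm = stage_rhythm(state, sdir),
      randomize = stage_randomize(state, sdir),
      genedist = stage_genedist(state, sdir),
      expression = stage_expression(state, sdir),
      report = stage_report(state, sdir)
    )
  }
  manifest <- list(
    package = "ladcycle",
    package_version = as.character(utils::packageVersion("ladcycle")),
    seed = config$seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(file.path(outdir, "config.yaml")))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(state)
}

require_state <- function(state, what, needed_by) {
  if (is.null(state[[what]])) {
    stop(sprintf("stage '%s' requires '%s' from an earlier stage",
                 needed_by, what), call. = FALSE)
  }
  state[[what]]
}

stage_simulate <- function(state, sdir) {
  cfg <- state$config
  sim <- cfg$simulate
  grid <- state$grid
  genome <- generate_genome(
    n_chroms = sim$n_chroms, chrom_length = sim$chrom_length,
    n_lads = sim$n_lads, n_genes = sim$n_genes, seed = cfg$seed)
  scenario <- default_lad_scenario(
    genome$base_lads, periodic_fraction = sim$periodic_fraction,
    noise_fraction = sim$noise_fraction, gate_fraction = sim$gate_fraction,
    periods = sim$periods, amplitude = sim$amplitude,
    baseline = sim$baseline, noise_sd = sim$noise_sd, seed = cfg$seed + 1)
  tc <- generate_lad_timecourse(
    genome$base_lads, scenario, grid,
    n_replicates = length(grid$replicates), seed = cfg$seed + 2,
    ns_sample = isTRUE(sim$ns_sample))
  ex_cfg <- sim$expression
  ex_specs <- default_expression_scenario(
    genome$genes, periodic_fraction = ex_cfg$periodic_fraction,
    noise_fraction = ex_cfg$noise_fraction, periods = sim$periods,
    base = ex_cfg$base, amplitude = ex_cfg$amplitude,
    noise_sd = ex_cfg$noise_sd, seed = cfg$seed + 3)
  expr_grid <- time_grid(grid$ct_labels, grid$times_h,
                         paste0("r", seq_len(cfg$expression_replicates)))
  ex <- generate_expression_timecourse(ex_specs, expr_grid,
                                       n_replicates = cfg$expression_replicates,
                                       seed = cfg$seed + 4)
  bed_dir <- file.path(sdir, "beds")
  dir.create(bed_dir, showWarnings = FALSE)
  for (nm in names(tc$lad_sets)) {
    write_bed(tc$lad_sets[[nm]], file.path(bed_dir, paste0(nm, ".bed")))
  }
  write_genes_bed(genome$genes, file.path(sdir, "genes.bed"))
  write_fpkm(ex$fpkm, file.path(sdir, "fpkm.tsv"))
  write_tsv(tc$truth, file.path(sdir, "lad_truth.tsv"))
  write_tsv(ex$truth, file.path(sdir, "expression_truth.tsv"))
  state$lad_sets <- tc$lad_sets
  state$genes <- genome$genes
  state$fpkm <- ex$fpkm
  state$expr_grid <- expr_grid
  state$lad_truth <- tc$truth
  state$expr_truth <- ex$truth
  state
}

read_input_lads <- function(config, grid) {
  dir <- config$inputs$lad_dir
  if (is.null(dir)) {
    stop("config$inputs$lad_dir is required when the simulate stage is not run",
         call. = FALSE)
  }
  samples <- grid_samples(grid)
  ns <- sample_name("NS", grid$replicates)
  sets <- list()
  for (nm in samples) {
    path <- file.path(dir, paste0(nm, ".bed"))
    if (!file.exists(path)) stop("missing LAD BED file: ", path, call. = FALSE)
    sets[[nm]] <- normalize_lads(read_bed(path, label = nm))
  }
  for (nm in ns) {
    path <- file.path(dir, paste0(nm, ".bed"))
    if (file.exists(path)) sets[[nm]] <- normalize_lads(read_bed(path, label = nm))
  }
  sets
}

stage_lads <- function(state, sdir) {
  cfg <- state$config
  grid <- state$grid
  if (is.null(state$lad_sets)) state$lad_sets <- read_input_lads(cfg, grid)
  lad_sets <- lapply(state$lad_sets, normalize_lads)
  has_ns <- all(sample_name("NS", grid$replicates) %in% names(lad_sets))
  cts <- c(grid$ct_labels, if (has_ns) "NS")
  intersects <- replicate_intersects(lad_sets, grid, cts = cts)

  # replicate agreement per CT
  jac <- do.call(rbind, lapply(cts, function(ct) {
    pairs <- utils::combn(grid$replicates, 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- lad_sets[[sample_name(ct, pairs[1, j])]]
      b <- lad_sets[[sample_name(ct, pairs[2, j])]]
      tibble::tibble(ct = ct, rep_a = pairs[1, j], rep_b = pairs[2, j],
                     jaccard = jaccard_lads(a, b))
    }))
  }))
  write_tsv(jac, file.path(sdir, "replicate_jaccard.tsv"))
  write_tsv(lad_stats(intersects), file.path(sdir, "lad_stats.tsv"))

  grid_sets <- lad_sets[grid_samples(grid)]
  covmax <- compute_covmax(grid_sets)
  write_bed(lad_set(covmax$chrom, covmax$start, covmax$end, label = "cov_max"),
            file.path(sdir, "covmax.bed"), names = covmax$lad_id)
  series <- border_series(covmax, grid_sets, grid)
  write_tsv(series, file.path(sdir, "border_series.tsv"))

  if (has_ns) {
    gl <- classify_gain_loss(reference = intersects[["NS"]],
                             comparison = intersects[[grid$ct_labels[1]]])
    write_tsv(gl, file.path(sdir, "gain_loss.tsv"))
    write_tsv(gain_loss_summary(gl), file.path(sdir, "gain_loss_summary.tsv"))
    state$gain_loss <- gl
  }
  state$lad_sets <- lad_sets
  state$intersects <- intersects
  state$covmax <- covmax
  state$border_series <- series
  state
}

stage_rhythm <- function(state, sdir) {
  series <- require_state(state, "border_series", "rhythm")
  variable <- filter_variable_borders(series, state$config$min_border_sd)
  fits <- fit_border_rhythms(variable, state$grid, state$rhythm_config)
  fits$period_group_label <- period_group_label(fits$period_group)
  write_tsv(fits, file.path(sdir, "border_rhythms.tsv"))
  state$variable_series <- variable
  state$border_fits <- fits
  state
}

stage_randomize <- function(state, sdir) {
  fits <- require_state(state, "border_fits", "randomize")
  cfg <- state$config
  sig <- fits[fits$p_combined < cfg$thresholds$relaxed, ]
  keys <- paste(state$variable_series$lad_id, state$variable_series$side)
  sub <- state$variable_series[keys %in% paste(sig$lad_id, sig$side), ]
  if (nrow(sub) > 0) {
    verdicts <- randomize_borders(
      sub, state$grid, state$rhythm_config,
      n_shuffles = cfg$randomization$n_shuffles, seed = cfg$seed + 5,
      threshold = cfg$thresholds$relaxed,
      min_discordant = cfg$randomization$min_discordant)
  } else {
    verdicts <- tibble::tibble(lad_id = character(), side = character(),
                               series_id = character(),
                               experimental_group = character(),
                               shuffle_groups = character(),
                               n_shuffles = integer(),
                               n_discordant = integer(), passes = logical(),
                               p_combined = numeric())
  }
  write_tsv(verdicts, file.path(sdir, "randomization.tsv"))
  state$verdicts <- verdicts
  state
}

stage_genedist <- function(state, sdir) {
  cfg <- state$config
  grid <- state$grid
  if (is.null(state$genes)) {
    path <- cfg$inputs$genes
    if (is.null(path)) stop("config$inputs$genes is required", call. = FALSE)
    state$genes <- read_genes(path)
  }
  intersects <- require_state(state, "intersects", "genedist")
  membership <- lapply(grid$ct_labels, function(ct) {
    assign_membership(state$genes, intersects[[ct]])
  })
  names(membership) <- grid$ct_labels
  distances <- lapply(grid$ct_labels, function(ct) {
    gene_to_nearest_lad(state$genes, intersects[[ct]])
  })
  names(distances) <- grid$ct_labels
  dist_long <- do.call(rbind, lapply(grid$ct_labels, function(ct) {
    cbind(tibble::tibble(ct = ct), distances[[ct]])
  }))
  write_tsv(dist_long, file.path(sdir, "gene_lad_distances.tsv"))

  dc <- cfg$distance_cts
  if (all(dc %in% grid$ct_labels)) {
    dv <- distance_variation(distances[[dc[1]]], distances[[dc[2]]],
                             distances[[dc[3]]])
    write_tsv(dv$variation, file.path(sdir, "distance_variation.tsv"))
    write_tsv(dv$excluded, file.path(sdir, "distance_variation_excluded.tsv"))
    state$distance_variation <- dv
  }
  state$membership <- membership
  state$distances <- distances
  state
}

stage_expression <- function(state, sdir) {
  cfg <- state$config
  if (is.null(state$fpkm)) {
    path <- cfg$inputs$fpkm
    if (is.null(path)) stop("config$inputs$fpkm is required", call. = FALSE)
    state$fpkm <- read_fpkm(path)
    state$expr_grid <- time_grid(state$grid$ct_labels, state$grid$times_h,
                                 paste0("r", seq_len(cfg$expression_replicates)))
  }
  classes <- classify_periodic(state$fpkm, state$expr_grid,
                               state$rhythm_config)
  write_tsv(classes, file.path(sdir, "gene_classes.tsv"))
  nonper <- classify_nonperiodic(classes)
  write_tsv(nonper, file.path(sdir, "nonperiodic_genes.tsv"))
  state$gene_classes <- classes
  state$nonperiodic <- nonper
  if (!is.null(state$membership) && !is.null(state$genes)) {
    aligned <- match(state$genes$gene_id, classes$gene_id)
    if (!anyNA(aligned) && length(aligned) == nrow(classes)) {
      classes_aligned <- classes[aligned, ]
      frac <- periodic_genes_in_lads(classes_aligned, state$membership)
      write_tsv(frac, file.path(sdir, "periodic_genes_in_lads.tsv"))
      state$periodic_in_lads <- frac
    }
  }
  state
}

stage_report <- function(state, sdir) {
  cfg <- state$config
  fits <- require_state(state, "border_fits", "report")
  thr <- cfg$thresholds
  sig_strong <- fits[fits$p_combined < thr$strong, ]
  sig_relaxed <- fits[fits$p_combined < thr$relaxed, ]

  borders <- fits
  if (!is.null(state$verdicts) && nrow(state$verdicts) > 0) {
    v <- state$verdicts[, c("lad_id", "side", "experimental_group",
                            "shuffle_groups", "n_discordant", "passes")]
    borders <- merge(as.data.frame(borders), as.data.frame(v),
                     by = c("lad_id", "side"), all.x = TRUE, sort = FALSE)
    borders <- borders[order(borders$lad_id, borders$side), ]
  }
  write_tsv(borders, file.path(sdir, "periodic_borders.tsv"))

  summary_rows <- tibble::tibble(
    metric = c("n_covmax_lads", "n_variable_borders",
               "n_periodic_borders_strong", "n_periodic_lads_strong",
               "n_periodic_borders_relaxed", "n_periodic_lads_relaxed",
               "n_randomization_pass"),
    value = c(
      if (!is.null(state$covmax)) nrow(state$covmax) else NA,
      if (!is.null(state$variable_series))
        nrow(unique(state$variable_series[, c("lad_id", "side")])) else NA,
      nrow(sig_strong), length(unique(sig_strong$lad_id)),
      nrow(sig_relaxed), length(unique(sig_relaxed$lad_id)),
      if (!is.null(state$verdicts)) sum(state$verdicts$passes) else NA
    )
  )
  if (!is.null(state$gene_classes)) {
    gc <- state$gene_classes
    summary_rows <- rbind(summary_rows, tibble::tibble(
      metric = c("n_genes", "n_periodic_genes", "n_nonperiodic_genes"),
      value = c(nrow(gc), sum(grepl("^periodic-", gc$class)),
                nrow(state$nonperiodic))
    ))
  }
  if (!is.null(state$gain_loss)) {
    gs <- gain_loss_summary(state$gain_loss)
    summary_rows <- rbind(summary_rows, tibble::tibble(
      metric = paste0(gs$direction, "_", gsub("[^a-z]", "_", gs$mode), "_bp"),
      value = gs$bp
    ))
  }
  write_tsv(summary_rows, file.path(sdir, "summary.tsv"))

  # genes inside or within the capture window of strongly periodic LADs
  if (!is.null(state$genes) && !is.null(state$covmax) &&
      nrow(sig_strong) > 0) {
    per_lads <- state$covmax[state$covmax$lad_id %in% sig_strong$lad_id, ]
    near <- genes_near_lads(state$genes, per_lads,
                            window_bp = cfg$window_bp)
    if (!is.null(state$gene_classes)) {
      near$class <- state$gene_classes$class[
        match(near$gene_id, state$gene_classes$gene_id)]
    }
    write_tsv(near, file.path(sdir, "genes_near_periodic_lads.tsv"))
    state$genes_near_periodic <- near
  }

  if (!is.null(state$gene_classes) && !is.null(state$genes)) {
    per <- state$gene_classes[grepl("^periodic-", state$gene_classes$class), ]
    ctx <- merge(as.data.frame(per),
                 as.data.frame(state$genes[, c("gene_id", "chrom", "start",
                                               "end", "strand")]),
                 by = "gene_id", sort = TRUE)
    write_tsv(ctx, file.path(sdir, "periodic_genes.tsv"))
  }
  state$summary <- summary_rows
  state
}
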