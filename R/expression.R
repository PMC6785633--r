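#' Read an FPKM expression matrix
#'
#' Parses a TSV with a `gene_id` column followed by one column per
#' (CT, replicate) sample, named `<CT>_<replicate>` (e.g. `CT0_r1`). Values
#' must be non-negative FPKM.
#'
#' @param path TSV file path.
#' @return A numeric matrix (genes x samples) with gene ids as row names and
#'   sample names as column names.
#' @export
read_fpkm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") {
    stop("first column of an FPKM table must be 'gene_id'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("FPKM values must be numeric", call. = FALSE)
  if (any(m < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  rownames(m) <- df$gene_id
  m
}

# genes x samples matrix -> per-gene replicates x CT matrix builder
fpkm_gene_matrix <- function(fpkm_row, grid) {
  m <- matrix(NA_real_, nrow = length(grid$replicates),
              ncol = length(grid$ct_labels),
              dimnames = list(grid$replicates, grid$ct_labels))
  for (i in seq_along(grid$ct_labels)) {
    for (j in seq_along(grid$replicates)) {
      nm <- sample_name(grid$ct_labels[i], grid$replicates[j])
      if (!nm %in% names(fpkm_row)) {
        stop("FPKM matrix is missing sample column: ", nm, call. = FALSE)
      }
      m[j, i] <- fpkm_row[[nm]]
    }
  }
  m
}

#' Classify genes as periodic / other / non-significant from FPKM series
#'
#' For each expressed gene, the FPKM series is z-score normalized across all
#' (CT, replicate) samples and submitted to [meta_fit()]. Genes with a
#' combined p below the stringent threshold are `periodic-<group>` when a
#' period group is assigned and `periodic-other` when the mean period falls
#' outside every group window; the rest are `not-significant`. Genes not
#' expressed above `expressed_min` in at least one sample are excluded from
#' fitting and labelled `not-expressed`.
#'
#' @param fpkm genes x samples matrix from [read_fpkm()].
#' @param grid a [time_grid()] whose (CT, replicate) pairs name the columns.
#' @param config a [rhythm_config()]; the stringent threshold
#'   `config$p_strong` defines periodicity.
#' @param expressed_min a gene is "expressed" iff FPKM > `expressed_min` in
#'   at least one sample (default 0).
#' @return A tibble with one row per gene: the [meta_fit()] fields plus
#'   `gene_id` and `class`.
#' @export
classify_periodic <- function(fpkm, grid, config = rhythm_config(),
                              expressed_min = 0) {
  gene_ids <- rownames(fpkm)
  rows <- lapply(seq_len(nrow(fpkm)), function(i) {
    row <- fpkm[i, ]
    if (!any(row > expressed_min)) {
      fit <- tibble::tibble(
        series_id = gene_ids[i], p_jtk = NA_real_, p_ls = NA_real_,
        p_combined = NA_real_, period_jtk = NA_real_, period_ls = NA_real_,
        period_mean = NA_real_, phase_h = NA_real_, amplitude = NA_real_,
        base = NA_real_, period_group = NA_real_, phase_group = "none")
      return(cbind(tibble::tibble(gene_id = gene_ids[i]), fit,
                   tibble::tibble(class = "not-expressed")))
    }
    z <- zscore_normalize(as.numeric(row))
    names(z) <- colnames(fpkm)
    m <- fpkm_gene_matrix(as.list(z), grid)
    fit <- meta_fit(m, grid, config, series_id = gene_ids[i])
    cls <- if (fit$p_combined < config$p_strong) {
      if (!is.na(fit$period_group)) {
        paste0("periodic-", period_group_label(fit$period_group))
      } else "periodic-other"
    } else "not-significant"
    cbind(tibble::tibble(gene_id = gene_ids[i]), fit,
          tibble::tibble(class = cls))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Select non-periodic genes
#'
#' Genes whose expression is discordant with every tentatively fitted cosine
#' curve: `1 > p_combined > 0.9999` (both bounds strict, so a combined p of
#' exactly 1 is excluded).
#'
#' @param classes classification tibble from [classify_periodic()].
#' @return The subset of rows satisfying the non-periodic criterion.
#' @export
classify_nonperiodic <- function(classes) {
  p <- classes$p_combined
  classes[!is.na(p) & p > 0.9999 & p < 1, ]
}

#' Fraction of periodic genes inside LADs at each CT
#'
#' @param classes classification tibble from [classify_periodic()].
#' @param membership named list (one element per CT) of logical `in_lad`
#'   vectors aligned with `classes` rows (see [assign_membership()]).
#' @return A tibble `ct`, `n_periodic`, `n_in_lad`, `fraction` (`NA` when
#'   there are no periodic genes).
#' @export
periodic_genes_in_lads <- function(classes, membership) {
  periodic <- grepl("^periodic-", classes$class)
  rows <- lapply(names(membership), function(ct) {
    flags <- membership[[ct]]
    if (length(flags) != nrow(classes)) {
      stop("membership vectors must align with classification rows",
           call. = FALSE)
    }
    n_p <- sum(periodic)
    tibble::tibble(
      ct = ct, n_periodic = n_p, n_in_lad = sum(periodic & flags),
      fraction = if (n_p == 0) NA_real_ else sum(periodic & flags) / n_p
    )
  })
  do.call(rbind, rows)
}
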