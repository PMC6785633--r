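#' Read stranded gene annotations
#'
#' Parses a BED6 file (name = gene id, strand column required) into a gene
#' table. Coordinates are 0-based half-open. The transcription start site
#' (TSS) is `start` for + strand genes and `end - 1` for - strand genes.
#'
#' @param path BED6 file path.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)([[:space:]]|$)", lines) &
    !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character(), tss = numeric()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    i <- idx[which(nf < 6)[1]]
    stop(sprintf("%s line %d: BED6 requires 6 fields (name and strand)",
                 path, i), call. = FALSE)
  }
  get <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  strand <- get(6)
  bad <- is.na(start) | is.na(end) | start >= end | !(strand %in% c("+", "-"))
  if (any(bad)) {
    i <- idx[which(bad)[1]]
    stop(sprintf("%s line %d: malformed gene record", path, i), call. = FALSE)
  }
  tibble::tibble(
    gene_id = get(4), chrom = get(1), start = start, end = end,
    strand = strand, tss = ifelse(strand == "+", start, end - 1)
  )
}

#' Gene-to-LAD membership by TSS overlap
#'
#' A gene is ascribed to a LAD if its transcription start site (a single bp)
#' lies within a LAD interval.
#'
#' @param genes gene tibble (see [read_genes()]).
#' @param lads a normalized `lad_set` (typically the replicate intersect at
#'   one CT).
#' @return Logical vector `in_lad`, one element per gene.
#' @export
assign_membership <- function(genes, lads) {
  assert_lad_set(lads, "lads")
  if (nrow(genes) == 0) return(logical(0))
  if (nrow(lads) == 0) return(rep(FALSE, nrow(genes)))
  lv <- unique(c(genes$chrom, lads$chrom))
  tss_gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = lv),
    ranges = IRanges::IRanges(start = genes$tss + 1, width = 1)
  )
  GenomicRanges::countOverlaps(tss_gr, as_granges(lads, seqlevels = lv)) > 0
}

#' Strand-respecting gene-to-nearest-LAD distances
#'
#' For each gene, the distance from its 5' and 3' ends to, respectively, the
#' nearest 3' and 5' LAD border, respecting gene strand. On the + strand
#' `d5` is measured from `start` toward lower coordinates and `d3` from
#' `end` toward higher coordinates; on the - strand the roles are mirrored.
#' A gene lying entirely inside a LAD keeps that containing LAD excluded and
#' is measured to the first neighboring LAD on each side; a LAD that overlaps
#' (without containing) a gene on a side gives distance 0 on that side.
#' Distances are never negative; a side with no LAD on the gene's chromosome
#' is missing (`NA`). `nearest` is the minimum over the present sides.
#'
#' @param genes gene tibble (see [read_genes()]).
#' @param lads a normalized `lad_set` (replicate intersect at one CT).
#' @return A tibble `gene_id`, `in_lad` (TSS membership), `d5`, `d3`,
#'   `nearest`.
#' @export
gene_to_nearest_lad <- function(genes, lads) {
  assert_lad_set(lads, "lads")
  lads <- normalize_lads(lads)
  n <- nrow(genes)
  d_left <- rep(NA_real_, n)
  d_right <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    gs <- genes$start[i]; ge <- genes$end[i]
    L <- lads[lads$chrom == genes$chrom[i], ]
    if (nrow(L) == 0) next
    containing <- L$start <= gs & L$end >= ge
    Lx <- L[!containing, ]
    if (nrow(Lx) == 0) next
    # left (lower-coordinate) side of the gene
    if (any(Lx$start < gs & Lx$end > gs)) {
      d_left[i] <- 0
    } else {
      up <- Lx$end[Lx$end <= gs]
      if (length(up) > 0) d_left[i] <- gs - max(up)
    }
    # right (higher-coordinate) side
    if (any(Lx$start < ge & Lx$end > ge)) {
      d_right[i] <- 0
    } else {
      down <- Lx$start[Lx$start >= ge]
      if (length(down) > 0) d_right[i] <- min(down) - ge
    }
  }
  plus <- genes$strand == "+"
  d5 <- ifelse(plus, d_left, d_right)
  d3 <- ifelse(plus, d_right, d_left)
  nearest <- pmin(d5, d3, na.rm = TRUE)
  nearest[is.na(d5) & is.na(d3)] <- NA_real_
  tibble::tibble(
    gene_id = genes$gene_id,
    in_lad = assign_membership(genes, lads),
    d5 = d5, d3 = d3, nearest = nearest
  )
}

#' Variation in gene-to-nearest-LAD distance across three CTs
#'
#' Computes the signed changes `delta_a = nearest(ct_mid) - nearest(ct_first)`
#' and `delta_b = nearest(ct_last) - nearest(ct_mid)` (decrease < 0) and
#' labels each gene's sign pair: quadrants Q1 (increase-increase),
#' Q2 (decrease-then-increase), Q3 (decrease-decrease),
#' Q4 (increase-then-decrease), with zero changes mapped to on-axis
#' categories (`x-axis`, `y-axis`, `origin`). Genes with a missing distance
#' at any of the three CTs are excluded and reported with a reason.
#'
#' @param d_first,d_mid,d_last distance tibbles from
#'   [gene_to_nearest_lad()] at the three CTs (same gene order).
#' @return A list with `variation` (tibble `gene_id`, `delta_a`, `delta_b`,
#'   `quadrant`, `label`) and `excluded` (tibble `gene_id`, `reason`).
#' @export
distance_variation <- function(d_first, d_mid, d_last) {
  stopifnot(identical(d_first$gene_id, d_mid$gene_id),
            identical(d_mid$gene_id, d_last$gene_id))
  ok <- !is.na(d_first$nearest) & !is.na(d_mid$nearest) & !is.na(d_last$nearest)
  excluded <- tibble::tibble(
    gene_id = d_first$gene_id[!ok],
    reason = "missing nearest-LAD distance at one or more CTs"
  )
  da <- d_mid$nearest[ok] - d_first$nearest[ok]
  db <- d_last$nearest[ok] - d_mid$nearest[ok]
  lab <- function(a, b) {
    if (a == 0 && b == 0) return(c("origin", "origin"))
    if (a == 0) return(c("x-axis", "x-axis"))
    if (b == 0) return(c("y-axis", "y-axis"))
    if (a > 0 && b > 0) return(c("Q1", "increase-increase"))
    if (a < 0 && b > 0) return(c("Q2", "decrease-then-increase"))
    if (a < 0 && b < 0) return(c("Q3", "decrease-decrease"))
    c("Q4", "increase-then-decrease")
  }
  labs <- t(vapply(seq_along(da), function(i) lab(da[i], db[i]), character(2)))
  variation <- tibble::tibble(
    gene_id = d_first$gene_id[ok],
    delta_a = da, delta_b = db,
    quadrant = if (length(da) > 0) labs[, 1] else character(0),
    label = if (length(da) > 0) labs[, 2] else character(0)
  )
  list(variation = variation, excluded = excluded)
}

#' Genes near LAD extremities
#'
#' Captures genes whose body overlaps the window
#' `[lad.start - window_bp, lad.end + window_bp)` around a LAD (default
#' 2.5 Mb, the neighborhood used for periodic LADs). Genes overlapping the
#' LAD region itself are reported separately with `position = "inside"`.
#'
#' @param genes gene tibble (see [read_genes()]).
#' @param lads either a cov_max tibble (with `lad_id`) or a `lad_set`.
#' @param window_bp window size in bp on each side (default 2,500,000).
#' @return A tibble `gene_id`, `lad_id`, `position` (`"inside"`/`"near"`).
#' @export
genes_near_lads <- function(genes, lads, window_bp = 2.5e6) {
  if (window_bp < 0) stop("window_bp must be >= 0", call. = FALSE)
  if (is_lad_set(lads)) {
    lads <- tibble::tibble(lad_id = sprintf("LAD%04d", seq_len(nrow(lads))),
                           chrom = lads$chrom, start = lads$start,
                           end = lads$end)
  }
  rows <- list()
  for (j in seq_len(nrow(lads))) {
    ws <- max(0, lads$start[j] - window_bp)
    we <- lads$end[j] + window_bp
    sel <- genes$chrom == lads$chrom[j] & genes$start < we & genes$end > ws
    if (!any(sel)) next
    inside <- genes$start < lads$end[j] & genes$end > lads$start[j]
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = genes$gene_id[sel],
      lad_id = lads$lad_id[j],
      position = ifelse(inside[sel], "inside", "near")
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene_id = character(), lad_id = character(),
                          position = character()))
  }
  do.call(rbind, rows)
}
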