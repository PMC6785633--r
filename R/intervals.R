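#' Genomic interval sets for LAD analysis
#'
#' A `lad_set` holds the lamina-associated domain (LAD) calls of one sample
#' (one circadian time point x one biological replicate) as 0-based half-open
#' intervals. It is a tibble with columns `chrom`, `start`, `end` and a
#' `label` attribute identifying the sample. All interval algebra in the
#' package operates on normalized (sorted, merged) `lad_set` objects.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates
#'   (`0 <= start < end`).
#' @param label sample identifier stored as an attribute.
#'
#' @return A `lad_set` tibble with columns `chrom`, `start`, `end`.
#' @examples
#' lad_set("chr1", c(0L, 500L), c(100L, 900L), label = "CT0_r1")
#' @export
lad_set <- function(chrom = character(), start = integer(), end = integer(),
                    label = "") {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start and end must have the same length", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("interval coordinates must be finite", call. = FALSE)
  }
  if (any(start != floor(start)) || any(end != floor(end))) {
    stop("interval coordinates must be integers", call. = FALSE)
  }
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop(sprintf("invalid interval (start >= end) at position %d: %s:%s-%s",
                 bad[1], chrom[bad[1]], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)), call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end)
  attr(out, "label") <- label
  class(out) <- c("lad_set", class(tibble::tibble()))
  out
}

#' @rdname lad_set
#' @param x a `lad_set`.
#' @export
set_label <- function(x) {
  lb <- attr(x, "label", exact = TRUE)
  if (is.null(lb)) "" else lb
}

is_lad_set <- function(x) inherits(x, "lad_set")

assert_lad_set <- function(x, arg = "x") {
  if (!is_lad_set(x)) {
    stop(sprintf("`%s` must be a lad_set (see lad_set())", arg), call. = FALSE)
  }
  invisible(x)
}

## 0-based half-open -> 1-based closed GRanges and back
as_granges <- function(x, seqlevels = NULL) {
  lv <- sort(unique(c(seqlevels, x$chrom)))
  if (length(lv) == 0) lv <- "chrUn"
  gr <- GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lv),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
  gr
}

granges_to_lad_set <- function(gr, label = "") {
  gr <- GenomicRanges::sort(gr)
  lad_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    label = label
  )
}

#' Normalize an interval set
#'
#' Sorts intervals by (chrom, start) and merges overlapping or book-ended
#' (touching) intervals, so that the result is pairwise disjoint and
#' non-adjacent. Coverage is preserved except where overlaps are collapsed.
#' The operation is idempotent.
#'
#' @param x a `lad_set`.
#' @return A normalized `lad_set` with the same label.
#' @examples
#' normalize_lads(lad_set("chr1", c(0, 50), c(100, 150)))
#' @export
normalize_lads <- function(x) {
  assert_lad_set(x)
  if (nrow(x) == 0) return(x)
  gr <- GenomicRanges::reduce(as_granges(x))
  granges_to_lad_set(gr, label = set_label(x))
}

#' Total coverage of an interval set in base pairs
#'
#' @param x a `lad_set` (normalized sets give exact domain coverage; for
#'   unnormalized sets overlapping bases are counted multiply).
#' @return Total `sum(end - start)` in bp.
#' @export
coverage_bp <- function(x) {
  assert_lad_set(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

pair_granges <- function(a, b) {
  lv <- unique(c(a$chrom, b$chrom))
  list(a = as_granges(a, seqlevels = lv), b = as_granges(b, seqlevels = lv))
}

#' Base-pair-wise intersection, subtraction and union of interval sets
#'
#' `intersect_lads()` returns the bases covered by both sets,
#' `subtract_lads()` the bases of `a` not covered by `b`, and
#' `union_lads()` the bases covered by either set. All inputs are normalized
#' first; results are normalized `lad_set` objects. Coverage identities hold
#' exactly: `coverage(a \ b) = coverage(a) - coverage(a intersect b)`.
#'
#' @param a,b `lad_set` objects.
#' @param label label for the result.
#' @return A normalized `lad_set`.
#' @examples
#' a <- lad_set("chr1", 0, 100)
#' b <- lad_set("chr1", 50, 150)
#' intersect_lads(a, b)
#' subtract_lads(a, b)
#' union_lads(a, b)
#' @export
intersect_lads <- function(a, b, label = "") {
  assert_lad_set(a, "a"); assert_lad_set(b, "b")
  p <- pair_granges(a, b)
  granges_to_lad_set(GenomicRanges::intersect(p$a, p$b), label = label)
}

#' @rdname intersect_lads
#' @export
subtract_lads <- function(a, b, label = "") {
  assert_lad_set(a, "a"); assert_lad_set(b, "b")
  p <- pair_granges(a, b)
  granges_to_lad_set(GenomicRanges::setdiff(p$a, p$b), label = label)
}

#' @rdname intersect_lads
#' @export
union_lads <- function(a, b, label = "") {
  assert_lad_set(a, "a"); assert_lad_set(b, "b")
  p <- pair_granges(a, b)
  granges_to_lad_set(GenomicRanges::union(p$a, p$b), label = label)
}

#' Jaccard index of two interval sets
#'
#' Base-pair-wise intersection over union, the standard measure of LAD
#' overlap between replicates or consecutive time points. If both sets are
#' empty the index is undefined and `NA` is returned (not 0), to avoid a
#' spurious "no overlap" signal.
#'
#' @param a,b `lad_set` objects.
#' @return A fraction in `[0, 1]`, or `NA_real_` if both sets are empty.
#' @examples
#' jaccard_lads(lad_set("chr1", 0, 100), lad_set("chr1", 50, 150)) # 1/3
#' @export
jaccard_lads <- function(a, b) {
  assert_lad_set(a, "a"); assert_lad_set(b, "b")
  if (nrow(a) == 0 && nrow(b) == 0) return(NA_real_)
  u <- coverage_bp(union_lads(a, b))
  if (u == 0) return(NA_real_)
  coverage_bp(intersect_lads(a, b)) / u
}

#' Read and write BED interval files
#'
#' `read_bed()` parses BED3+ (tab-separated) files into a `lad_set`;
#' `track`/`browser` header lines and `#` comments are skipped. Coordinates
#' are kept in the native BED convention (0-based half-open), so
#' `write_bed(read_bed(f))` round-trips coordinates exactly. Malformed lines
#' raise an error naming the line number.
#'
#' @param path file path.
#' @param label sample label; defaults to the file name without extension.
#' @return `read_bed()` returns a `lad_set`; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)([[:space:]]|$)", lines) &
    !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(lad_set(label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    i <- idx[which(nf < 3)[1]]
    stop(sprintf("%s line %d: fewer than 3 tab-separated fields", path, i),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  s_chr <- vapply(fields, `[[`, character(1), 2)
  e_chr <- vapply(fields, `[[`, character(1), 3)
  ok <- grepl("^[0-9]+$", s_chr) & grepl("^[0-9]+$", e_chr)
  if (any(!ok)) {
    i <- idx[which(!ok)[1]]
    stop(sprintf("%s line %d: non-integer coordinates", path, i), call. = FALSE)
  }
  start <- as.numeric(s_chr)
  end <- as.numeric(e_chr)
  bad <- start >= end
  if (any(bad)) {
    i <- idx[which(bad)[1]]
    stop(sprintf("%s line %d: start >= end", path, i), call. = FALSE)
  }
  lad_set(chrom, start, end, label = label)
}

#' @rdname read_bed
#' @param x a `lad_set` to write.
#' @param names optional character vector of interval names (BED name field),
#'   e.g. LAD identifiers; recycled errors are not allowed.
#' @export
write_bed <- function(x, path, names = NULL) {
  assert_lad_set(x)
  ord <- order(x$chrom, x$start, x$end)
  df <- data.frame(chrom = x$chrom[ord],
                   start = format(x$start[ord], scientific = FALSE, trim = TRUE),
                   end = format(x$end[ord], scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  if (!is.null(names)) {
    if (length(names) != nrow(x)) {
      stop("`names` must have one entry per interval", call. = FALSE)
    }
    df$name <- names[ord]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
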