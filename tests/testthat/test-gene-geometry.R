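mk_genes <- function(...) {
  df <- tibble::as_tibble(data.frame(..., stringsAsFactors = FALSE))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

test_that("TSS membership respects strand", {
  lads <- normalize_lads(lad_set("chr1", 150, 250))
  g_plus <- mk_genes(gene_id = "a", chrom = "chr1", start = 200, end = 300,
                     strand = "+")
  g_minus <- mk_genes(gene_id = "b", chrom = "chr1", start = 200, end = 300,
                      strand = "-")
  expect_true(assign_membership(g_plus, lads))
  expect_false(assign_membership(g_minus, lads))
  # membership is invariant to input normalization order
  shuffled <- lad_set("chr1", c(200, 150), c(250, 210))
  expect_true(assign_membership(g_plus, normalize_lads(shuffled)))
})

test_that("distances match the worked examples", {
  lads <- normalize_lads(lad_set("chr1", c(0, 500), c(100, 600)))
  g <- mk_genes(gene_id = c("p", "in", "m"), chrom = "chr1",
                start = c(200, 520, 200), end = c(300, 540, 300),
                strand = c("+", "+", "-"))
  d <- gene_to_nearest_lad(g, lads)
  expect_equal(d$d5[1], 100)   # + strand: to upstream LAD 3' border
  expect_equal(d$d3[1], 200)
  expect_equal(d$nearest[1], 100)
  # gene inside a LAD: containing LAD excluded, first neighbors used
  expect_true(d$in_lad[2])
  expect_equal(d$d5[2], 520 - 100)
  expect_true(is.na(d$d3[2]))
  expect_equal(d$nearest[2], 420)
  # - strand mirrors the sides
  expect_equal(d$d5[3], 200)
  expect_equal(d$d3[3], 100)
})

test_that("partially overlapping LADs give distance 0 on that side", {
  lads <- normalize_lads(lad_set("chr1", 250, 400))
  g <- mk_genes(gene_id = "a", chrom = "chr1", start = 200, end = 300,
                strand = "+")
  d <- gene_to_nearest_lad(g, lads)
  expect_equal(d$d3, 0)
  expect_true(is.na(d$d5))
  expect_equal(d$nearest, 0)
})

test_that("distances agree with a brute-force border scan on random layouts", {
  set.seed(111)
  for (rep in 1:25) {
    lads <- random_set(sample(3:40, 1), chroms = c("chrA", "chrB"),
                       genome_len = 5000, max_width = 300)
    n_g <- 8
    chrom <- sample(c("chrA", "chrB"), n_g, replace = TRUE)
    start <- sample.int(4900, n_g)
    genes <- mk_genes(gene_id = paste0("g", 1:n_g), chrom = chrom,
                      start = start, end = start + sample.int(80, n_g),
                      strand = sample(c("+", "-"), n_g, replace = TRUE))
    d <- gene_to_nearest_lad(genes, lads)
    for (i in seq_len(n_g)) {
      o <- oracle_gene_distance(genes[i, ], lads)
      expect_equal(d$d5[i], o$d5)
      expect_equal(d$d3[i], o$d3)
      exp_near <- suppressWarnings(min(c(o$d5, o$d3), na.rm = TRUE))
      if (is.infinite(exp_near)) exp_near <- NA_real_
      expect_equal(d$nearest[i], exp_near)
    }
  }
})

test_that("mirroring the genome axis swaps d5/d3 and preserves nearest", {
  set.seed(112)
  G <- 5000
  lads <- random_set(10, chroms = "chrA", genome_len = G, max_width = 200)
  n_g <- 6
  start <- sample.int(G - 100, n_g)
  genes <- mk_genes(gene_id = paste0("g", 1:n_g), chrom = "chrA",
                    start = start, end = start + sample.int(60, n_g),
                    strand = sample(c("+", "-"), n_g, replace = TRUE))
  d <- gene_to_nearest_lad(genes, lads)
  # reflect coordinates x -> G - x and flip strands
  lads_m <- normalize_lads(lad_set("chrA", G - lads$end, G - lads$start))
  genes_m <- mk_genes(gene_id = genes$gene_id, chrom = "chrA",
                      start = G - genes$end, end = G - genes$start,
                      strand = ifelse(genes$strand == "+", "-", "+"))
  d_m <- gene_to_nearest_lad(genes_m, lads_m)
  expect_equal(d_m$d5, d$d5)
  expect_equal(d_m$d3, d$d3)
  expect_equal(d_m$nearest, d$nearest)
})

test_that("distance variation computes signed deltas, quadrants and exclusions", {
  mk_d <- function(nearest) tibble::tibble(gene_id = c("a", "b", "c"),
                                           in_lad = FALSE, d5 = nearest,
                                           d3 = nearest, nearest = nearest)
  dv <- distance_variation(mk_d(c(1000, 5, NA)), mk_d(c(400, 5, 1)),
                           mk_d(c(900, 5, 2)))
  v <- dv$variation
  expect_equal(v$delta_a[v$gene_id == "a"], -600)
  expect_equal(v$delta_b[v$gene_id == "a"], 500)
  expect_equal(v$label[v$gene_id == "a"], "decrease-then-increase")
  expect_equal(v$quadrant[v$gene_id == "a"], "Q2")
  expect_equal(v$quadrant[v$gene_id == "b"], "origin")
  expect_equal(dv$excluded$gene_id, "c")
  # telescoping identity on random inputs
  set.seed(113)
  a <- abs(rnorm(3, 1000, 300)); b <- abs(rnorm(3, 1000, 300))
  c3 <- abs(rnorm(3, 1000, 300))
  dv2 <- distance_variation(mk_d(a), mk_d(b), mk_d(c3))
  expect_equal(dv2$variation$delta_a + dv2$variation$delta_b, c3 - a)
})

test_that("gene capture near LADs follows the 2.5 Mb window rule", {
  lads <- tibble::tibble(lad_id = "LAD0001", chrom = "chr1", start = 10e6,
                         end = 12e6)
  genes <- mk_genes(gene_id = c("near5", "beyond", "inside"),
                    chrom = "chr1",
                    start = c(8e6, 14.6e6, 10.5e6),
                    end = c(8.1e6, 14.7e6, 10.6e6),
                    strand = "+")
  got <- genes_near_lads(genes, lads)
  expect_setequal(got$gene_id, c("near5", "inside"))
  expect_equal(got$position[got$gene_id == "near5"], "near")
  expect_equal(got$position[got$gene_id == "inside"], "inside")
  # oracle scan on a random layout
  set.seed(114)
  lads2 <- tibble::tibble(lad_id = sprintf("L%02d", 1:5), chrom = "chrA",
                          start = sort(sample.int(4e6, 5)), end = 0)
  lads2$end <- lads2$start + 1e5
  st <- sample.int(5e6, 40)
  genes2 <- mk_genes(gene_id = paste0("g", 1:40), chrom = "chrA",
                     start = st, end = st + 1e4, strand = "+")
  win <- 3e5
  got2 <- genes_near_lads(genes2, lads2, window_bp = win)
  for (j in seq_len(nrow(lads2))) {
    hit <- genes2$start < lads2$end[j] + win & genes2$end > lads2$start[j] - win
    expect_setequal(got2$gene_id[got2$lad_id == lads2$lad_id[j]],
                    genes2$gene_id[hit])
  }
})
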