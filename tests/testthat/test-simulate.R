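grid2 <- toy_grid()

test_that("genome generation is deterministic and validates packing", {
  g1 <- generate_genome(seed = 5)
  g2 <- generate_genome(seed = 5)
  expect_identical(g1, g2)
  g3 <- generate_genome(seed = 6)
  expect_false(identical(g1$base_lads, g3$base_lads))
  expect_error(generate_genome(n_lads = 500, chrom_length = 1e6,
                               lad_size_range = c(2e5, 8e5), seed = 1),
               "infeasible packing")
  # no LADs: genes are all far
  g0 <- generate_genome(n_lads = 0, n_genes = 10, seed = 2)
  expect_equal(nrow(g0$base_lads), 0)
  expect_true(all(g0$genes$placement == "far"))
  # base LADs are disjoint per chromosome
  bl <- g1$base_lads
  for (ch in unique(bl$chrom)) {
    b <- bl[bl$chrom == ch, ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("gene placement labels are honest", {
  g <- generate_genome(seed = 11)
  lads <- lad_set(g$base_lads$chrom, g$base_lads$start, g$base_lads$end)
  memb <- assign_membership(g$genes, normalize_lads(lads))
  d <- gene_to_nearest_lad(g$genes, normalize_lads(lads))
  expect_true(all(memb[g$genes$placement == "inside"]))
  expect_true(all(!memb[g$genes$placement == "far"]))
  far_near <- d$nearest[g$genes$placement == "far"]
  expect_true(all(is.na(far_near) | far_near >= 5e6))
})

test_that("zero-amplitude, zero-noise dynamics reproduce the base LADs at every sample", {
  g <- generate_genome(seed = 3, n_lads = 6, n_genes = 6)
  scen <- default_lad_scenario(g$base_lads, periodic_fraction = 0,
                               noise_fraction = 0, gate_fraction = 0)
  tc <- generate_lad_timecourse(g$base_lads, scen, grid2, seed = 1)
  for (s in tc$lad_sets) {
    expect_equal(s$start, g$base_lads$start)
    expect_equal(s$end, g$base_lads$end)
  }
  expect_equal(tc$n_clamped, 0L)
})

test_that("appear-disappear gates remove the LAD at closed CTs", {
  g <- generate_genome(seed = 4, n_lads = 4, n_genes = 4)
  scen <- default_lad_scenario(g$base_lads, periodic_fraction = 0,
                               noise_fraction = 0, gate_fraction = 1, seed = 2)
  tc <- generate_lad_timecourse(g$base_lads, scen, grid2, seed = 2)
  truth <- tc$truth
  for (i in seq_len(nrow(g$base_lads))) {
    id <- g$base_lads$lad_id[i]
    gate <- scen$gates[scen$gates$lad_id == id, ]
    for (ci in seq_along(grid2$ct_labels)) {
      t <- grid2$times_h[ci]
      open <- cos(2 * pi * (t - gate$gate_phase_h) / gate$gate_period_h) >= 0
      in_bed <- any(tc$lad_sets[[paste0(grid2$ct_labels[ci], "_r1")]]$start ==
                      g$base_lads$start[i])
      expect_equal(in_bed, open)
      rel <- truth$rel[truth$lad_id == id & truth$ct == grid2$ct_labels[ci] &
                         truth$replicate == "r1"]
      if (!open) expect_equal(rel, c(0, 0))
    }
  }
})

test_that("border_series inverts the generator within coordinate quantization", {
  g <- generate_genome(seed = 12, n_lads = 10, n_genes = 5)
  scen <- default_lad_scenario(g$base_lads, periodic_fraction = 0.8,
                               noise_fraction = 0.2, gate_fraction = 0,
                               seed = 3)
  tc <- generate_lad_timecourse(g$base_lads, scen, grid2, seed = 4)
  covmax_truth <- g$base_lads  # the generator's base regions are the truth
  bs <- border_series(covmax_truth, tc$lad_sets, grid2)
  joined <- merge(as.data.frame(bs), as.data.frame(tc$truth),
                  by = c("lad_id", "side", "ct", "replicate"))
  L <- covmax_truth$length_bp[match(joined$lad_id, covmax_truth$lad_id)]
  expect_true(all(abs(joined$value - joined$rel) <= 1 / L + 1e-12))
})

test_that("expression generation honors the stated cosine arithmetic and seeds", {
  specs <- tibble::tibble(gene_id = "g", class = "periodic", period_h = 24,
                          phase_h = 0, amplitude = 2, base = 5, noise_sd = 0)
  ex <- generate_expression_timecourse(specs, grid2, n_replicates = 2, seed = 1)
  expect_equal(unname(ex$fpkm[1, c("CT0_r1", "CT6_r1", "CT12_r1")]),
               c(7, 5, 3))
  # identical columns for a constant gene with zero noise
  cst <- tibble::tibble(gene_id = "c", class = "constant", period_h = NA,
                        phase_h = NA, amplitude = 0, base = 4, noise_sd = 0)
  exc <- generate_expression_timecourse(cst, grid2, n_replicates = 3, seed = 2)
  expect_true(all(exc$fpkm == 4))
  # seeded reproducibility, byte-identical TSV
  spec2 <- tibble::tibble(gene_id = "n", class = "noise", period_h = NA,
                          phase_h = NA, amplitude = 0, base = 2, noise_sd = 1)
  e1 <- generate_expression_timecourse(spec2, grid2, 2, seed = 3)
  e2 <- generate_expression_timecourse(spec2, grid2, 2, seed = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fpkm(e1$fpkm, f1); write_fpkm(e2$fpkm, f2)
  expect_identical(readLines(f1), readLines(f2))
  # FPKM never negative; truncation is counted
  big_noise <- tibble::tibble(gene_id = "t", class = "noise", period_h = NA,
                              phase_h = NA, amplitude = 0, base = 0.1,
                              noise_sd = 5)
  e3 <- generate_expression_timecourse(big_noise, grid2, 3, seed = 4)
  expect_true(all(e3$fpkm >= 0))
  expect_gt(e3$n_truncated, 0)
})
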