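grid2 <- toy_grid()

# builds a full named list of identical sets for every (CT, replicate)
constant_sets <- function(set, grid = grid2) {
  nms <- as.vector(t(outer(grid$ct_labels, grid$replicates, paste, sep = "_")))
  out <- lapply(nms, function(nm) set)
  names(out) <- nms
  out
}

test_that("cov_max is the merged union across all samples", {
  sets <- list(CT0_r1 = lad_set("chr1", 0, 100),
               CT0_r2 = lad_set("chr1", 50, 150))
  cm <- compute_covmax(sets)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$start, 0)
  expect_equal(cm$end, 150)
  expect_equal(cm$length_bp, 150)

  sets2 <- list(a = lad_set("chr1", 0, 100), b = lad_set("chr1", 500, 600))
  expect_equal(nrow(compute_covmax(sets2)), 2)

  # oracle: cov_max == normalize(union of everything); regions disjoint
  set.seed(21)
  sets3 <- lapply(1:6, function(i) random_set(20))
  names(sets3) <- paste0("CT", rep(c(0, 6, 12), each = 2), "_r", 1:2)
  cm3 <- compute_covmax(sets3)
  manual <- Reduce(union_lads, sets3)
  expect_equal(cm3$start, manual$start)
  expect_equal(cm3$end, manual$end)
  if (nrow(cm3) > 1) {
    same_chrom <- cm3$chrom[-1] == cm3$chrom[-nrow(cm3)]
    expect_true(all(cm3$start[-1][same_chrom] > cm3$end[-nrow(cm3)][same_chrom]))
  }
  # union covers every input sample
  for (s in sets3) {
    expect_equal(nrow(subtract_lads(s, lad_set(cm3$chrom, cm3$start, cm3$end))), 0)
  }
})

test_that("border standardization follows the 0-1 cov_max convention", {
  cm <- tibble::tibble(lad_id = "LAD0001", chrom = "chr1", start = 1000,
                       end = 2000, length_bp = 1000)
  # fragment equal to cov_max -> (1, 1); absent -> (0, 0); partial 5' retraction
  frag <- lad_set("chr1", 1200, 2000)
  sets <- constant_sets(frag)
  sets[["CT6_r1"]] <- lad_set("chr1", 1000, 2000)   # full
  sets[["CT6_r2"]] <- lad_set()                      # absent
  bs <- border_series(cm, sets, grid2)
  val <- function(ct, rep, side) {
    bs$value[bs$ct == ct & bs$replicate == rep & bs$side == side]
  }
  expect_equal(val("CT0", "r1", "5p"), 0.8)
  expect_equal(val("CT0", "r1", "3p"), 1.0)
  expect_equal(val("CT6", "r1", "5p"), 1.0)
  expect_equal(val("CT6", "r1", "3p"), 1.0)
  expect_equal(val("CT6", "r2", "5p"), 0.0)
  expect_equal(val("CT6", "r2", "3p"), 0.0)
})

test_that("internal splits are ignored: only outermost extremities count", {
  cm <- tibble::tibble(lad_id = "LAD0001", chrom = "chr1", start = 0,
                       end = 1000, length_bp = 1000)
  split_frag <- lad_set("chr1", c(100, 600), c(300, 900))
  bs <- border_series(cm, constant_sets(split_frag), grid2)
  expect_equal(unique(bs$value[bs$side == "5p"]), 1 - 100 / 1000)
  expect_equal(unique(bs$value[bs$side == "3p"]), 1 - (1000 - 900) / 1000)
})

test_that("rel5 + rel3 - 1 equals fragment span over cov_max length", {
  set.seed(31)
  for (i in 1:20) {
    L <- 1000
    a <- sample(0:700, 1)
    b <- a + sample(100:(L - a - 1), 1)
    cm <- tibble::tibble(lad_id = "LAD0001", chrom = "chr1", start = 0,
                         end = L, length_bp = L)
    bs <- border_series(cm, constant_sets(lad_set("chr1", a, b)), grid2)
    rel5 <- bs$value[bs$side == "5p"][1]
    rel3 <- bs$value[bs$side == "3p"][1]
    expect_equal(rel5 + rel3 - 1, (b - a) / L)
  }
})

test_that("a fragment outside its cov_max region is an internal error", {
  cm <- tibble::tibble(lad_id = "LAD0001", chrom = "chr1", start = 100,
                       end = 200, length_bp = 100)
  sets <- constant_sets(lad_set("chr1", 50, 150))
  expect_error(border_series(cm, sets, grid2), "outside its cov_max")
})

test_that("gain/loss decomposition classifies stand-alone vs extension", {
  ref <- lad_set("chr1", 0, 100)
  comp <- lad_set("chr1", c(0, 300), c(150, 400))
  gl <- classify_gain_loss(ref, comp)
  gained <- gl[gl$direction == "gained", ]
  gained <- gained[order(gained$start), ]
  expect_equal(gained$mode, c("extension", "stand-alone"))
  expect_equal(gained$bp, c(50, 100))
  expect_equal(nrow(gl[gl$direction == "lost", ]), 0)
  expect_equal(nrow(classify_gain_loss(ref, ref)), 0)

  # coverage identity + per-bp oracle on random sets
  set.seed(41)
  for (i in 1:20) {
    a <- random_set(15); b <- random_set(15)
    gl2 <- classify_gain_loss(a, b)
    gained_bp <- sum(gl2$bp[gl2$direction == "gained"])
    lost_bp <- sum(gl2$bp[gl2$direction == "lost"])
    expect_equal(coverage_bp(b) - coverage_bp(a), gained_bp - lost_bp)
    # oracle: tag each gained bp by whether its containing b-LAD touches a
    if (nrow(gl2) > 0) {
      for (j in seq_len(nrow(gl2))) {
        own <- if (gl2$direction[j] == "gained") b else a
        other <- if (gl2$direction[j] == "gained") a else b
        hit <- own[own$chrom == gl2$chrom[j] & own$start <= gl2$start[j] &
                     own$end >= gl2$end[j], ]
        expect_equal(nrow(hit), 1)
        touches <- coverage_bp(intersect_lads(
          lad_set(hit$chrom, hit$start, hit$end), other)) > 0
        expect_equal(gl2$mode[j] != "stand-alone", touches)
      }
    }
  }
})

test_that("book-ended gains count as extension", {
  gl <- classify_gain_loss(lad_set("chr1", 0, 100), lad_set("chr1", 0, 200))
  expect_equal(gl$mode, "extension")
  expect_equal(gl$bp, 100)
})

test_that("lad_stats reports coverage, count and median size", {
  st <- lad_stats(list(x = lad_set("chr1", c(0, 200), c(100, 400))))
  expect_equal(st$coverage_bp, 300)
  expect_equal(st$n_lads, 2)
  expect_equal(st$median_size_bp, 150)
  st1 <- lad_stats(list(x = lad_set("chr1", 10, 60)))
  expect_equal(st1$median_size_bp, 50)
  st0 <- lad_stats(list(x = lad_set()))
  expect_equal(st0$n_lads, 0)
  expect_true(is.na(st0$median_size_bp))
  # independent recount on random sets
  set.seed(51)
  y <- random_set(25)
  sty <- lad_stats(list(y = y))
  expect_equal(sty$coverage_bp, sum(y$end - y$start))
  expect_equal(sty$median_size_bp, median(y$end - y$start))
})

test_that("variable-border filter keeps only borders that vary", {
  cm <- tibble::tibble(lad_id = "LAD0001", chrom = "chr1", start = 0,
                       end = 1000, length_bp = 1000)
  sets <- constant_sets(lad_set("chr1", 0, 1000))
  sets[["CT12_r1"]] <- lad_set("chr1", 100, 1000)  # 5' varies once
  bs <- border_series(cm, sets, grid2)
  kept <- filter_variable_borders(bs)
  expect_setequal(unique(kept$side), "5p")
  expect_equal(nrow(filter_variable_borders(bs, min_sd = 0.5)), 0)
})
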