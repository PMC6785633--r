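## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own interval/rank machinery: interval algebra is checked
## against per-bp logical membership vectors, JTK p-values against full
## permutation enumeration, and gene distances against a linear border scan.

# ---- per-bp interval oracle (toy genome, <= 10 kb per chrom) ----

# lad_set -> named list of logical membership vectors of length genome_len
bp_mask <- function(set, chroms, genome_len) {
  masks <- lapply(chroms, function(ch) {
    m <- rep(FALSE, genome_len)
    rows <- which(set$chrom == ch)
    for (i in rows) {
      s <- set$start[i]; e <- set$end[i]
      if (e > s) m[(s + 1):e] <- TRUE  # bp k occupies index k+1 (0-based)
    }
    m
  })
  names(masks) <- chroms
  masks
}

mask_to_set <- function(masks, label = "") {
  chrom <- character(); start <- numeric(); end <- numeric()
  for (ch in names(masks)) {
    r <- rle(masks[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    chrom <- c(chrom, rep(ch, sum(keep)))
    start <- c(start, starts[keep])
    end <- c(end, ends[keep])
  }
  lad_set(chrom, start, end, label = label)
}

oracle_op <- function(a, b, op, chroms, genome_len) {
  ma <- bp_mask(a, chroms, genome_len)
  mb <- bp_mask(b, chroms, genome_len)
  out <- lapply(chroms, function(ch) {
    switch(op,
           intersect = ma[[ch]] & mb[[ch]],
           subtract = ma[[ch]] & !mb[[ch]],
           union = ma[[ch]] | mb[[ch]])
  })
  names(out) <- chroms
  mask_to_set(out)
}

oracle_jaccard <- function(a, b, chroms, genome_len) {
  ma <- unlist(bp_mask(a, chroms, genome_len))
  mb <- unlist(bp_mask(b, chroms, genome_len))
  u <- sum(ma | mb)
  if (u == 0) NA_real_ else sum(ma & mb) / u
}

random_set <- function(n, chroms = c("chrA", "chrB"), genome_len = 1000,
                       max_width = 120) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(genome_len - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  normalize_lads(lad_set(chrom, start, pmin(start + width, genome_len)))
}

expect_same_intervals <- function(x, y) {
  expect_equal(as.data.frame(x[, c("chrom", "start", "end")]),
               as.data.frame(y[, c("chrom", "start", "end")]),
               ignore_attr = TRUE)
}

# ---- permutation enumeration oracle for the JTK exact null ----

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  # insert n into each position of each (n-1)-permutation
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1)
      row <- row + 1
    }
  }
  out
}

# Independent JT statistic: concordant pairs between ordered reference groups,
# ties counted 1/2, computed directly from definitions.
oracle_jt_stat <- function(values, ref) {
  J <- 0
  n <- length(values)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (ref[j] > ref[i] + 1e-9) {
        J <- J + (values[j] > values[i]) + 0.5 * (values[j] == values[i])
      }
    }
  }
  J
}

# Enumerated one-sided p-value of the JT statistic for a cosine reference.
oracle_jtk_config_p <- function(values, times_h, period, lag) {
  ref <- round(cos(2 * pi * (times_h - lag) / period), 9)
  J_obs <- oracle_jt_stat(values, ref)
  perms <- all_permutations(length(values))
  J_all <- apply(perms, 1, function(ix) oracle_jt_stat(values[ix], ref))
  mean(J_all >= J_obs - 1e-9)
}

# ---- brute-force gene distance oracle ----

# Straight transcription of the distance rule: scan every LAD border.
oracle_gene_distance <- function(gene, lads) {
  L <- lads[lads$chrom == gene$chrom, ]
  d_left <- NA_real_; d_right <- NA_real_
  if (nrow(L) > 0) {
    containing <- L$start <= gene$start & L$end >= gene$end
    Lx <- L[!containing, , drop = FALSE]
    if (nrow(Lx) > 0) {
      best_l <- Inf; best_r <- Inf
      for (i in seq_len(nrow(Lx))) {
        if (Lx$start[i] < gene$start && Lx$end[i] > gene$start) best_l <- 0
        if (Lx$end[i] <= gene$start) {
          best_l <- min(best_l, gene$start - Lx$end[i])
        }
        if (Lx$start[i] < gene$end && Lx$end[i] > gene$end) best_r <- 0
        if (Lx$start[i] >= gene$end) {
          best_r <- min(best_r, Lx$start[i] - gene$end)
        }
      }
      if (is.finite(best_l)) d_left <- best_l
      if (is.finite(best_r)) d_right <- best_r
    }
  }
  if (gene$strand == "+") list(d5 = d_left, d3 = d_right)
  else list(d5 = d_right, d3 = d_left)
}

# ---- shared fixtures ----

toy_grid <- function(replicates = c("r1", "r2")) {
  time_grid(paste0("CT", seq(0, 30, 6)), seq(0, 30, 6), replicates)
}

cosine_series <- function(period, phase = 0, amplitude = 0.4, base = 0.5,
                          noise_sd = 0, times = seq(0, 30, 6)) {
  v <- base + amplitude * cos(2 * pi * (times - phase) / period)
  if (noise_sd > 0) v <- v + rnorm(length(times), 0, noise_sd)
  pmin(pmax(v, 0), 1)
}
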