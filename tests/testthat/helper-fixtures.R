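# Shared fixture builders and the independent brute-force ROH oracle.

# small genome + evenly spaced map for constructed-genotype tests
toy_genome <- function(lengths = c(C1 = 30e6, C2 = 20e6)) ra_genome(lengths)

toy_map <- function(genome, spacing = 15000) {
  chrom <- character(0); pos <- numeric(0)
  for (cc in genome$chrom_ids) {
    p <- seq(spacing, genome$chrom_lengths[[cc]], by = spacing)
    chrom <- c(chrom, rep(cc, length(p)))
    pos <- c(pos, p)
  }
  marker_map(chrom, pos, genome = genome)
}

# genotype matrix from a list of per-individual vectors
toy_gm <- function(map, ...) {
  rows <- list(...)
  genotype_matrix(do.call(rbind, rows), map,
                  ids = sprintf("ind%02d", seq_along(rows)))
}

# Brute-force ROH caller used as the oracle: enumerates every window and
# every run explicitly, with no shared code with call_roh().
roh_oracle_chrom <- function(geno, pos, params) {
  w <- params$window_snp
  m <- length(geno)
  segs <- list()
  if (m >= w) {
    nwin <- m - w + 1L
    hom_win <- rep(FALSE, nwin)
    for (k in seq_len(nwin)) {
      win <- geno[k:(k + w - 1L)]
      hom_win[k] <- sum(win == 1L, na.rm = TRUE) <= params$window_het &&
        sum(is.na(win)) <= params$window_missing
    }
    elig <- rep(FALSE, m)
    ws <- seq_len(nwin)
    for (i in seq_len(m)) {
      ks <- which(ws <= i & ws + w - 1L >= i)
      if (length(ks))
        elig[i] <- mean(hom_win[ks]) >= params$hit_threshold
    }
    runs <- list()
    cur <- integer(0)
    for (i in seq_len(m)) {
      if (elig[i]) {
        if (length(cur) &&
            (pos[i] - pos[cur[length(cur)]]) > params$max_gap_kb * 1000) {
          runs[[length(runs) + 1L]] <- cur
          cur <- integer(0)
        }
        cur <- c(cur, i)
      } else if (length(cur)) {
        runs[[length(runs) + 1L]] <- cur
        cur <- integer(0)
      }
    }
    if (length(cur)) runs[[length(runs) + 1L]] <- cur
    for (r in runs) {
      homs <- r[!is.na(geno[r]) & geno[r] != 1L]
      if (!length(homs)) next
      a <- min(homs); b <- max(homs)
      n <- b - a + 1L
      lk <- (pos[b] - pos[a] + 1) / 1000
      if (n >= params$min_snp && lk >= params$min_kb &&
          lk / n <= params$density_kb)
        segs[[length(segs) + 1L]] <- data.frame(start = pos[a], end = pos[b],
                                                n_snps = n, length_kb = lk)
    }
  }
  if (!length(segs))
    return(data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric()))
  do.call(rbind, segs)
}

roh_oracle <- function(gm, map, params) {
  out <- list()
  for (ii in seq_len(nrow(gm))) {
    for (cc in unique(map$chrom)) {
      jj <- which(map$chrom == cc)
      seg <- roh_oracle_chrom(gm[ii, jj], map$pos[jj], params)
      if (nrow(seg))
        out[[length(out) + 1L]] <- cbind(
          data.frame(individual = rownames(gm)[ii], chrom = cc),
          seg)
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random ROH-calling instance: genotypes with planted homozygous tracts
# and parameters drawn from the calibration grid
random_roh_instance <- function(max_snps = 300, max_ind = 5) {
  m <- sample(50:max_snps, 1L)
  n <- sample.int(max_ind, 1L)
  pos <- sort(sample.int(m * 30000L, m))
  map <- marker_map(rep("C1", m), pos)
  gm <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE,
                      prob = c(0.4, 0.25, 0.25, 0.1)),
               nrow = n)
  # plant a few near-homozygous tracts so segments actually occur
  for (i in seq_len(n)) {
    for (k in seq_len(sample(0:2, 1L))) {
      a <- sample.int(m - 40L, 1L)
      len <- sample(40:min(120L, m - a), 1L)
      tract <- sample(c(0L, 2L), len, replace = TRUE,
                      prob = c(0.5, 0.5))
      noise <- runif(len)
      tract[noise < 0.02] <- 1L
      tract[noise > 0.98] <- NA
      gm[i, a:(a + len - 1L)] <- tract
    }
  }
  params <- roh_params(
    window_snp = sample(24:40, 1L),
    window_het = sample(0:1, 1L),
    window_missing = sample(0:5, 1L),
    hit_threshold = 0.05,
    min_kb = sample(c(200, 500), 1L),
    max_gap_kb = sample(c(100, 500, 1000), 1L),
    density_kb = sample(c(50, 100), 1L))
  list(gm = genotype_matrix(gm, map), map = map, params = params)
}

expect_same_segments <- function(got, want) {
  cols <- c("individual", "chrom", "start", "end", "n_snps")
  got <- got[do.call(order, got[cols]), cols]
  want <- want[do.call(order, want[cols]), cols]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
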