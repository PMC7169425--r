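hwe_gm <- function(map, n, p, seed = 1) {
  set.seed(seed)
  genotype_matrix(matrix(stats::rbinom(n * nrow(map), 2L,
                                       rep(p, each = n)), nrow = n), map)
}

test_that("window counts follow the n_c - 36 bookkeeping on any map", {
  g <- toy_genome(c(C1 = 30e6, C2 = 20e6, C3 = 10e6))
  n_c <- c(100, 61, 37)
  map <- marker_map(rep(g$chrom_ids, n_c),
                    unlist(lapply(seq_along(n_c), function(i)
                      sort(sample.int(g$chrom_lengths[i], n_c[i])))),
                    genome = g)
  gm <- hwe_gm(map, 8, runif(nrow(map), 0.1, 0.9), seed = 2)
  st <- scan_windows(gm, map, window_snp = 37)
  expect_equal(nrow(st), sum(n_c - 36))
  expect_equal(as.vector(table(st$chrom)[g$chrom_ids]), n_c - 36L)
  # a chromosome below the window size is skipped with a warning
  map2 <- marker_map(c(rep("C1", 50), rep("C2", 10)),
                     c(sort(sample.int(30e6, 50)),
                       sort(sample.int(20e6, 10))))
  gm2 <- hwe_gm(map2, 8, runif(60, 0.2, 0.8), seed = 3)
  expect_warning(st2 <- scan_windows(gm2, map2, 37), "C2")
  expect_equal(nrow(st2), 14L)
})

test_that("Hp hits its algebraic extremes", {
  map <- marker_map(rep("C1", 40), sort(sample.int(1e6, 40)))
  mono <- genotype_matrix(matrix(0L, nrow = 4, ncol = 40), map)
  # a monomorphic scan is degenerate (sd 0) and must error
  expect_error(scan_windows(mono, map, 37), "degenerate")
  # every site balanced: all windows at the 0.5 maximum, which is also a
  # degenerate (sd 0) scan
  half <- genotype_matrix(matrix(c(0L, 0L, 2L, 2L), nrow = 4, ncol = 40),
                          map)
  expect_error(scan_windows(half, map, 37), "degenerate")
  s_maj <- 37 * 4; s_min <- 37 * 4
  expect_equal(2 * s_maj * s_min / (s_maj + s_min)^2, 0.5)
})

test_that("windows mixing monomorphic and balanced sites span the Hp range", {
  set.seed(8)
  m <- 200
  map <- marker_map(rep("C1", m), sort(sample.int(5e6, m)))
  p <- runif(m, 0.05, 0.95)
  p[1:60] <- 0       # a fixed stretch: Hp = 0 windows
  gm <- hwe_gm(map, 20, p, seed = 9)
  st <- scan_windows(gm, map, 37)
  expect_true(all(st$Hp >= 0 & st$Hp <= 0.5))
  expect_equal(st$Hp[1], 0)   # fully monomorphic window
  expect_equal(st$ZHp, (st$Hp - mean(st$Hp)) /
                 sqrt(mean((st$Hp - mean(st$Hp))^2)))
})

test_that("ZHp is standardized to mean 0 and sd 1 to 1e-9", {
  set.seed(12)
  g <- toy_genome(c(C1 = 30e6, C2 = 20e6))
  map <- toy_map(g, spacing = 200000)
  gm <- hwe_gm(map, 30, runif(nrow(map), 0.1, 0.9), seed = 13)
  st <- scan_windows(gm, map, 37)
  expect_lt(abs(mean(st$ZHp)), 1e-9)
  expect_lt(abs(sqrt(mean(st$ZHp^2)) - 1), 1e-9)
})

test_that("Hp is invariant to which allele is labeled as reference", {
  set.seed(21)
  m <- 120
  map <- marker_map(rep("C1", m), sort(sample.int(2e6, m)))
  gm <- hwe_gm(map, 12, runif(m, 0.1, 0.9), seed = 22)
  flipped <- genotype_matrix(2L - unclass(gm), map)
  st1 <- scan_windows(gm, map, 37)
  st2 <- scan_windows(flipped, map, 37)
  expect_equal(st1$Hp, st2$Hp)
  expect_equal(st1$ZHp, st2$ZHp)
})

test_that("window tags follow the suggestive and strict thresholds", {
  st <- data.frame(chrom = "C1", start = 1:5, end = 2:6,
                   ZHp = c(-3.2, -2.7, 0, 2.7, 3.2))
  tagged <- classify_windows(st)
  expect_equal(tagged$tag, c("low-strict", "low-suggestive", "none",
                             "high-suggestive", "high-strict"))
  # on standard-normal scores about 1.24% of windows pass |ZHp| >= 2.5
  set.seed(33)
  z <- rnorm(20823)
  frac <- mean(abs(z) >= 2.5)
  expected <- 2 * pnorm(-2.5)
  bound <- 3 * sqrt(expected * (1 - expected) / 20823)
  expect_lt(abs(frac - expected), bound)
})

test_that("regions merge overlapping and bookended windows per class/tier", {
  st <- data.frame(
    chrom = c("C1", "C1", "C1", "C1"),
    start = c(100e3, 300e3, 800e3, 900e3),
    end = c(500e3, 700e3, 850e3, 950e3),
    ZHp = c(-3.5, -3.1, 2.6, 2.8))
  tagged <- classify_windows(st)
  reg <- merge_regions(tagged)
  low_strict <- reg[reg$class == "low" & reg$tier == "strict", ]
  expect_equal(nrow(low_strict), 1L)
  expect_equal(low_strict$start, 100e3)
  expect_equal(low_strict$end, 700e3)
  expect_equal(low_strict$n_windows, 2L)
  # high suggestive windows are separate (gap > 1 bp)
  high_sug <- reg[reg$class == "high" & reg$tier == "suggestive", ]
  expect_equal(nrow(high_sug), 2L)
  # strict windows are members of their suggestive-tier region too
  low_sug <- reg[reg$class == "low" & reg$tier == "suggestive", ]
  expect_equal(low_sug$n_windows, 2L)
})

test_that("three windows sharing 36 of 37 SNPs merge into one region", {
  set.seed(44)
  m <- 39
  map <- marker_map(rep("C1", m), sort(sample.int(2e6, m)))
  st <- data.frame(chrom = "C1",
                   start = map$pos[1:3], end = map$pos[37:39],
                   ZHp = c(-2.6, -2.8, -2.7))
  reg <- merge_regions(classify_windows(st))
  sug <- reg[reg$tier == "suggestive", ]
  expect_equal(nrow(sug), 1L)
  expect_equal(sug$n_windows, 3L)
  expect_equal(sug$start, map$pos[1])
  expect_equal(sug$end, map$pos[39])
})

test_that("markers from the bundled table match regions by position", {
  ann <- turbot_qtl_markers()
  regions <- data.frame(
    chrom = c("C02", "C08"),
    start = c(18400000, 900000),
    end = c(19300000, 1100000),
    class = c("low", "high"),
    tier = c("strict", "suggestive"),
    n_windows = c(5L, 2L), peak_zhp = c(-3.4, 2.7))
  hit <- intersect_markers(regions, ann)
  c02 <- sort(strsplit(hit$regions$markers[1], ",")[[1]])
  expect_equal(c02, sort(c("Sma-USC223", "Sma-USC50", "Sma-E183",
                           "7415_42")))
  c08 <- strsplit(hit$regions$markers[2], ",")[[1]]
  expect_true("Sma-E99" %in% c08)
  expect_true(all(hit$markers$pos >= hit$markers$region_start &
                    hit$markers$pos <= hit$markers$region_end))
  none <- intersect_markers(regions, ann[0, ])
  expect_equal(none$regions$markers, c("", ""))
  expect_equal(nrow(none$markers), 0L)
})

test_that("an injected sweep is recovered as a strict low-diversity region", {
  sw <- sweep_spec("C02", 5e6, 9e6, kind = "low", intensity = 1)
  cfg <- sim_config(n_snps = 8000, seed = 61, sweeps = list(sw))
  b <- build_design(cfg, design_broodstock(46))
  st <- classify_windows(scan_windows(b$gm, b$map))
  reg <- merge_regions(st)
  strict_low <- reg[reg$class == "low" & reg$tier == "strict", ]
  expect_true(any(strict_low$chrom == "C02" & strict_low$start <= 9e6 &
                    strict_low$end >= 5e6))
  # and a balancing region is at least suggestive high
  hi <- sweep_spec("C05", 5e6, 9e6, kind = "high", intensity = 1)
  cfgw <- sim_config(n_snps = 8000, seed = 62, sweeps = list(hi))
  w <- build_design(cfgw, design_wild(36))
  regw <- merge_regions(classify_windows(scan_windows(w$gm, w$map)))
  hi_sug <- regw[regw$class == "high" & regw$tier == "suggestive", ]
  expect_true(any(hi_sug$chrom == "C05" & hi_sug$start <= 9e6 &
                    hi_sug$end >= 5e6))
})
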