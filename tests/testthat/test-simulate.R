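test_that("founder heterozygosity matches the binomial expectation", {
  cfg <- sim_config(n_snps = 2000, seed = 31, maf = maf_fixed(0.5),
                    error_rate = 0, missing_rate = 0)
  f <- simulate_founders(cfg, 100)
  h1 <- f$haplotypes[seq(1, 200, 2), ]
  h2 <- f$haplotypes[seq(2, 200, 2), ]
  het <- mean(h1 != h2)
  se <- sqrt(0.5 * 0.5 / length(h1))
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("the same seed reproduces identical founders and designs", {
  cfg <- sim_config(n_snps = 500, seed = 77)
  f1 <- simulate_founders(sim_config(n_snps = 500, seed = 77,
                                     maf = maf_beta(0.8, 0.8)), 5)
  f2 <- simulate_founders(sim_config(n_snps = 500, seed = 77,
                                     maf = maf_beta(0.8, 0.8)), 5)
  expect_identical(f1$haplotypes, f2$haplotypes)
  expect_identical(f1$map$pos, f2$map$pos)
  d1 <- build_design(cfg, design_families(c(full_sib = 2), 3))
  d2 <- build_design(cfg, design_families(c(full_sib = 2), 3))
  expect_identical(unclass(d1$gm), unclass(d2$gm))
  expect_identical(d1$truth$f_true, d2$truth$f_true)
  expect_identical(d1$truth$segments, d2$truth$segments)
})

test_that("monomorphic founders (maf 0) leave filter_sites an empty panel", {
  cfg <- sim_config(n_snps = 200, seed = 5, maf = maf_fixed(0),
                    error_rate = 0, missing_rate = 0)
  f <- simulate_founders(cfg, 4)
  gm <- genotype_matrix(f$haplotypes[c(1, 3, 5, 7), ] +
                          f$haplotypes[c(2, 4, 6, 8), ], f$map)
  expect_error(filter_sites(gm, f$map, min_call_rate = 0), "empty panel")
})

test_that("crossover counts follow the genetic map length", {
  g <- ra_genome(c(C1 = 36e6))  # 60 cM at 0.6 Mb/cM
  cfg <- sim_config(genome = g, n_snps = 200, mb_per_cm = 0.6,
                    maf = maf_fixed(0.5), seed = 12)
  f <- simulate_founders(cfg, 2)
  pair <- list(founder_haplotype(f, 1), founder_haplotype(f, 2))
  set.seed(1234)
  n_rep <- 3000
  # parents are founders with distinct labels, so every crossover is a
  # label switch in the gamete's segment list
  xo <- vapply(seq_len(n_rep), function(i)
    nrow(meiose(pair, f$map, cfg)$segs) - 1L, integer(1))
  expect_lt(abs(mean(xo) - 0.6), 3 * sqrt(0.6 / n_rep))
})

test_that("infinite mb_per_cm gives a gamete equal to one parental haplotype", {
  g <- ra_genome(c(C1 = 10e6))
  cfg <- sim_config(genome = g, n_snps = 100, mb_per_cm = Inf,
                    maf = maf_fixed(0.4), seed = 2)
  f <- simulate_founders(cfg, 2)
  pair <- list(founder_haplotype(f, 1), founder_haplotype(f, 2))
  gam <- meiose(pair, f$map, cfg)
  expect_equal(nrow(gam$segs), 1L)
  src <- gam$segs$label
  expect_true(identical(gam$alleles, pair[[src]]$alleles))
})

test_that("realized kinship matches pedigree expectation per class", {
  classes <- c(unrelated = 0, second_cousin = 1 / 64, first_cousin = 1 / 16,
               half_sib = 1 / 8, full_sib = 1 / 4)
  counts <- c(unrelated = 40L, second_cousin = 40L, first_cousin = 40L,
              half_sib = 40L, full_sib = 40L)
  # truth kinship comes from ancestry segments, so a sparse map suffices
  cfg <- sim_config(n_snps = 100, seed = 909, error_rate = 0,
                    missing_rate = 0)
  d <- build_design(cfg, design_families(counts, offspring_per_family = 1))
  for (cl in names(classes)) {
    th <- d$truth$theta$theta_true[d$truth$theta$class == cl]
    if (classes[[cl]] == 0) {
      expect_true(all(th == 0))
    } else {
      se <- stats::sd(th) / sqrt(length(th))
      expect_lt(abs(mean(th) - classes[[cl]]), 3 * se)
    }
  }
})

test_that("offspring autozygosity truth is exact segment bookkeeping", {
  cfg <- sim_config(n_snps = 300, seed = 404, error_rate = 0,
                    missing_rate = 0)
  d <- build_design(cfg, design_families(c(full_sib = 3, unrelated = 2),
                                         offspring_per_family = 4))
  seg <- d$truth$segments
  tot <- tapply(seg$end - seg$start, seg$individual, sum)
  for (id in names(d$truth$f_true)) {
    s <- if (id %in% names(tot)) tot[[id]] else 0
    expect_equal(d$truth$f_true[[id]],
                 s / d$genome$total_length, tolerance = 1e-12)
  }
  # unrelated parents: exactly zero autozygosity (disjoint founder labels)
  un <- grep("^F0[45]_O", names(d$truth$f_true), value = TRUE)
  expect_true(all(d$truth$f_true[un] == 0))
  # full-sib matings average about a quarter of the genome autozygous
  fs <- grep("^F0[123]_O", names(d$truth$f_true), value = TRUE)
  expect_lt(abs(mean(d$truth$f_true[fs]) - 0.25), 0.1)
})

test_that("with no noise, genotypes equal the sum of founder haplotypes", {
  cfg <- sim_config(n_snps = 400, seed = 21, error_rate = 0,
                    missing_rate = 0, maf = maf_beta(0.8, 0.8))
  d <- build_design(cfg, design_broodstock(6))
  expect_false(anyNA(d$gm))
  expect_true(all(d$gm %in% 0:2))
  # and noise rates shift genotypes at about the configured frequency
  cfg2 <- sim_config(n_snps = 400, seed = 21, error_rate = 0,
                     missing_rate = 0.2, maf = maf_beta(0.8, 0.8))
  d2 <- build_design(cfg2, design_broodstock(6))
  expect_lt(abs(mean(is.na(d2$gm)) - 0.2), 0.05)
  expect_equal(d2$gm[!is.na(d2$gm)], d$gm[!is.na(d2$gm)])
})

test_that("inject_region sweeps and balancing regions behave at the limits", {
  g <- ra_genome(c(C1 = 10e6))
  cfg <- sim_config(genome = g, n_snps = 200, seed = 8,
                    maf = maf_fixed(0.4), error_rate = 0, missing_rate = 0)
  f <- simulate_founders(cfg, 20)
  sw1 <- sweep_spec("C1", 1, 10e6, kind = "low", intensity = 1)
  out <- inject_region(f$haplotypes, f$map, sw1)
  expect_true(all(apply(out, 2, function(col) length(unique(col)) == 1L)))
  sw0 <- sweep_spec("C1", 1, 10e6, kind = "low", intensity = 0)
  expect_identical(inject_region(f$haplotypes, f$map, sw0), f$haplotypes)
  # an interval covering too few markers for the scan is rejected
  narrow <- sweep_spec("C1", 1, 1e5, kind = "low", intensity = 1)
  expect_error(inject_region(f$haplotypes, f$map, narrow), "37")
  hi <- sweep_spec("C1", 1, 10e6, kind = "high", intensity = 1)
  out2 <- inject_region(f$haplotypes, f$map, hi)
  expect_lt(abs(mean(out2) - 0.5), 0.05)
})

test_that("write_design emits re-readable files with the seed recorded", {
  cfg <- sim_config(n_snps = 300, seed = 55)
  d <- build_design(cfg, design_families(c(full_sib = 1), 3))
  dir <- withr::local_tempdir()
  write_design(d, dir)
  expect_true(any(grepl("rohatlas_seed=55",
                        readLines(file.path(dir, "genotypes.vcf"), n = 5))))
  back <- read_genotypes(file.path(dir, "genotypes.vcf"), "vcf")
  expect_equal(unclass(back$gm), unclass(d$gm))
  ped <- read.table(file.path(dir, "pedigree.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(ped), nrow(d$pedigree))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yml"))
  expect_equal(cfg_back$seed, 55)
})
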