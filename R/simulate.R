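#' Simulation configuration
#'
#' Describes the synthetic study system: a multi-chromosome genome, a SNP
#' panel of a given size, a uniform genetic map fixed by its Mb-per-cM
#' ratio, a founder allele-frequency spectrum, per-genotype error and
#' missingness, and optional injected low/high-diversity regions. Defaults
#' emulate a reduced-representation panel on a 22-chromosome, 567-Mb
#' genome with a 0.6 Mb/cM map.
#'
#' @param genome an [ra_genome()]; defaults to [turbot_genome()].
#' @param n_snps panel size (markers placed uniformly per chromosome,
#'   proportionally to chromosome length).
#' @param mb_per_cm physical-to-genetic map ratio (Mb per centimorgan);
#'   `Inf` suppresses recombination.
#' @param maf founder allele-frequency spectrum ([maf_beta()],
#'   [maf_fixed()], [maf_empirical()]); `NULL` lets [build_design()] pick a
#'   population-appropriate default.
#' @param error_rate per-genotype mis-call probability; a mis-called
#'   genotype is replaced by one of the other two codes with equal
#'   probability.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed; the same seed reproduces identical output.
#' @param sweeps list of [sweep_spec()] regions injected into the founder
#'   haplotypes.
#' @return list of class `ra_sim_config`.
#' @export
sim_config <- function(genome = turbot_genome(), n_snps = 21615,
                       mb_per_cm = 0.6, maf = NULL, error_rate = 0.005,
                       missing_rate = 0.03, seed = 1L, sweeps = list()) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            mb_per_cm > 0, n_snps >= 1)
  for (sw in sweeps) {
    stopifnot(inherits(sw, "ra_sweep_spec"))
    if (!sw$chrom %in% genome$chrom_ids)
      stop("sweep on unknown chromosome ", sw$chrom)
    if (sw$start < 1 || sw$end > genome$chrom_lengths[sw$chrom])
      stop("sweep interval outside chromosome bounds")
  }
  structure(list(genome = genome, n_snps = as.integer(n_snps),
                 mb_per_cm = mb_per_cm, maf = maf,
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed), sweeps = sweeps),
            class = "ra_sim_config")
}

#' Founder allele-frequency spectra
#'
#' `maf_beta()` draws alternate-allele frequencies from a Beta
#' distribution: shapes (0.3, 1.2) give a rare-allele-enriched (wild-like)
#' spectrum, (0.8, 0.8) a rare-allele-depleted (broodstock-like) one.
#' `maf_fixed()` uses one constant frequency; `maf_empirical()` resamples a
#' supplied list.
#'
#' @param shape1,shape2 Beta shapes.
#' @param p constant frequency.
#' @param values frequencies resampled with replacement.
#' @return spectrum descriptor for [sim_config()].
#' @export
maf_beta <- function(shape1, shape2)
  structure(list(dist = "beta", shape1 = shape1, shape2 = shape2),
            class = "ra_maf")

#' @rdname maf_beta
#' @export
maf_fixed <- function(p) structure(list(dist = "fixed", p = p),
                                   class = "ra_maf")

#' @rdname maf_beta
#' @export
maf_empirical <- function(values)
  structure(list(dist = "empirical", values = values), class = "ra_maf")

.draw_freqs <- function(maf, m) {
  switch(maf$dist,
         beta = stats::rbeta(m, maf$shape1, maf$shape2),
         fixed = rep(maf$p, m),
         empirical = sample(maf$values, m, replace = TRUE),
         stop("unknown maf spectrum"))
}

#' Injected extreme-diversity region
#'
#' @param chrom chromosome id.
#' @param start,end interval (bp, 1-based inclusive).
#' @param kind `"low"` (sweep-like: frequencies pushed toward fixation) or
#'   `"high"` (balancing-like: frequencies pushed toward 0.5).
#' @param intensity in `[0, 1]`; 0 leaves haplotypes unchanged, 1 makes a
#'   `"low"` region fully monomorphic.
#' @return list of class `ra_sweep_spec`.
#' @export
sweep_spec <- function(chrom, start, end, kind = c("low", "high"),
                       intensity = 1) {
  kind <- match.arg(kind)
  stopifnot(end > start, intensity >= 0, intensity <= 1)
  structure(list(chrom = chrom, start = start, end = end, kind = kind,
                 intensity = intensity), class = "ra_sweep_spec")
}

# uniform marker placement, proportional allocation by chromosome length
.sim_map <- function(cfg) {
  g <- cfg$genome
  n_chrom <- length(g$chrom_ids)
  if (cfg$n_snps < n_chrom)
    stop("n_snps must be at least the number of chromosomes")
  share <- cfg$n_snps * g$chrom_lengths / g$total_length
  n_c <- pmax(1L, floor(share))
  rem <- cfg$n_snps - sum(n_c)
  if (rem > 0) {
    extra <- order(share - floor(share), decreasing = TRUE)
    n_c[extra[seq_len(rem)]] <- n_c[extra[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    cut <- order(n_c, decreasing = TRUE)
    n_c[cut[seq_len(-rem)]] <- n_c[cut[seq_len(-rem)]] - 1L
  }
  chrom <- rep(g$chrom_ids, n_c)
  pos <- unlist(lapply(seq_along(g$chrom_ids), function(i) {
    sort(sample.int(g$chrom_lengths[i], n_c[i]))
  }), use.names = FALSE)
  marker_map(chrom, pos, sprintf("sim%06d", seq_along(chrom)),
             ref = "A", alt = "B", genome = g)
}

#' Simulate a panel of unrelated founders
#'
#' Marker positions are uniform per chromosome; founder haplotype alleles
#' are drawn site-wise independently at the configured allele frequencies.
#' Each haplotype carries a unique founder-genome label for exact IBD
#' tracking through later meioses.
#'
#' @param cfg an [sim_config()]; `cfg$maf` must be set (see [build_design()]
#'   for population defaults).
#' @param n number of founder individuals (>= 2).
#' @return list of class `ra_founders` with `map`, `haplotypes` (2n x m 0/1
#'   allele matrix), `labels` (founder-genome id per haplotype), `freqs`
#'   (founder alternate-allele frequency per marker) and `cfg`.
#' @export
simulate_founders <- function(cfg, n) {
  stopifnot(inherits(cfg, "ra_sim_config"), n >= 2)
  if (is.null(cfg$maf)) stop("cfg$maf must be set")
  set.seed(cfg$seed)
  map <- .sim_map(cfg)
  m <- nrow(map)
  freqs <- .draw_freqs(cfg$maf, m)
  hap <- matrix(stats::rbinom(2L * n * m, 1L, rep(freqs, each = 2L * n)),
                nrow = 2L * n)
  for (sw in cfg$sweeps) hap <- inject_region(hap, map, sw)
  structure(list(map = map, haplotypes = hap, labels = seq_len(2L * n),
                 freqs = freqs, cfg = cfg),
            class = "ra_founders")
}

#' Push allele frequencies in an interval toward fixation or balance
#'
#' `kind = "low"` copies one template haplotype over the interval into each
#' other haplotype with probability `intensity` (a hard sweep at intensity
#' 1 leaves the interval monomorphic); `kind = "high"` redraws selected
#' haplotypes' interval alleles at frequency 0.5. Haplotypes outside the
#' interval are untouched. Intervals covering fewer than `min_markers`
#' markers are rejected as undetectable by a `min_markers`-SNP window scan.
#'
#' @param haplotypes 0/1 allele matrix (haplotypes x markers).
#' @param map matching marker map.
#' @param spec a [sweep_spec()].
#' @param min_markers minimum markers the interval must cover.
#' @return the modified haplotype matrix.
#' @export
inject_region <- function(haplotypes, map, spec, min_markers = 37L) {
  stopifnot(inherits(spec, "ra_sweep_spec"))
  j <- which(map$chrom == spec$chrom & map$pos >= spec$start &
               map$pos <= spec$end)
  if (length(j) < min_markers)
    stop("interval covers ", length(j), " markers; at least ", min_markers,
         " required")
  nh <- nrow(haplotypes)
  if (spec$kind == "low") {
    hit <- which(stats::runif(nh) < spec$intensity)
    hit <- setdiff(hit, 1L)
    if (length(hit))
      haplotypes[hit, j] <- rep(haplotypes[1L, j], each = length(hit))
  } else {
    hit <- which(stats::runif(nh) < spec$intensity)
    if (length(hit))
      haplotypes[hit, j] <- stats::rbinom(length(hit) * length(j), 1L, 0.5)
  }
  haplotypes
}

# ---- haplotype objects with ancestry segments --------------------------

# a haplotype is a list(alleles = 0/1 vector over markers,
#                       segs = data.frame(chrom, start, end, label))
# segs partition each chromosome in half-open [start, end) bp coordinates.

#' Extract one founder haplotype as a segment-tracked haplotype object
#'
#' @param founders an `ra_founders`.
#' @param h haplotype row index (1 .. 2n).
#' @return haplotype object usable with [meiose()].
#' @export
founder_haplotype <- function(founders, h) {
  g <- founders$cfg$genome
  list(alleles = founders$haplotypes[h, ],
       segs = data.frame(chrom = g$chrom_ids, start = 0,
                         end = unname(g$chrom_lengths),
                         label = founders$labels[h],
                         stringsAsFactors = FALSE))
}

.clip_segs <- function(segs, lo, hi) {
  keep <- segs$end > lo & segs$start < hi
  s <- segs[keep, , drop = FALSE]
  s$start <- pmax(s$start, lo)
  s$end <- pmin(s$end, hi)
  s
}

# merge adjacent same-label segments (within chromosome) to keep lists short
.compact_segs <- function(segs) {
  n <- nrow(segs)
  if (n <= 1L) return(segs)
  new_run <- c(TRUE, segs$chrom[-1] != segs$chrom[-n] |
                 segs$label[-1] != segs$label[-n])
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  data.frame(chrom = segs$chrom[starts], start = segs$start[starts],
             end = segs$end[ends], label = segs$label[starts],
             stringsAsFactors = FALSE)
}

#' One meiosis: recombine a pair of parental haplotypes into a gamete
#'
#' Crossover counts per chromosome are Poisson with mean
#' `length_bp / (mb_per_cm * 1e6) / 100` (Haldane: no interference);
#' crossover positions are uniform. The gamete carries its ancestors'
#' founder-genome labels as exact bp segments.
#'
#' @param pair list of the parent's two haplotype objects (see
#'   [founder_haplotype()]).
#' @param map marker map (positions within chromosome lengths).
#' @param cfg an [sim_config()] (supplies genome and `mb_per_cm`).
#' @return a gamete haplotype object.
#' @export
meiose <- function(pair, map, cfg) {
  g <- cfg$genome
  idx <- .chrom_index(map)
  alleles <- integer(nrow(map))
  seg_parts <- vector("list", length(g$chrom_ids))
  for (ci in seq_along(g$chrom_ids)) {
    cc <- g$chrom_ids[ci]
    len <- g$chrom_lengths[ci]
    lambda <- len / (cfg$mb_per_cm * 1e6) / 100
    n_xo <- stats::rpois(1L, lambda)
    xo <- sort(stats::runif(n_xo, 0, len))
    start <- sample.int(2L, 1L)
    ii <- idx[[cc]]
    if (!is.null(ii) && length(ii)) {
      src <- (start - 1L + findInterval(map$pos[ii], xo)) %% 2L + 1L
      alleles[ii] <- ifelse(src == 1L, pair[[1]]$alleles[ii],
                            pair[[2]]$alleles[ii])
    }
    b <- c(0, xo, len)
    parts <- vector("list", n_xo + 1L)
    for (k in seq_len(n_xo + 1L)) {
      s <- (start - 1L + k - 1L) %% 2L + 1L
      ps <- pair[[s]]$segs
      parts[[k]] <- .clip_segs(ps[ps$chrom == cc, , drop = FALSE],
                               b[k], b[k + 1L])
    }
    seg_parts[[ci]] <- do.call(rbind, parts)
  }
  segs <- do.call(rbind, seg_parts)
  rownames(segs) <- NULL
  list(alleles = alleles, segs = .compact_segs(segs))
}

# total bp over which two haplotypes carry the same founder label
.ibd_segments <- function(sa, sb) {
  out <- vector("list", 0L)
  for (cc in unique(sa$chrom)) {
    a <- sa[sa$chrom == cc, , drop = FALSE]
    b <- sb[sb$chrom == cc, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    i <- 1L; j <- 1L
    while (i <= nrow(a) && j <= nrow(b)) {
      lo <- max(a$start[i], b$start[j])
      hi <- min(a$end[i], b$end[j])
      if (hi > lo && a$label[i] == b$label[j])
        out[[length(out) + 1L]] <- data.frame(chrom = cc, start = lo,
                                              end = hi,
                                              stringsAsFactors = FALSE)
      if (a$end[i] <= b$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.ibd_share <- function(sa, sb, total_length) {
  seg <- .ibd_segments(sa, sb)
  sum(seg$end - seg$start) / total_length
}

# realized kinship between two individuals from their 4 haplotypes
.theta_true <- function(ind1, ind2, total_length) {
  0.25 * (.ibd_share(ind1$h1$segs, ind2$h1$segs, total_length) +
            .ibd_share(ind1$h1$segs, ind2$h2$segs, total_length) +
            .ibd_share(ind1$h2$segs, ind2$h1$segs, total_length) +
            .ibd_share(ind1$h2$segs, ind2$h2$segs, total_length))
}

.mate <- function(p1, p2, map, cfg)
  list(h1 = meiose(list(p1$h1, p1$h2), map, cfg),
       h2 = meiose(list(p2$h1, p2$h2), map, cfg))

# founder individual from two rows of a raw haplotype matrix
.raw_ind <- function(hap, labels, r1, r2, genome) {
  mk <- function(r) list(
    alleles = hap[r, ],
    segs = data.frame(chrom = genome$chrom_ids, start = 0,
                      end = unname(genome$chrom_lengths), label = labels[r],
                      stringsAsFactors = FALSE))
  list(h1 = mk(r1), h2 = mk(r2))
}

# parents of each kinship class from a small founder pedigree:
# expected theta 0, 1/64, 1/16, 1/8, 1/4
.founders_per_class <- c(unrelated = 2L, second_cousin = 6L,
                         first_cousin = 4L, half_sib = 3L, full_sib = 2L)

.make_parent_pair <- function(class, fnd, map, cfg) {
  g <- cfg$genome
  f <- function(k) .raw_ind(fnd$hap, fnd$labels, 2L * k - 1L, 2L * k, g)
  switch(class,
    unrelated = list(f(1L), f(2L)),
    full_sib = {
      a <- f(1L); b <- f(2L)
      list(.mate(a, b, map, cfg), .mate(a, b, map, cfg))
    },
    half_sib = {
      a <- f(1L); b <- f(2L); c3 <- f(3L)
      list(.mate(a, b, map, cfg), .mate(a, c3, map, cfg))
    },
    first_cousin = {
      a <- f(1L); b <- f(2L)
      s1 <- .mate(a, b, map, cfg); s2 <- .mate(a, b, map, cfg)
      list(.mate(s1, f(3L), map, cfg), .mate(s2, f(4L), map, cfg))
    },
    second_cousin = {
      a <- f(1L); b <- f(2L)
      g1 <- .mate(a, b, map, cfg); g2 <- .mate(a, b, map, cfg)
      h1 <- .mate(g1, f(3L), map, cfg); h2 <- .mate(g2, f(4L), map, cfg)
      list(.mate(h1, f(5L), map, cfg), .mate(h2, f(6L), map, cfg))
    },
    stop("unknown kinship class: ", class))
}

#' Study designs for [build_design()]
#'
#' `design_wild()` / `design_broodstock()` sample `n` unrelated founders
#' with a rare-allele-enriched / rare-allele-depleted spectrum;
#' `design_families()` founds families whose parent pairs realize the five
#' kinship classes (expected kinship 0, 1/64, 1/16, 1/8, 1/4) and mates
#' each pair to produce offspring.
#'
#' @param n number of individuals.
#' @param class_counts named counts over
#'   `c("unrelated", "second_cousin", "first_cousin", "half_sib",
#'   "full_sib")`; the default mix spreads 26 families across all five
#'   classes.
#' @param offspring_per_family offspring produced per family.
#' @return design descriptor.
#' @export
design_wild <- function(n = 36) list(type = "wild", n = n)

#' @rdname design_wild
#' @export
design_broodstock <- function(n = 46) list(type = "broodstock", n = n)

#' @rdname design_wild
#' @export
design_families <- function(class_counts = c(unrelated = 6L,
                                             second_cousin = 5L,
                                             first_cousin = 5L,
                                             half_sib = 5L,
                                             full_sib = 5L),
                            offspring_per_family = 40L) {
  bad <- setdiff(names(class_counts), names(.founders_per_class))
  if (length(bad)) stop("unknown kinship class: ", paste(bad, collapse = ", "))
  list(type = "families", class_counts = class_counts,
       offspring_per_family = as.integer(offspring_per_family))
}

.apply_noise <- function(gm, cfg) {
  if (cfg$error_rate > 0) {
    err <- which(!is.na(gm) & stats::runif(length(gm)) < cfg$error_rate)
    if (length(err)) {
      shift <- sample.int(2L, length(err), replace = TRUE)
      gm[err] <- (gm[err] + shift) %% 3L
    }
  }
  if (cfg$missing_rate > 0)
    gm[stats::runif(length(gm)) < cfg$missing_rate] <- NA_integer_
  gm
}

#' Simulate a full study design with ground truth
#'
#' Generates a marker map, founder haplotypes and, for family designs, a
#' gamete-dropped pedigree realizing the requested kinship classes.
#' Genotyping error and missingness are applied after truth capture, so the
#' returned truth records realized (not expected) identity by descent.
#'
#' @param cfg an [sim_config()]; when `cfg$maf` is `NULL`, wild designs use
#'   `maf_beta(0.3, 1.2)` and broodstock/family designs
#'   `maf_beta(0.8, 0.8)`.
#' @param design a [design_wild()], [design_broodstock()] or
#'   [design_families()].
#' @return list of class `ra_design` with `gm`, `map`, `genome`, `pedigree`
#'   (id, sire, dam, family, generation) and `truth`: `f_true` (realized
#'   autozygous genome fraction per individual), `segments` (true
#'   autozygous segments), `theta` (per family: realized parental kinship
#'   and design class) and `freqs`.
#' @export
build_design <- function(cfg, design) {
  stopifnot(inherits(cfg, "ra_sim_config"))
  if (is.null(cfg$maf)) {
    cfg$maf <- if (identical(design$type, "wild")) maf_beta(0.3, 1.2)
               else maf_beta(0.8, 0.8)
  }
  set.seed(cfg$seed)
  map <- .sim_map(cfg)
  m <- nrow(map)
  g <- cfg$genome
  freqs <- .draw_freqs(cfg$maf, m)

  if (design$type %in% c("wild", "broodstock")) {
    n <- design$n
    hap <- matrix(stats::rbinom(2L * n * m, 1L, rep(freqs, each = 2L * n)),
                  nrow = 2L * n)
    for (sw in cfg$sweeps) hap <- inject_region(hap, map, sw)
    gm0 <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    ids <- sprintf("%s%03d", if (design$type == "wild") "W" else "B",
                   seq_len(n))
    rownames(gm0) <- ids
    gm <- genotype_matrix(.apply_noise(gm0, cfg), map, ids = ids)
    ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                      family = NA_character_, generation = 0L,
                      stringsAsFactors = FALSE)
    truth <- list(f_true = stats::setNames(rep(0, n), ids),
                  segments = data.frame(individual = character(),
                                        chrom = character(),
                                        start = numeric(), end = numeric()),
                  theta = NULL, freqs = freqs)
    return(structure(list(gm = gm, map = map, genome = g, pedigree = ped,
                          truth = truth, cfg = cfg), class = "ra_design"))
  }

  stopifnot(design$type == "families")
  classes <- rep(names(design$class_counts), design$class_counts)
  n_fam <- length(classes)
  k <- design$offspring_per_family
  n_ind <- n_fam * (2L + k)
  gm0 <- matrix(0L, nrow = n_ind, ncol = m)
  ids <- character(n_ind)
  ped <- vector("list", n_fam)
  theta <- data.frame(family = character(n_fam), class = classes,
                      sire = character(n_fam), dam = character(n_fam),
                      theta_true = numeric(n_fam), stringsAsFactors = FALSE)
  f_true <- numeric(n_fam * k)
  f_ids <- character(n_fam * k)
  seg_list <- vector("list", n_fam * k)
  row <- 0L; orow <- 0L; next_label <- 0L
  for (fi in seq_len(n_fam)) {
    cl <- classes[fi]
    fam <- sprintf("F%02d", fi)
    nf <- .founders_per_class[[cl]]
    fhap <- matrix(stats::rbinom(2L * nf * m, 1L,
                                 rep(freqs, each = 2L * nf)),
                   nrow = 2L * nf)
    for (sw in cfg$sweeps) fhap <- inject_region(fhap, map, sw)
    fnd <- list(hap = fhap, labels = next_label + seq_len(2L * nf))
    next_label <- next_label + 2L * nf
    pp <- .make_parent_pair(cl, fnd, map, cfg)
    sire_id <- paste0(fam, "_S"); dam_id <- paste0(fam, "_D")
    theta$family[fi] <- fam
    theta$sire[fi] <- sire_id; theta$dam[fi] <- dam_id
    theta$theta_true[fi] <- .theta_true(pp[[1]], pp[[2]], g$total_length)
    for (pi in 1:2) {
      row <- row + 1L
      ids[row] <- if (pi == 1L) sire_id else dam_id
      gm0[row, ] <- pp[[pi]]$h1$alleles + pp[[pi]]$h2$alleles
    }
    off_ids <- sprintf("%s_O%02d", fam, seq_len(k))
    for (oi in seq_len(k)) {
      off <- .mate(pp[[1]], pp[[2]], map, cfg)
      row <- row + 1L; orow <- orow + 1L
      ids[row] <- off_ids[oi]
      gm0[row, ] <- off$h1$alleles + off$h2$alleles
      aut <- .ibd_segments(off$h1$segs, off$h2$segs)
      f_ids[orow] <- off_ids[oi]
      f_true[orow] <- sum(aut$end - aut$start) / g$total_length
      if (nrow(aut))
        seg_list[[orow]] <- cbind(individual = off_ids[oi], aut)
    }
    ped[[fi]] <- data.frame(
      id = c(sire_id, dam_id, off_ids),
      sire = c(NA_character_, NA_character_, rep(sire_id, k)),
      dam = c(NA_character_, NA_character_, rep(dam_id, k)),
      family = fam, generation = c(0L, 0L, rep(1L, k)),
      stringsAsFactors = FALSE)
  }
  rownames(gm0) <- ids
  gm <- genotype_matrix(.apply_noise(gm0, cfg), map, ids = ids)
  segments <- if (length(Filter(Negate(is.null), seg_list)))
    do.call(rbind, Filter(Negate(is.null), seg_list))
  else data.frame(individual = character(), chrom = character(),
                  start = numeric(), end = numeric())
  rownames(segments) <- NULL
  structure(list(gm = gm, map = map, genome = g,
                 pedigree = do.call(rbind, ped),
                 truth = list(f_true = stats::setNames(f_true, f_ids),
                              segments = segments, theta = theta,
                              freqs = freqs),
                 cfg = cfg),
            class = "ra_design")
}

#' Write a simulated design to disk
#'
#' Emits a VCF of the genotypes (seed recorded in the header), a pedigree
#' TSV, a truth TSV of autozygous segments (`individual`, `chrom`, `start`,
#' `end`) plus per-individual `f_true`, a per-family kinship TSV where
#' available, and the configuration as a YAML key-value file.
#'
#' @param design an `ra_design` from [build_design()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(design$gm, design$map, file.path(dir, "genotypes.vcf"),
                  format = "vcf",
                  header_lines = sprintf("##rohatlas_seed=%d",
                                         design$cfg$seed))
  utils::write.table(design$pedigree, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seg <- design$truth$segments
  seg$start <- floor(seg$start) + 1
  seg$end <- ceiling(seg$end)
  utils::write.table(seg, file.path(dir, "truth_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(individual = names(design$truth$f_true),
               f_true = unname(design$truth$f_true)),
    file.path(dir, "truth_f.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(design$truth$theta))
    utils::write.table(design$truth$theta, file.path(dir, "truth_theta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- design$cfg
  yaml::write_yaml(list(
    n_snps = cfg$n_snps, mb_per_cm = cfg$mb_per_cm,
    error_rate = cfg$error_rate, missing_rate = cfg$missing_rate,
    seed = cfg$seed,
    chrom_lengths = as.list(cfg$genome$chrom_lengths)),
    file.path(dir, "config.yml"))
  invisible(dir)
}
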