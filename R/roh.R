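#' ROH calling parameters
#'
#' Parameter set for the observational sliding-window ROH caller, mirroring
#' PLINK 1.9's homozygosity options: a scanning window of `window_snp`
#' consecutive SNPs slid one SNP at a time, a per-window allowance of
#' heterozygous (`window_het`, 0 or 1) and missing (`window_missing`)
#' calls, a per-SNP homozygous-window hit threshold, and final segment
#' filters on SNP count, length and SNP density.
#'
#' @param window_snp SNPs per scanning window (the calibration grid spans
#'   24-40).
#' @param window_het heterozygous calls allowed per window (0 or 1).
#' @param window_missing missing calls allowed per window.
#' @param hit_threshold minimum fraction of homozygous windows among those
#'   containing a SNP for the SNP to be ROH-eligible.
#' @param min_snp minimum SNPs per final segment (set equal to
#'   `window_snp` across the calibration grid).
#' @param min_kb minimum segment length in kb.
#' @param max_gap_kb split a candidate run where adjacent SNPs are further
#'   apart than this.
#' @param density_kb maximum mean kb per SNP within a segment.
#' @return list of class `ra_roh_params`.
#' @export
roh_params <- function(window_snp = 37L, window_het = 1L,
                       window_missing = 5L, hit_threshold = 0.05,
                       min_snp = window_snp, min_kb = 200,
                       max_gap_kb = 1000, density_kb = 50) {
  stopifnot(window_snp >= 1, window_het %in% c(0L, 1L),
            window_missing >= 0, hit_threshold > 0, hit_threshold <= 1,
            min_snp >= 1, min_kb > 0, max_gap_kb > 0, density_kb > 0)
  structure(list(window_snp = as.integer(window_snp),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 hit_threshold = hit_threshold,
                 min_snp = as.integer(min_snp), min_kb = min_kb,
                 max_gap_kb = max_gap_kb, density_kb = density_kb),
            class = "ra_roh_params")
}

# ROH segments for one genotype vector on one chromosome
.call_roh_chrom <- function(geno, pos, params) {
  m <- length(geno)
  w <- params$window_snp
  if (m < w) return(NULL)
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  nwin <- m - w + 1L
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  k <- seq_len(nwin)
  hom_win <- (cs_het[k + w] - cs_het[k]) <= params$window_het &
    (cs_mis[k + w] - cs_mis[k]) <= params$window_missing
  cs_hom <- c(0L, cumsum(hom_win))
  i <- seq_len(m)
  first_win <- pmax(1L, i - w + 1L)
  last_win <- pmin(i, nwin)
  n_win <- last_win - first_win + 1L
  hits <- cs_hom[last_win + 1L] - cs_hom[first_win]
  eligible <- hits / n_win >= params$hit_threshold
  if (!any(eligible)) return(NULL)
  # maximal runs of eligible SNPs, split at large gaps
  gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
  run_id <- cumsum(!eligible | gap_break)
  runs <- split(which(eligible), run_id[eligible])
  hom <- !het & !mis
  out <- lapply(runs, function(r) {
    hr <- r[hom[r]]
    if (!length(hr)) return(NULL)
    a <- hr[1L]; b <- hr[length(hr)]
    n_snps <- b - a + 1L
    len_kb <- (pos[b] - pos[a] + 1) / 1000
    if (n_snps < params$min_snp || len_kb < params$min_kb ||
        len_kb / n_snps > params$density_kb) return(NULL)
    c(a, b, n_snps, len_kb)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Call runs of homozygosity
#'
#' Observational sliding-window ROH detection with PLINK 1.9 semantics:
#' (1) slide a window of `window_snp` consecutive SNPs one SNP at a time
#' within each chromosome; a window is homozygous when it contains at most
#' `window_het` heterozygous and `window_missing` missing calls; (2) a
#' SNP's hit fraction is the proportion of homozygous windows among the
#' windows containing it (windows fully inside the chromosome); the SNP is
#' ROH-eligible when the fraction reaches `hit_threshold`; (3) maximal
#' runs of consecutive eligible SNPs form candidate segments, split where
#' adjacent SNPs lie more than `max_gap_kb` apart; (4) segment ends are
#' trimmed to the outermost homozygous (non-het, non-missing) call;
#' (5) segments are kept when they reach `min_snp` SNPs, `min_kb` kb and a
#' mean kb-per-SNP of at most `density_kb`.
#'
#' @param gm genotype matrix.
#' @param map matching marker map.
#' @param params an [roh_params()].
#' @param individuals ids or row indices; default all.
#' @return data.frame of segments with columns `individual`, `chrom`,
#'   `start`, `end` (bp, 1-based inclusive at the outermost member SNPs),
#'   `n_snps`, `length_kb`.
#' @export
call_roh <- function(gm, map, params = roh_params(), individuals = NULL) {
  stopifnot(inherits(params, "ra_roh_params"))
  if (is.null(individuals)) individuals <- seq_len(nrow(gm))
  if (is.character(individuals)) {
    ix <- match(individuals, rownames(gm))
    if (any(is.na(ix))) stop("individual index out of range")
    individuals <- ix
  }
  if (any(individuals < 1L) || any(individuals > nrow(gm)))
    stop("individual index out of range")
  idx <- .chrom_index(map)
  res <- vector("list", 0L)
  for (ii in individuals) {
    g <- gm[ii, ]
    for (cc in names(idx)) {
      jj <- idx[[cc]]
      seg <- .call_roh_chrom(g[jj], map$pos[jj], params)
      if (!is.null(seg))
        res[[length(res) + 1L]] <- data.frame(
          individual = rownames(gm)[ii], chrom = cc,
          start = map$pos[jj][seg[, 1L]], end = map$pos[jj][seg[, 2L]],
          n_snps = as.integer(seg[, 3L]), length_kb = seg[, 4L],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' Total length of ROH segments strictly longer than `cutoff_mb`, divided
#' by the total genome length.
#'
#' @param segments data.frame from [call_roh()] (one individual's
#'   segments).
#' @param genome an [ra_genome()].
#' @param cutoff_mb length cut-off in Mb (the calibration explores 1, 2,
#'   4, 8 and 10).
#' @return F_ROH in `[0, 1]`.
#' @examples
#' seg <- data.frame(length_kb = c(2000, 3670))
#' f_roh(seg, ra_genome(c(C01 = 567e6)), cutoff_mb = 1)  # 0.01
#' @export
f_roh <- function(segments, genome, cutoff_mb = 1) {
  stopifnot(cutoff_mb > 0)
  if (!nrow(segments)) return(0)
  keep <- segments$length_kb > cutoff_mb * 1000
  sum(segments$length_kb[keep]) * 1000 / genome$total_length
}

#' F_ROH for every individual in a segment table
#'
#' @param segments data.frame from [call_roh()] over several individuals.
#' @param genome an [ra_genome()].
#' @param cutoff_mb length cut-off in Mb.
#' @param individuals ids to report (zero for individuals without
#'   segments); defaults to the ids present in `segments`.
#' @return named numeric vector of F_ROH values.
#' @export
f_roh_by_individual <- function(segments, genome, cutoff_mb = 1,
                                individuals = NULL) {
  if (is.null(individuals)) individuals <- unique(segments$individual)
  keep <- segments$length_kb > cutoff_mb * 1000
  tot <- tapply(segments$length_kb[keep], segments$individual[keep], sum)
  out <- stats::setNames(rep(0, length(individuals)), individuals)
  hit <- intersect(names(tot), individuals)
  out[hit] <- tot[hit] * 1000 / genome$total_length
  out
}

#' Summarize ROH segments into length classes
#'
#' Classes (Mb): <1, 1-2, 2-4, 4-8, 8-12, 12-16, 16-24, >24.
#'
#' @param segments data.frame from [call_roh()].
#' @return data.frame with `class`, `count` and `total_mb` per class.
#' @export
roh_size_classes <- function(segments) {
  breaks <- c(0, 1, 2, 4, 8, 12, 16, 24, Inf)
  labels <- c("<1", "1-2", "2-4", "4-8", "8-12", "12-16", "16-24", ">24")
  mb <- segments$length_kb / 1000
  cls <- cut(mb, breaks = breaks, labels = labels, right = FALSE)
  data.frame(class = labels,
             count = as.integer(table(cls)[labels]),
             total_mb = as.numeric(tapply(mb, factor(cls, levels = labels),
                                          sum, default = 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ROH islands: population-level enrichment of ROH in 50-kb windows
#'
#' Tiles the genome in non-overlapping `window_kb` windows, counts the
#' individuals with at least 1 bp of ROH overlap per window, and tests
#' each window's count against an upper-tail binomial null whose success
#' probability `p0` is the genome-wide mean per-individual ROH coverage
#' fraction. Significance is Bonferroni-corrected over the windows with a
#' nonzero count (override with `bonferroni_n`); adjacent significant
#' windows are merged into islands.
#'
#' The default `alpha` of 0.0128 reproduces a per-window threshold of
#' 2e-5 when about 640 windows carry ROH, which is the published
#' configuration of this test for turbot broodstock; with no ROH anywhere
#' the scan returns no islands at any level.
#'
#' @param segments data.frame from [call_roh()] over the population.
#' @param genome an [ra_genome()].
#' @param n_individuals individuals scanned (>= 2), including those
#'   without any ROH.
#' @param window_kb tile width in kb.
#' @param alpha family-wise significance level.
#' @param bonferroni_n optional fixed Bonferroni denominator.
#' @return list of class `ra_roh_islands` with `windows` (chrom, start,
#'   end, count, p_value, significant), `islands` (merged significant
#'   windows), `p0` and the correction denominator `m`.
#' @export
roh_islands <- function(segments, genome, n_individuals, window_kb = 50,
                        alpha = 0.0128, bonferroni_n = NULL) {
  stopifnot(n_individuals >= 2)
  wbp <- window_kb * 1000
  n_win_chrom <- ceiling(genome$chrom_lengths / wbp)
  offsets <- c(0, cumsum(n_win_chrom))[seq_along(n_win_chrom)]
  names(offsets) <- genome$chrom_ids
  total_windows <- sum(n_win_chrom)
  count <- integer(total_windows)
  if (nrow(segments)) {
    w1 <- floor((segments$start - 1) / wbp) + 1
    w2 <- pmin(floor((segments$end - 1) / wbp) + 1,
               n_win_chrom[segments$chrom])
    nrep <- as.integer(w2 - w1 + 1)
    win <- as.integer(offsets[segments$chrom] + w1)
    win <- unlist(lapply(seq_along(win), function(i)
      win[i] + 0:(nrep[i] - 1L)), use.names = FALSE)
    hits <- unique(data.frame(ind = rep(segments$individual, nrep),
                              win = win, stringsAsFactors = FALSE))
    tab <- table(hits$win)
    count[as.integer(names(tab))] <- as.integer(tab)
    cov <- tapply(segments$length_kb, segments$individual, sum) * 1000
    p0 <- sum(cov) / n_individuals / genome$total_length
  } else {
    p0 <- 0
  }
  p_value <- if (p0 > 0)
    stats::pbinom(count - 1L, n_individuals, p0, lower.tail = FALSE)
  else ifelse(count > 0, 0, 1)  # degenerate null; no ROH means count == 0
  m <- if (is.null(bonferroni_n)) sum(count > 0L) else bonferroni_n
  significant <- if (m > 0) p_value < alpha / m else rep(FALSE, total_windows)
  chrom <- rep(genome$chrom_ids, n_win_chrom)
  win_in_chrom <- unlist(lapply(n_win_chrom, seq_len), use.names = FALSE)
  windows <- data.frame(
    chrom = chrom,
    start = (win_in_chrom - 1) * wbp + 1,
    end = pmin(win_in_chrom * wbp, genome$chrom_lengths[chrom]),
    count = count, p_value = p_value, significant = significant,
    stringsAsFactors = FALSE)
  rownames(windows) <- NULL
  sig <- windows[windows$significant, , drop = FALSE]
  islands <- .merge_intervals(sig, gap = 1)
  structure(list(windows = windows, islands = islands, p0 = p0, m = m,
                 alpha = alpha),
            class = "ra_roh_islands")
}

#' @export
print.ra_roh_islands <- function(x, ...) {
  cat(sprintf(
    "<ra_roh_islands> %d/%d windows significant, %d island(s); p0 = %.4g\n",
    sum(x$windows$significant), nrow(x$windows), nrow(x$islands), x$p0))
  invisible(x)
}

# merge intervals (sorted by chrom tiling order) that overlap or lie
# within `gap` bp of each other
.merge_intervals <- function(x, gap = 1) {
  if (!nrow(x))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  new_blk <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$start[-1] > x$end[-nrow(x)] + gap)
  blk <- cumsum(new_blk)
  starts <- which(new_blk)
  ends_idx <- c(starts[-1] - 1L, nrow(x))
  data.frame(chrom = x$chrom[starts],
             start = x$start[starts],
             end = vapply(seq_along(starts), function(b)
               max(x$end[starts[b]:ends_idx[b]]), numeric(1)),
             n_windows = as.integer(ends_idx - starts + 1L),
             stringsAsFactors = FALSE)
}

#' Export ROH segments as a plink.hom-style TSV
#'
#' @param segments data.frame from [call_roh()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path) {
  out <- data.frame(IID = segments$individual, CHR = segments$chrom,
                    POS1 = segments$start, POS2 = segments$end,
                    KB = segments$length_kb, NSNP = segments$n_snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
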