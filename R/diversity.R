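#' Sliding-window pooled heterozygosity scan
#'
#' Slides a window of `window_snp` consecutive SNPs, one SNP at a time and
#' never across chromosome boundaries. For each SNP the major and minor
#' allele counts among non-missing calls are computed (major = the more
#' frequent allele in the sample at that SNP; an exact tie is broken toward
#' the alternate allele, which leaves Hp unchanged). Per window,
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2` where `S_maj`/`S_min` are
#' the window sums of the per-SNP major/minor counts, and
#' `ZHp = (Hp - mean(Hp)) / sd(Hp)` standardized over all windows
#' genome-wide (population denominator). Chromosomes with fewer than
#' `window_snp` markers are skipped with a warning; a chromosome with
#' `n_c >= window_snp` markers yields `n_c - window_snp + 1` windows.
#'
#' @param gm genotype matrix.
#' @param map matching marker map.
#' @param window_snp window width in SNPs.
#' @return data.frame of class `ra_scan` with columns `chrom`,
#'   `first_snp`, `last_snp` (marker indices into `map`), `start`, `end`
#'   (bp of the first and last member SNP), `sum_maj`, `sum_min`, `Hp`,
#'   `ZHp`.
#' @export
scan_windows <- function(gm, map, window_snp = 37L) {
  w <- as.integer(window_snp)
  nA <- colSums(gm == 0L, na.rm = TRUE) * 2L + colSums(gm == 1L, na.rm = TRUE)
  nB <- colSums(gm == 2L, na.rm = TRUE) * 2L + colSums(gm == 1L, na.rm = TRUE)
  n_maj <- ifelse(nA > nB, nA, nB)   # tie (nA == nB) goes to the alt allele
  n_min <- ifelse(nA > nB, nB, nA)
  idx <- .chrom_index(map)
  short <- names(idx)[vapply(idx, length, integer(1)) < w]
  if (length(short))
    warning("chromosome(s) with fewer than ", w, " markers skipped: ",
            paste(short, collapse = ", "))
  res <- vector("list", length(idx))
  for (ci in seq_along(idx)) {
    jj <- idx[[ci]]
    m <- length(jj)
    if (m < w) next
    nwin <- m - w + 1L
    cs_maj <- c(0, cumsum(n_maj[jj]))
    cs_min <- c(0, cumsum(n_min[jj]))
    k <- seq_len(nwin)
    s_maj <- cs_maj[k + w] - cs_maj[k]
    s_min <- cs_min[k + w] - cs_min[k]
    res[[ci]] <- data.frame(
      chrom = names(idx)[ci],
      first_snp = jj[k], last_snp = jj[k + w - 1L],
      start = map$pos[jj[k]], end = map$pos[jj[k + w - 1L]],
      sum_maj = s_maj, sum_min = s_min,
      Hp = ifelse(s_maj + s_min > 0,
                  2 * s_maj * s_min / (s_maj + s_min)^2, 0),
      stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("no chromosome has enough markers to scan")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  mu <- mean(out$Hp)
  sg <- sqrt(mean((out$Hp - mu)^2))
  if (sg == 0) stop("degenerate scan: all windows have identical Hp")
  out$ZHp <- (out$Hp - mu) / sg
  class(out) <- c("ra_scan", "data.frame")
  out
}

#' Tag windows by ZHp extremeness
#'
#' Windows with `ZHp <= -suggestive` / `>= suggestive` are suggestive low-
#' / high-diversity windows; those beyond `strict` are additionally
#' strict. The tag records the highest tier reached (a strict window is
#' also part of the suggestive tier).
#'
#' @param stats scan table from [scan_windows()].
#' @param suggestive,strict positive thresholds, `strict >= suggestive`.
#' @return `stats` with an added `tag` column in `{none, low-suggestive,
#'   low-strict, high-suggestive, high-strict}`.
#' @export
classify_windows <- function(stats, suggestive = 2.5, strict = 3.0) {
  stopifnot(suggestive > 0, strict >= suggestive)
  z <- stats$ZHp
  tag <- rep("none", length(z))
  tag[z <= -suggestive] <- "low-suggestive"
  tag[z <= -strict] <- "low-strict"
  tag[z >= suggestive] <- "high-suggestive"
  tag[z >= strict] <- "high-strict"
  stats$tag <- tag
  stats
}

#' Merge tagged windows into extreme-diversity regions
#'
#' For each class (low/high) and tier (suggestive includes strict
#' windows; strict only strict ones), overlapping or bookended windows are
#' merged; a region spans its member windows' SNP bounds.
#'
#' @param stats tagged scan table from [classify_windows()].
#' @return data.frame of regions: `chrom`, `start`, `end`, `class`,
#'   `tier`, `n_windows`, `peak_zhp` (most extreme member ZHp).
#' @export
merge_regions <- function(stats) {
  if (is.null(stats$tag)) stop("run classify_windows() first")
  pick <- list(
    c("low", "suggestive"), c("low", "strict"),
    c("high", "suggestive"), c("high", "strict"))
  out <- lapply(pick, function(p) {
    cls <- p[1L]; tier <- p[2L]
    sel <- if (tier == "suggestive")
      stats$tag %in% paste0(cls, c("-suggestive", "-strict"))
    else stats$tag == paste0(cls, "-strict")
    x <- stats[sel, , drop = FALSE]
    if (!nrow(x)) return(NULL)
    merged <- .merge_tagged(x)
    merged$class <- cls
    merged$tier <- tier
    merged
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      tier = character(), n_windows = integer(),
                      peak_zhp = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "class", "tier", "n_windows",
          "peak_zhp")]
}

.merge_tagged <- function(x) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  n <- nrow(x)
  new_blk <- c(TRUE, x$chrom[-1] != x$chrom[-n] |
                 x$start[-1] > x$end[-n] + 1)
  starts <- which(new_blk)
  ends_idx <- c(starts[-1] - 1L, n)
  data.frame(
    chrom = x$chrom[starts],
    start = x$start[starts],
    end = vapply(seq_along(starts), function(b)
      max(x$end[starts[b]:ends_idx[b]]), numeric(1)),
    n_windows = as.integer(ends_idx - starts + 1L),
    peak_zhp = vapply(seq_along(starts), function(b) {
      z <- x$ZHp[starts[b]:ends_idx[b]]
      z[which.max(abs(z))]
    }, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Match annotated markers to extreme-diversity regions
#'
#' A marker matches a region when its position lies inside the region's
#' interval (same chromosome, 1-based inclusive).
#'
#' @param regions data.frame from [merge_regions()].
#' @param ann annotation table (see [read_marker_annotation()]).
#' @return list with `regions` (a `markers` column added: comma-separated
#'   matched ids) and `markers` (one row per marker-region match with the
#'   region tier and class).
#' @export
intersect_markers <- function(regions, ann) {
  marker_rows <- vector("list", 0L)
  regions$markers <- ""
  if (nrow(regions)) for (i in seq_len(nrow(regions))) {
    hit <- ann$chrom == regions$chrom[i] & ann$pos >= regions$start[i] &
      ann$pos <= regions$end[i]
    if (any(hit)) {
      regions$markers[i] <- paste(ann$id[hit], collapse = ",")
      marker_rows[[length(marker_rows) + 1L]] <- data.frame(
        id = ann$id[hit], chrom = ann$chrom[hit], pos = ann$pos[hit],
        region_start = regions$start[i], region_end = regions$end[i],
        class = regions$class[i], tier = regions$tier[i],
        stringsAsFactors = FALSE)
    }
  }
  markers <- if (length(marker_rows)) do.call(rbind, marker_rows)
  else data.frame(id = character(), chrom = character(), pos = numeric(),
                  region_start = numeric(), region_end = numeric(),
                  class = character(), tier = character(),
                  stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  list(regions = regions, markers = markers)
}

#' Export a genome atlas of diversity regions, ROH islands and markers
#'
#' Writes one BED track per component (0-based half-open): extreme-
#' diversity regions (class/tier in the name field), ROH islands, and
#' annotated markers falling inside regions, plus the per-window scan as
#' TSV.
#'
#' @param dir output directory.
#' @param stats tagged scan table ([classify_windows()]).
#' @param regions regions table ([merge_regions()]), optionally after
#'   [intersect_markers()].
#' @param islands optional `ra_roh_islands` object.
#' @param ann optional marker annotation.
#' @param prefix file-name prefix (e.g. the population label).
#' @return `dir`, invisibly.
#' @export
export_atlas <- function(dir, stats, regions, islands = NULL, ann = NULL,
                         prefix = "atlas") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    stats[, c("chrom", "start", "end", "Hp", "ZHp",
              if ("tag" %in% names(stats)) "tag")],
    file.path(dir, paste0(prefix, "_windows.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(regions)) {
    regions$name <- paste(regions$class, regions$tier, sep = "-")
    export_bed(regions, file.path(dir, paste0(prefix, "_regions.bed")),
               name_col = "name")
  }
  utils::write.table(regions,
                     file.path(dir, paste0(prefix, "_regions.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(islands)) {
    utils::write.table(islands$windows,
                       file.path(dir, paste0(prefix, "_rohi_windows.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(islands$islands))
      export_bed(islands$islands,
                 file.path(dir, paste0(prefix, "_rohi.bed")))
  }
  if (!is.null(ann) && nrow(regions)) {
    hit <- intersect_markers(regions, ann)
    if (nrow(hit$markers)) {
      mk <- data.frame(chrom = hit$markers$chrom,
                       start = hit$markers$pos, end = hit$markers$pos,
                       name = hit$markers$id)
      export_bed(mk, file.path(dir, paste0(prefix, "_markers.bed")),
                 name_col = "name")
    }
  }
  invisible(dir)
}
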