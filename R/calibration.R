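#' Calibrate ROH-calling conditions against pedigree kinship
#'
#' For each calling condition (heterozygote allowance x SNPs-per-window,
#' with `min_snp` tied to `window_snp`) and each F_ROH length cut-off,
#' computes every offspring's F_ROH and regresses it (ordinary least
#' squares, one observation per offspring) on the parental kinship
#' coefficient of its family. A slope near 1 and a high R-squared indicate
#' that the condition recovers pedigree inbreeding well.
#'
#' @param gm genotype matrix holding the family offspring (and possibly
#'   their parents).
#' @param map matching marker map.
#' @param genome an [ra_genome()].
#' @param pedigree data.frame with `id`, `sire`, `dam`, `family` (see
#'   [build_design()]); rows with both parents known are the offspring.
#' @param theta named numeric vector of parental kinship per family label
#'   (realized truth or [estimate_ibd()] output).
#' @param grid data.frame with columns `window_het` and `window_snp`; the
#'   default crosses het 0/1 with the 24-40 SNP grid.
#' @param cutoffs F_ROH length cut-offs in Mb.
#' @param panel label for the marker panel being calibrated.
#' @param params_base template [roh_params()] supplying the remaining
#'   calling parameters.
#' @return object of class `ra_calibration`: list with `cells` (one row
#'   per condition x cutoff: `panel`, `window_het`, `window_snp`,
#'   `cutoff_mb`, `intercept`, `slope`, `r2`, plus the coefficient of
#'   variation of F_ROH within each kinship class) and `froh` (offspring x
#'   condition F_ROH values).
#' @export
calibrate <- function(gm, map, genome, pedigree, theta,
                      grid = expand.grid(window_het = 0:1,
                                         window_snp = c(24L, 37L, 40L)),
                      cutoffs = c(1, 2, 4, 8, 10), panel = "panel",
                      params_base = roh_params()) {
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), ,
                  drop = FALSE]
  off <- off[off$id %in% rownames(gm), , drop = FALSE]
  if (!nrow(off)) stop("no offspring with known parents in the pedigree")
  if (any(!off$family %in% names(theta)))
    stop("every offspring's family must appear in theta")
  x <- unname(theta[off$family])
  if (length(unique(round(x, 12))) < 3L)
    stop("degenerate regression: fewer than 3 distinct theta values")
  cells <- vector("list", 0L)
  froh_all <- list()
  classes <- classify_kinship(pmin(pmax(x, 0), 0.5))
  for (gi in seq_len(nrow(grid))) {
    p <- params_base
    p$window_het <- as.integer(grid$window_het[gi])
    p$window_snp <- as.integer(grid$window_snp[gi])
    p$min_snp <- p$window_snp
    segs <- call_roh(gm, map, p, individuals = off$id)
    for (cu in cutoffs) {
      fr <- f_roh_by_individual(segs, genome, cutoff_mb = cu,
                                individuals = off$id)
      fit <- stats::lm(fr ~ x)
      cv_cls <- vapply(unique(classes), function(cl) {
        v <- fr[classes == cl]
        if (length(v) < 2L || mean(v) == 0) return(NA_real_)
        100 * stats::sd(v) / mean(v)
      }, numeric(1))
      cell <- data.frame(panel = panel,
                         window_het = p$window_het,
                         window_snp = p$window_snp,
                         cutoff_mb = cu,
                         intercept = unname(stats::coef(fit)[1L]),
                         slope = unname(stats::coef(fit)[2L]),
                         r2 = summary(fit)$r.squared,
                         stringsAsFactors = FALSE)
      for (cl in names(cv_cls)) cell[[paste0("cv_froh_", cl)]] <- cv_cls[[cl]]
      cells[[length(cells) + 1L]] <- cell
      froh_all[[sprintf("het%d_snp%d_cut%g", p$window_het, p$window_snp,
                        cu)]] <- fr
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells, froh = froh_all, theta = theta,
                 offspring = off$id),
            class = "ra_calibration")
}

#' @export
print.ra_calibration <- function(x, ...) {
  cat(sprintf("<ra_calibration> %d condition cells, %d offspring\n",
              nrow(x$cells), length(x$offspring)))
  best <- x$cells[which.max(x$cells$r2), ]
  cat(sprintf("  best R2 = %.3f at het=%d, window=%d, cutoff=%g Mb\n",
              best$r2, best$window_het, best$window_snp, best$cutoff_mb))
  invisible(x)
}

#' Coefficient of variation of regression coefficients across panels
#'
#' For each calling condition (`window_het` x `cutoff_mb`, and
#' `window_snp` when it varies), computes the percent coefficient of
#' variation, `100 * sd / mean` (sample standard deviation), of the
#' regression intercept and slope across marker panels. At least two
#' panels per condition are required; a zero mean yields `NA`.
#'
#' @param cells calibration cell table (`$cells` of [calibrate()], or
#'   rows bound over several panels).
#' @return data.frame with one row per condition: `window_het`,
#'   `cutoff_mb` (and `window_snp`), `n_panels`, `cv_intercept`,
#'   `cv_slope`.
#' @export
cv_across_panels <- function(cells) {
  key_cols <- c("window_het", "cutoff_mb")
  if ("window_snp" %in% names(cells) &&
      length(unique(cells$window_snp)) > 1L)
    key_cols <- c("window_het", "window_snp", "cutoff_mb")
  key <- interaction(cells[key_cols], drop = TRUE)
  out <- lapply(levels(key), function(k) {
    g <- cells[key == k, , drop = FALSE]
    if (nrow(g) < 2L)
      stop("need at least 2 panels per condition for a CV")
    cv <- function(v) if (mean(v) == 0) NA_real_
                      else 100 * stats::sd(v) / mean(v)
    cbind(g[1L, key_cols, drop = FALSE],
          data.frame(n_panels = nrow(g),
                     cv_intercept = cv(g$intercept),
                     cv_slope = cv(g$slope)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select the best calling condition
#'
#' Conditions (`window_het` x `window_snp` x `cutoff_mb`) are ranked by
#' mean R-squared across panels, ties broken by the lower slope CV and
#' then the lower intercept CV. Within the winning condition, the panel
#' with the highest R-squared is returned; a panel tie is broken toward
#' the smaller absolute intercept (the intercept is the baseline F_ROH of
#' nominally unrelated parents, so a larger one points to spurious ROH
#' from genotyping artifacts), then toward the slope closest to 1.
#'
#' @param cells calibration cells over one or more panels.
#' @return single-row data.frame: the winning cell, with `mean_r2`,
#'   `cv_slope` and `cv_intercept` columns appended.
#' @export
select_best <- function(cells) {
  if (!nrow(cells)) stop("no calibration cells")
  key_cols <- intersect(c("window_het", "window_snp", "cutoff_mb"),
                        names(cells))
  key <- interaction(cells[key_cols], drop = TRUE)
  multi_panel <- any(tapply(cells$panel, key, function(v)
    length(unique(v))) > 1L)
  cond <- lapply(levels(key), function(k) {
    g <- cells[key == k, , drop = FALSE]
    cv <- function(v) if (length(v) < 2L || mean(v) == 0) Inf
                      else 100 * stats::sd(v) / mean(v)
    data.frame(key = k, mean_r2 = mean(g$r2),
               cv_slope = if (multi_panel) cv(g$slope) else Inf,
               cv_intercept = if (multi_panel) cv(g$intercept) else Inf,
               stringsAsFactors = FALSE)
  })
  cond <- do.call(rbind, cond)
  ord <- order(-cond$mean_r2, cond$cv_slope, cond$cv_intercept)
  win <- cond[ord[1L], ]
  g <- cells[key == win$key, , drop = FALSE]
  g <- g[order(-g$r2, abs(g$intercept), abs(g$slope - 1)), , drop = FALSE]
  out <- g[1L, , drop = FALSE]
  out$mean_r2 <- win$mean_r2
  out$cv_slope <- ifelse(is.finite(win$cv_slope), win$cv_slope, NA_real_)
  out$cv_intercept <- ifelse(is.finite(win$cv_intercept),
                             win$cv_intercept, NA_real_)
  rownames(out) <- NULL
  out
}

#' Bundled calibration reference table
#'
#' Published regression summaries (intercept, slope, R-squared) of
#' offspring F_ROH on parental kinship for three turbot SNP panels
#' (18,198 / 21,615 / 25,511 markers), 0 or 1 heterozygote allowed per
#' window, and four ROH length cut-offs, as shipped in
#' `inst/extdata/table1_calibration.tsv`. The `flag` column marks one
#' suspect printed value (a probable typo) which is carried as printed.
#'
#' @return data.frame with columns `panel`, `window_het`, `cutoff_mb`,
#'   `intercept`, `slope`, `r2`, `flag`.
#' @export
turbot_calibration_table <- function() {
  utils::read.table(
    system.file("extdata", "table1_calibration.tsv", package = "rohatlas",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
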