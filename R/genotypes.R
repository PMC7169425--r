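#' Genotype matrix
#'
#' Diploid biallelic genotypes coded 0 (hom-ref), 1 (het), 2 (hom-alt) and
#' `NA` (missing), one row per individual and one column per marker of the
#' accompanying marker map. Genotypes are unphased; phase in input files is
#' ignored. Missing calls are never imputed.
#'
#' @param calls integer matrix (individuals x markers) with values in
#'   0/1/2/NA.
#' @param map the matching [marker_map()].
#' @param ids individual identifiers (row names).
#' @return The validated matrix, of class `ra_geno`.
#' @export
genotype_matrix <- function(calls, map, ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map))
    stop("genotype matrix has ", ncol(calls), " markers; map has ", nrow(map))
  v <- calls[!is.na(calls)]
  if (length(v) && (min(v) < 0L || max(v) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(calls)))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  rownames(calls) <- ids
  colnames(calls) <- map$marker_id
  class(calls) <- c("ra_geno", class(calls))
  calls
}

#' Site filters applied before analysis
#'
#' Retains markers genotyped in strictly more than `min_call_rate` of the
#' individuals, optionally drops markers at which only a single allele is
#' observed, and optionally keeps a single marker per locus tag (the one
#' closest to the locus 5' end, i.e. lowest position). The operation is
#' idempotent.
#'
#' @param gm genotype matrix ([genotype_matrix()]).
#' @param map matching marker map.
#' @param min_call_rate call-rate threshold in `[0, 1]`; markers are kept
#'   when call rate > `min_call_rate` (strict, so 0 keeps any genotyped
#'   marker).
#' @param drop_monomorphic drop markers where all non-missing calls carry a
#'   single allele.
#' @param locus_tag optional character vector (one per marker) of locus tags
#'   (e.g. RAD-tag ids); per tag only the lowest-position marker is kept.
#' @return list with filtered `gm` and `map` (and `locus_tag` when given).
#' @export
filter_sites <- function(gm, map, min_call_rate = 0.56,
                         drop_monomorphic = TRUE, locus_tag = NULL) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1)
  n <- nrow(gm)
  keep <- colMeans(!is.na(gm)) > min_call_rate
  if (drop_monomorphic) {
    nA <- colSums(gm == 0L, na.rm = TRUE) * 2L + colSums(gm == 1L, na.rm = TRUE)
    nB <- colSums(gm == 2L, na.rm = TRUE) * 2L + colSums(gm == 1L, na.rm = TRUE)
    keep <- keep & nA > 0L & nB > 0L
  }
  if (!is.null(locus_tag)) {
    stopifnot(length(locus_tag) == nrow(map))
    first <- rep(TRUE, nrow(map))
    tagged <- which(!is.na(locus_tag) & keep)
    if (length(tagged)) {
      # map rows are position-ordered, so the first kept marker of a tag is
      # the closest to the 5' end
      first[tagged] <- !duplicated(locus_tag[tagged])
    }
    keep <- keep & first
  }
  if (!any(keep)) stop("empty panel: no marker passed the site filters")
  out_map <- map[keep, , drop = FALSE]
  rownames(out_map) <- NULL
  class(out_map) <- c("ra_map", "data.frame")
  res <- list(gm = gm[, keep, drop = FALSE], map = out_map)
  class(res$gm) <- c("ra_geno", class(res$gm)[class(res$gm) != "ra_geno"])
  if (!is.null(locus_tag)) res$locus_tag <- locus_tag[keep]
  res
}
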