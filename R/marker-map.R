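#' Marker map
#'
#' Ordered SNP positions per chromosome: the coordinate backbone for sliding
#' windows, ROH segments and diversity scans. Coordinates are 1-based
#' inclusive throughout the package; exported BED converts to 0-based
#' half-open.
#'
#' @param chrom chromosome id per marker.
#' @param pos 1-based position in bp per marker.
#' @param marker_id unique marker identifiers; generated when missing.
#' @param ref,alt optional reference/alternate alleles.
#' @param genome optional [ra_genome()]; when supplied, every chromosome in
#'   the map must be part of the genome and positions must fit within it.
#' @return A data.frame of class `ra_map` with columns `chrom`, `pos`,
#'   `marker_id`, `ref`, `alt`, ordered by (chrom, pos).
#' @export
marker_map <- function(chrom, pos, marker_id = NULL, ref = NA, alt = NA,
                       genome = NULL) {
  n <- length(chrom)
  if (length(pos) != n) stop("chrom and pos lengths differ")
  if (is.null(marker_id)) marker_id <- sprintf("snp%06d", seq_len(n))
  if (anyDuplicated(marker_id)) stop("marker ids must be unique")
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  marker_id = as.character(marker_id),
                  ref = rep_len(as.character(ref), n),
                  alt = rep_len(as.character(alt), n),
                  stringsAsFactors = FALSE)
  chrom_levels <- unique(m$chrom)
  if (!is.null(genome)) {
    unknown <- setdiff(chrom_levels, genome$chrom_ids)
    if (length(unknown))
      stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    chrom_levels <- intersect(genome$chrom_ids, chrom_levels)
    bad <- m$pos > genome$chrom_lengths[m$chrom] | m$pos < 1
    if (any(bad)) stop("marker positions outside chromosome bounds")
  }
  ord <- order(match(m$chrom, chrom_levels), m$pos)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  for (cc in chrom_levels) {
    p <- m$pos[m$chrom == cc]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", cc)
  }
  class(m) <- c("ra_map", "data.frame")
  m
}

# markers per chromosome, in map order
.chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)[unique(map$chrom)]

#' Average marker spacing in kb per SNP
#'
#' @param map an `ra_map`.
#' @param genome an `ra_genome`.
#' @return `round(total_length / 1000 / n_markers)`, an integer number of kb.
#' @examples
#' snp_density_kb(marker_map(c("C01", "C01"), c(1, 500)),
#'                ra_genome(c(C01 = 1e6)))
#' @export
snp_density_kb <- function(map, genome) {
  if (nrow(map) == 0L) stop("empty marker map")
  round(genome$total_length / 1000 / nrow(map))
}
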