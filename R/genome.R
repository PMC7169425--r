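#' Genome description
#'
#' A genome is an ordered set of chromosomes with lengths in base pairs.
#' It is the coordinate backbone for window tiling, ROH coverage and the
#' denominator of the genomic inbreeding coefficient F_ROH.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names are the chromosome identifiers, in order.
#' @return An object of class `ra_genome` with elements `chrom_ids`,
#'   `chrom_lengths` and `total_length`.
#' @examples
#' g <- ra_genome(c(chr1 = 2e6, chr2 = 1e6))
#' g$total_length
#' @export
ra_genome <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chromosome ids must be unique and named")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive")
  structure(
    list(chrom_ids = names(chrom_lengths),
         chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                         names(chrom_lengths)),
         total_length = sum(as.numeric(chrom_lengths))),
    class = "ra_genome")
}

#' Default turbot-like genome: 22 chromosomes totaling 567 Mb
#'
#' Chromosome lengths default to (near) equal shares of the total; a length
#' table may override via [ra_genome()].
#'
#' @param total_length total genome size in bp.
#' @param n_chrom number of chromosomes.
#' @return An `ra_genome`.
#' @export
turbot_genome <- function(total_length = 567e6, n_chrom = 22) {
  base <- floor(total_length / n_chrom)
  len <- rep(base, n_chrom)
  len[n_chrom] <- total_length - base * (n_chrom - 1)
  ids <- sprintf("C%02d", seq_len(n_chrom))
  ra_genome(stats::setNames(len, ids))
}

#' @export
print.ra_genome <- function(x, ...) {
  cat(sprintf("<ra_genome> %d chromosomes, %.1f Mb total\n",
              length(x$chrom_ids), x$total_length / 1e6))
  invisible(x)
}
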