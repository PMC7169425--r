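#' Method-of-moments IBD estimation for a pair of individuals
#'
#' Estimates the proportions of the genome over which a pair shares 0, 1 or
#' 2 alleles identical by descent (Z0, Z1, Z2) from identity-by-state
#' counts, using sample allele frequencies, in the style of PLINK's
#' `--genome` report. Negative raw estimates are bounded to zero and the
#' triple renormalized to sum to one. `PI_HAT = Z1/2 + Z2` is the
#' proportion of alleles shared IBD and `theta = PI_HAT/2` the kinship
#' coefficient, which equals the expected inbreeding coefficient of the
#' pair's offspring.
#'
#' Markers used are those jointly non-missing in the pair and polymorphic
#' in the sample; allele frequencies are estimated from the full genotype
#' matrix.
#'
#' @param gm genotype matrix ([genotype_matrix()]).
#' @param map matching marker map (unused beyond dimension checks; kept for
#'   interface symmetry).
#' @param pair length-2 vector of individual ids or row indices.
#' @return data.frame of class `ra_pair_ibd` with columns `id1`, `id2`,
#'   `n_markers`, `ibs0`, `ibs1`, `ibs2`, `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `theta`, `class`.
#' @export
estimate_ibd <- function(gm, map, pair) {
  stopifnot(length(pair) == 2L)
  if (is.character(pair)) pair <- match(pair, rownames(gm))
  if (any(is.na(pair)) || any(pair < 1L) || any(pair > nrow(gm)))
    stop("individual index out of range")
  g1 <- gm[pair[1L], ]
  g2 <- gm[pair[2L], ]
  # sample alternate-allele frequencies from the full input
  nn <- colSums(!is.na(gm))
  p <- (colSums(gm == 2L, na.rm = TRUE) * 2 + colSums(gm == 1L, na.rm = TRUE)) /
    (2 * pmax(nn, 1L))
  use <- !is.na(g1) & !is.na(g2) & p > 0 & p < 1
  if (sum(use) < 100L)
    stop("insufficient markers: ", sum(use), " joint polymorphic markers")
  g1 <- g1[use]; g2 <- g2[use]; p <- p[use]; q <- 1 - p
  # |g1 - g2| is 2 for opposite homozygotes (IBS 0), 1 for hom vs het
  # (IBS 1) and 0 for identical codes (IBS 2, incl. het/het)
  ibs <- 2L - abs(g1 - g2)
  n <- length(ibs)
  obs <- c(sum(ibs == 0L), sum(ibs == 1L), sum(ibs == 2L))
  # expected per-marker P(IBS = i | IBD = z)
  e00 <- sum(2 * p^2 * q^2)
  e10 <- sum(4 * p^3 * q + 4 * p * q^3)
  e20 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e11 <- sum(2 * p^2 * q + 2 * p * q^2)
  e21 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  z0 <- obs[1L] / e00
  z1 <- (obs[2L] - z0 * e10) / e11
  z2 <- (obs[3L] - z0 * e20 - z1 * e21) / n
  z <- pmax(c(z0, z1, z2), 0)
  z <- if (sum(z) > 0) z / sum(z) else c(1, 0, 0)
  pi_hat <- z[2L] / 2 + z[3L]
  theta <- pi_hat / 2
  out <- data.frame(id1 = rownames(gm)[pair[1L]],
                    id2 = rownames(gm)[pair[2L]],
                    n_markers = n, ibs0 = obs[1L], ibs1 = obs[2L],
                    ibs2 = obs[3L], Z0 = z[1L], Z1 = z[2L], Z2 = z[3L],
                    PI_HAT = pi_hat, theta = theta,
                    class = classify_kinship(theta),
                    stringsAsFactors = FALSE)
  class(out) <- c("ra_pair_ibd", "data.frame")
  out
}

#' IBD estimates for many pairs
#'
#' @param gm genotype matrix.
#' @param map matching marker map.
#' @param pairs two-column matrix or data.frame of ids/indices; `NULL`
#'   means all pairs.
#' @return data.frame, one [estimate_ibd()] row per pair.
#' @export
pairwise_ibd <- function(gm, map, pairs = NULL) {
  if (is.null(pairs)) {
    cmb <- utils::combn(nrow(gm), 2L)
    pairs <- cbind(cmb[1L, ], cmb[2L, ])
  }
  pairs <- as.matrix(pairs)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    estimate_ibd(gm, map, pairs[i, ])))
  rownames(out) <- NULL
  out
}

#' Assign a kinship class from the kinship coefficient
#'
#' Class boundaries: unrelated below 0.0076, second cousin up to 0.038,
#' first cousin up to 0.0937, half-sibling up to 0.1872, full-sibling
#' above. A value on a boundary is assigned to the higher-relatedness
#' class.
#'
#' @param theta kinship coefficient(s) in `[0, 0.5]`.
#' @return character vector of class labels.
#' @examples
#' classify_kinship(c(0, 0.05, 0.25))
#' @export
classify_kinship <- function(theta) {
  if (any(theta < 0 | theta > 0.5))
    stop("theta must be within [0, 0.5]")
  cut_pts <- c(0.0076, 0.038, 0.0937, 0.1872)
  labels <- c("unrelated", "second_cousin", "first_cousin", "half_sib",
              "full_sib")
  labels[findInterval(theta, cut_pts) + 1L]
}

#' Write a pairwise IBD table in plink.genome-like layout
#'
#' @param ibd data.frame from [pairwise_ibd()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ibd <- function(ibd, path) {
  out <- data.frame(FID1 = ibd$id1, IID1 = ibd$id1, FID2 = ibd$id2,
                    IID2 = ibd$id2, Z0 = ibd$Z0, Z1 = ibd$Z1, Z2 = ibd$Z2,
                    PI_HAT = ibd$PI_HAT, THETA = ibd$theta,
                    CLASS = ibd$class)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
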