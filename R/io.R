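#' Read genotypes and a marker map from VCF or PLINK-style PED/MAP text
#'
#' Only biallelic SNP records are kept; multiallelic records are dropped with
#' a warning giving the count. Phase separators in VCF genotypes are ignored
#' (genotypes are treated as unphased). For `format = "ped_map"`, `path` is
#' the common prefix of `<path>.ped` and `<path>.map`; allele codes are
#' oriented alphabetically (the alphabetically first allele observed at a
#' marker is taken as the reference), since PLINK text files carry no
#' ref/alt designation.
#'
#' @param path file path (VCF) or PED/MAP prefix.
#' @param format `"vcf"` or `"ped_map"`.
#' @param genome optional [ra_genome()] used to validate chromosome ids and
#'   positions; an unknown chromosome is an error naming the id.
#' @return list with `map` ([marker_map()]) and `gm` ([genotype_matrix()]).
#' @export
read_genotypes <- function(path, format = c("vcf", "ped_map"), genome = NULL) {
  format <- match.arg(format)
  if (format == "vcf") .read_vcf(path, genome) else .read_ped_map(path, genome)
}

.check_sorted <- function(chrom, pos) {
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) stop("unsorted marker map on ", cc)
  }
}

.read_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- t(as.matrix(fix))  # single-record file
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !is.na(alt)
  if (any(!biallelic))
    warning(sum(!biallelic), " multiallelic/non-SNP record(s) dropped")
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  chrom <- fix[biallelic, "CHROM"]
  pos <- as.numeric(fix[biallelic, "POS"])
  .check_sorted(chrom, pos)
  id <- fix[biallelic, "ID"]
  miss_id <- is.na(id) | id == "."
  id[miss_id] <- paste0(chrom[miss_id], "_", pos[miss_id])
  map <- marker_map(chrom, pos, id, ref = ref[biallelic],
                    alt = alt[biallelic], genome = genome)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  gm <- genotype_matrix(t(code), map, ids = colnames(gt))
  list(map = map, gm = gm)
}

.read_ped_map <- function(prefix, genome = NULL) {
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f) || !file.exists(map_f))
    stop("no such file: ", ped_f, " / ", map_f)
  mp <- utils::read.table(map_f, header = FALSE, stringsAsFactors = FALSE)
  colnames(mp)[1:4] <- c("chrom", "marker_id", "cm", "pos")
  .check_sorted(as.character(mp$chrom), mp$pos)
  map <- marker_map(mp$chrom, mp$pos, mp$marker_id, genome = genome)
  ped <- utils::read.table(ped_f, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop("PED column count does not match MAP marker count")
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  code <- matrix(NA_integer_, nrow = nrow(ped), ncol = m)
  ref <- alt <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2L)
      stop("more than two alleles at marker ", map$marker_id[j])
    ref[j] <- if (length(alleles) >= 1L) alleles[1L] else NA_character_
    alt[j] <- if (length(alleles) == 2L) alleles[2L] else NA_character_
    miss <- a1[, j] == "0" | a2[, j] == "0"
    nalt <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    nalt[is.na(nalt)] <- 0L
    code[, j] <- ifelse(miss, NA_integer_, as.integer(nalt))
  }
  map$ref <- ref; map$alt <- alt
  gm <- genotype_matrix(code, map, ids = ids)
  list(map = map, gm = gm)
}

#' Write genotypes as VCF or PLINK-style PED/MAP text
#'
#' The VCF writer emits minimal v4.2 records with GT fields; the PED/MAP
#' writer encodes alleles from the map's `ref`/`alt` columns, falling back to
#' `A`/`B` so that a write/read round trip preserves every call (see
#' [read_genotypes()] for the orientation rule).
#'
#' @param gm genotype matrix.
#' @param map matching marker map.
#' @param path output file (VCF) or prefix (PED/MAP).
#' @param format `"vcf"` or `"ped_map"`.
#' @param header_lines extra `##` header lines for the VCF (e.g. a seed
#'   stamp).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, map, path, format = c("vcf", "ped_map"),
                            header_lines = character()) {
  format <- match.arg(format)
  ref <- ifelse(is.na(map$ref), "A", map$ref)
  alt <- ifelse(is.na(map$alt), "B", map$alt)
  if (format == "vcf") {
    gt <- c("0/0", "0/1", "1/1")[gm + 1L]
    gt[is.na(gt)] <- "./."
    gt <- matrix(gt, nrow = nrow(gm))
    hdr <- c("##fileformat=VCFv4.2",
             header_lines,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(gm)), collapse = "\t"))
    body <- paste(map$chrom, format(map$pos, scientific = FALSE, trim = TRUE),
                  map$marker_id, ref, alt, ".", "PASS", ".", "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    return(invisible(path))
  }
  a1 <- matrix(ref[col(gm)], nrow = nrow(gm))
  a2 <- matrix(alt[col(gm)], nrow = nrow(gm))
  hom_alt <- which(gm == 2L); hom_ref <- which(gm == 0L)
  a1[hom_alt] <- a2[hom_alt]
  a2[hom_ref] <- a1[hom_ref]
  miss <- which(is.na(gm))
  a1[miss] <- "0"; a2[miss] <- "0"
  inter <- matrix("", nrow = nrow(gm), ncol = 2L * ncol(gm))
  inter[, seq(1L, 2L * ncol(gm), by = 2L)] <- a1
  inter[, seq(2L, 2L * ncol(gm), by = 2L)] <- a2
  ids <- rownames(gm)
  ped <- cbind(ids, ids, "0", "0", "0", "-9", inter)
  utils::write.table(ped, paste0(path, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mp <- data.frame(map$chrom, map$marker_id, 0,
                   format(map$pos, scientific = FALSE, trim = TRUE))
  utils::write.table(mp, paste0(path, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a functional-marker annotation table
#'
#' Tab-separated with header columns `id`, `chrom`, `pos`, `category`
#' (`High-GD`/`Low-GD`), `population` (`Broodstock`/`Wild`) and `note`. A
#' table of QTL-associated and outlier markers for turbot ships with the
#' package (see [turbot_qtl_markers()]).
#'
#' @param path TSV file.
#' @param genome optional [ra_genome()] for coordinate validation.
#' @return data.frame of annotated markers.
#' @export
read_marker_annotation <- function(path, genome = NULL) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("id", "chrom", "pos", "category", "population", "note")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (!all(ann$category %in% c("High-GD", "Low-GD")))
    stop("category must be High-GD or Low-GD")
  if (!all(ann$population %in% c("Broodstock", "Wild")))
    stop("population must be Broodstock or Wild")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(ann$chrom), genome$chrom_ids)
    if (length(unknown))
      stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    if (any(ann$pos < 1 | ann$pos > genome$chrom_lengths[ann$chrom]))
      stop("annotation positions outside chromosome bounds")
  }
  ann
}

#' Bundled turbot QTL/outlier marker annotation
#'
#' Markers associated with production-trait QTL (growth, disease resistance)
#' or flagged as selection outliers in domestic and wild turbot, with their
#' genome positions, as shipped in `inst/extdata/qtl_markers_turbot.tsv`.
#'
#' @return data.frame (see [read_marker_annotation()]).
#' @export
turbot_qtl_markers <- function() {
  read_marker_annotation(
    system.file("extdata", "qtl_markers_turbot.tsv", package = "rohatlas",
                mustWork = TRUE))
}

#' Export intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally a
#'   name column.
#' @param path output file.
#' @param name_col optional column used for the BED name field.
#' @return `path`, invisibly.
#' @export
export_bed <- function(x, path, name_col = NULL) {
  bed <- data.frame(x$chrom,
                    format(x$start - 1, scientific = FALSE, trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name_col)) bed$name <- x[[name_col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
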