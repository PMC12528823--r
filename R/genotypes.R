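#' Genotype matrix container
#'
#' Stores biallelic SNP calls as alternate-allele dosages (0, 1, 2, or `NA`
#' for missing) for a panel of individuals, together with the marker map
#' (chromosome label and physical position).  Chromosome labels are kept as
#' character strings so that split chromosome arms such as `"1S"` / `"1L"`
#' are representable.
#'
#' @param calls integer matrix, samples in rows and markers in columns;
#'   entries must be 0, 1, 2 or `NA`.  Row names are sample identifiers,
#'   column names marker identifiers.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based
#'   physical position in bp), one row per column of `calls`, same order.
#' @return an object of class `"geno_matrix"`.
#' @export
genotype_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(map), all(c("marker", "chrom", "pos") %in% names(map)))
  if (ncol(calls) != nrow(map))
    stop("`calls` has ", ncol(calls), " markers but `map` has ", nrow(map), " rows")
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$marker))
    stop("duplicated marker identifiers in map")
  if (any(map$pos < 0, na.rm = TRUE))
    stop("negative marker positions")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  colnames(calls) <- map$marker
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  structure(list(calls = calls, map = map[, c("marker", "chrom", "pos")]),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "markers\n")
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Number of samples / markers in a genotype matrix
#' @param g a `geno_matrix`
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$calls)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`
#' @param samples sample index or names (default all)
#' @param markers marker index or names (default all)
#' @return a `geno_matrix`
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  calls <- g$calls
  map <- g$map
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    calls <- calls[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (!is.null(samples))
    calls <- calls[samples, , drop = FALSE]
  genotype_matrix(calls, map)
}

#' Read genotypes from VCF or HapMap-style TSV
#'
#' VCF input is parsed with \pkg{vcfR}; only the GT field is used and
#' dosages are counts of the alternate allele.  Multi-allelic records are
#' dropped (a message reports how many).  The HapMap-style dialect is a
#' tab-separated table with columns `marker`, `chrom`, `pos` followed by one
#' column per sample holding 0/1/2/NA.
#'
#' @param path input file path.
#' @param format `"vcf"` or `"hapmap"`; guessed from the file extension when
#'   missing (`.vcf` -> vcf, otherwise hapmap).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "hapmap"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_hapmap(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message("read_genotypes: dropped ", sum(multi), " multi-allelic record(s)")
  if (all(multi)) stop("no usable biallelic markers in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(vcf@fix), names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dos <- gt_to_dosage(gt)           # markers x samples
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  genotype_matrix(t(dos), map)
}

# GT strings like "0/1", "1|1", "./." -> alternate-allele dosage
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lookup <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_integer_)
    suppressWarnings(ali <- as.integer(al))
    if (anyNA(ali)) stop("malformed GT field: '", s, "'")
    if (any(ali > 1)) stop("non-biallelic allele index in GT field: '", s, "'")
    sum(ali)
  }, integer(1))
  out <- lookup[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

read_genotypes_hapmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df)[1:3]))
    stop("hapmap-style file must start with columns marker, chrom, pos: ", path)
  if (nrow(df) == 0) stop("no usable markers in ", path)
  samp <- names(df)[-(1:3)]
  if (length(samp) == 0) stop("no sample columns in ", path)
  calls <- t(vapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.integer(df[i, -(1:3)]))
    v
  }, integer(length(samp))))
  if (length(samp) == 1) calls <- matrix(calls, ncol = 1)
  calls <- t(calls)  # samples x markers
  bad <- which(!(calls %in% c(0L, 1L, 2L, NA_integer_)))
  if (length(bad))
    stop("malformed dosage value in ", path, " near data row ",
         ((bad[1] - 1) %/% length(samp)) + 1)
  rownames(calls) <- samp
  map <- data.frame(marker = df$marker, chrom = df$chrom,
                    pos = as.integer(df$pos), stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}

#' Write genotypes to VCF or HapMap-style TSV
#'
#' The VCF writer emits a minimal plain-text VCF v4.2 with GT-only records
#' (REF/ALT set to placeholder A/B alleles); it round-trips exactly through
#' [read_genotypes()].
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"hapmap"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("hapmap", "vcf")) {
  format <- match.arg(format)
  if (format == "hapmap") {
    df <- data.frame(g$map, t(g$calls), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(g$calls)), collapse = "\t")),
               con)
    gtcode <- c("0/0", "0/1", "1/1")
    for (j in seq_len(n_markers(g))) {
      d <- g$calls[, j]
      gt <- ifelse(is.na(d), "./.", gtcode[d + 1L])
      writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$marker[j],
                         "A", "B", ".", "PASS", ".", "GT", gt), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Minor allele frequency per marker
#'
#' Computed on non-missing calls only.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, one MAF per marker (`NaN` if all calls missing).
#' @export
marker_maf <- function(g) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Marker and sample quality-control filter
#'
#' Removes markers with minor allele frequency below `maf_min` or with a
#' missing-call fraction strictly greater than `max_missing_marker`; then
#' removes samples with missing fraction strictly greater than
#' `max_missing_sample`.  Markers are filtered before samples, and MAF is
#' computed on non-missing calls.  Markers with MAF exactly equal to the
#' threshold are kept (keep if MAF >= `maf_min`).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @param max_missing_marker maximum tolerated missing fraction per marker.
#' @param max_missing_sample maximum tolerated missing fraction per sample.
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report` with per-filter removal counts).
#' @export
filter_markers <- function(g, maf_min = 0.05, max_missing_marker = 0.3,
                           max_missing_sample = 0.3) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            max_missing_marker >= 0, max_missing_marker <= 1,
            max_missing_sample >= 0, max_missing_sample <= 1)
  n_m_in <- n_markers(g); n_s_in <- n_samples(g)
  miss_m <- colMeans(is.na(g$calls))
  maf <- marker_maf(g)
  drop_miss <- miss_m > max_missing_marker
  drop_maf <- !drop_miss & (is.nan(maf) | maf < maf_min)
  keep_m <- !(drop_miss | drop_maf)
  if (!any(keep_m)) {
    rep0 <- qc_report(n_m_in, 0L, n_s_in, n_s_in,
                      sum(drop_miss), sum(drop_maf), 0L,
                      maf_min, max_missing_marker, max_missing_sample)
    stop(errorCondition(
      paste0("all markers removed by QC (", sum(drop_miss),
             " by missingness, ", sum(drop_maf), " by MAF)"),
      report = rep0, class = "metsel_qc_error"))
  }
  g2 <- subset_genotypes(g, markers = which(keep_m))
  miss_s <- rowMeans(is.na(g2$calls))
  keep_s <- miss_s <= max_missing_sample
  g3 <- subset_genotypes(g2, samples = which(keep_s))
  report <- qc_report(n_m_in, n_markers(g3), n_s_in, n_samples(g3),
                      sum(drop_miss), sum(drop_maf), sum(!keep_s),
                      maf_min, max_missing_marker, max_missing_sample)
  list(genotypes = g3, report = report)
}

qc_report <- function(n_markers_in, n_markers_out, n_samples_in, n_samples_out,
                      removed_marker_missing, removed_marker_maf,
                      removed_sample_missing,
                      maf_min, max_missing_marker, max_missing_sample) {
  structure(list(
    n_markers_in = as.integer(n_markers_in),
    n_markers_out = as.integer(n_markers_out),
    n_samples_in = as.integer(n_samples_in),
    n_samples_out = as.integer(n_samples_out),
    removed = c(marker_missing = as.integer(removed_marker_missing),
                marker_maf = as.integer(removed_marker_maf),
                sample_missing = as.integer(removed_sample_missing)),
    thresholds = c(maf_min = maf_min, max_missing_marker = max_missing_marker,
                   max_missing_sample = max_missing_sample),
    filter_order = c("marker_missingness", "marker_maf", "sample_missingness")),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker/sample QC (markers filtered before samples)\n")
  cat(sprintf("  markers: %d -> %d  (missing>%.0f%%: %d, MAF<%.3g: %d)\n",
              x$n_markers_in, x$n_markers_out,
              100 * x$thresholds["max_missing_marker"], x$removed["marker_missing"],
              x$thresholds["maf_min"], x$removed["marker_maf"]))
  cat(sprintf("  samples: %d -> %d  (missing>%.0f%%: %d)\n",
              x$n_samples_in, x$n_samples_out,
              100 * x$thresholds["max_missing_sample"], x$removed["sample_missing"]))
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Per-marker mean imputation of the dosage matrix, the convention used for
#' kinship, PCA and association scans.  Raw missing values are preserved in
#' the stored object; this returns a plain numeric matrix.
#'
#' @param g a [genotype_matrix()].
#' @return numeric samples x markers matrix without missing values.
#' @export
impute_dosage <- function(g) {
  x <- g$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  x
}
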