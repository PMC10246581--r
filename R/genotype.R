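#' Construct a genotype dosage matrix
#'
#' Container for SNP dosage calls of a set of breeding lines. Calls count the
#' alternate allele per marker: 0 and 2 are the two homozygotes, 1 is a
#' heterozygote, and `NA` marks a missing call.
#'
#' @param calls Integer matrix, lines x markers, values in `{0, 1, 2, NA}`.
#' @param line_ids Character vector of line (entry) identifiers, one per row.
#' @param marker_ids Character vector of marker identifiers, one per column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, line_ids = rownames(calls),
                            marker_ids = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    stopf("dosage calls must be 0, 1, 2 or NA; %d offending cells", sum(bad))
  }
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%05d", seq_len(ncol(calls)))
  if (length(line_ids) != nrow(calls) || length(marker_ids) != ncol(calls)) {
    stopf("identifier lengths do not match matrix dimensions")
  }
  dimnames(calls) <- list(line_ids, marker_ids)
  structure(list(calls = calls,
                 line_ids = as.character(line_ids),
                 marker_ids = as.character(marker_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-marker and per-line quality-control statistics
#'
#' `marker_missing_rate()` is the fraction of missing calls per marker,
#' `marker_het_rate()` the fraction of *non-missing* calls that are
#' heterozygous (dosage 1), and `line_missing_rate()` the fraction of missing
#' calls per line.
#'
#' @param G A [genotype_matrix()].
#' @return Named numeric vector.
#' @export
marker_missing_rate <- function(G) {
  colMeans(is.na(G$calls))
}

#' @rdname marker_missing_rate
#' @export
marker_het_rate <- function(G) {
  het <- colSums(G$calls == 1, na.rm = TRUE)
  typed <- colSums(!is.na(G$calls))
  out <- ifelse(typed == 0, 0, het / pmax(typed, 1))
  names(out) <- G$marker_ids
  out
}

#' @rdname marker_missing_rate
#' @export
line_missing_rate <- function(G) {
  rowMeans(is.na(G$calls))
}

#' Filter markers on missingness and heterozygosity
#'
#' Retains exactly the markers whose missing fraction is strictly below
#' `max_missing` and whose heterozygosity (fraction of non-missing calls equal
#' to 1) is strictly below `max_het`; marker order is preserved. The defaults
#' are the usual genotyping-by-sequencing QC thresholds for inbred wheat
#' panels (marker missingness < 40%, heterozygosity < 10%).
#'
#' @param G A [genotype_matrix()].
#' @param max_missing Exclusive upper bound on the per-marker missing fraction.
#' @param max_het Exclusive upper bound on the per-marker heterozygosity.
#' @return A filtered `genotype_matrix`.
#' @export
filter_markers <- function(G, max_missing = 0.40, max_het = 0.10) {
  if (!is_fraction(max_missing) || !is_fraction(max_het)) {
    stopf("max_missing and max_het must be single values in [0, 1]")
  }
  keep <- marker_missing_rate(G) < max_missing & marker_het_rate(G) < max_het
  genotype_matrix(G$calls[, keep, drop = FALSE],
                  G$line_ids, G$marker_ids[keep])
}

#' Filter lines on missingness
#'
#' Removes lines with *more than* `max_missing` missing data; a line at
#' exactly the threshold is retained.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing Inclusive upper bound on the per-line missing fraction.
#' @return A filtered `genotype_matrix`.
#' @export
filter_lines <- function(G, max_missing = 0.50) {
  if (!is_fraction(max_missing)) {
    stopf("max_missing must be a single value in [0, 1]")
  }
  keep <- line_missing_rate(G) <= max_missing
  if (!any(keep)) {
    stopf("all %d lines exceed %.0f%% missing data; nothing left after filtering",
          nrow(G$calls), 100 * max_missing)
  }
  genotype_matrix(G$calls[keep, , drop = FALSE],
                  G$line_ids[keep], G$marker_ids)
}

#' Mean-impute missing dosage calls
#'
#' Replaces each missing call by the marker's mean non-missing dosage,
#' returning a complete numeric matrix suitable as model input.
#'
#' @param G A [genotype_matrix()].
#' @return Numeric matrix (lines x markers) without missing values.
#' @export
impute_dosage <- function(G) {
  X <- G$calls
  storage.mode(X) <- "double"
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    stopf("markers entirely missing (%s); run filter_markers() first",
          paste(utils::head(G$marker_ids[all_missing], 3), collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV layout is lines x markers: first column `line_id`, remaining
#' columns named by marker, calls in `{0, 1, 2}` with `NA` for missing. VCF
#' input must contain biallelic SNPs only; genotypes are mapped
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA` (phased
#' separators are treated identically).
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  if (format == "tsv") read_genotype_tsv(path) else read_genotype_vcf(path)
}

read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "line_id") {
    stopf("malformed dosage TSV %s: first column must be 'line_id'", path)
  }
  mk <- names(df)[-1]
  calls <- matrix(NA_integer_, nrow(df), length(mk))
  for (j in seq_along(mk)) {
    v <- df[[j + 1]]
    v[v %in% c("NA", "", ".")] <- NA
    num <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(num) | !(num %in% 0:2)))
    if (length(bad)) {
      stopf("malformed dosage TSV %s: line %d, marker %s: value '%s'",
            path, bad[1] + 1L, mk[j], v[bad[1]])
    }
    calls[, j] <- num
  }
  genotype_matrix(calls, df[[1]], mk)
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stopf("multi-allelic VCF records are not supported (%d found, first at %s:%s)",
          sum(multi), vcf@fix[which(multi)[1], "CHROM"],
          vcf@fix[which(multi)[1], "POS"])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcf@fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(vcf@fix[no_id, "CHROM"], "_", vcf@fix[no_id, "POS"])
  core <- sub(":.*$", "", gt)
  core <- gsub("\\|", "/", core)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dose <- matrix(map[core], nrow = nrow(core))
  unknown <- !is.na(core) & !(core %in% c(names(map), "./.", "."))
  if (any(unknown)) {
    stopf("unparseable genotype call '%s' at record %d",
          core[which(unknown)[1]], which(unknown)[1] %% nrow(core))
  }
  # markers x samples -> lines x markers
  genotype_matrix(t(dose), colnames(gt), ids)
}

#' Write a genotype matrix
#'
#' `write_genotype_tsv()` writes the lines x markers dosage TSV consumed by
#' [read_genotype_matrix()]; `write_genotype_vcf()` writes a minimal biallelic
#' VCF (markers on chromosome "1" at consecutive positions, alleles A/T).
#'
#' @param G A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(G, path) {
  df <- as.data.frame(G$calls)
  df <- cbind(line_id = G$line_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
write_genotype_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$line_ids), collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_along(G$marker_ids)) {
    col <- G$calls[, j]
    gt <- ifelse(is.na(col), "./.", gt_map[col + 1L])
    writeLines(paste(c("1", j, G$marker_ids[j], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
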