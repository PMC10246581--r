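MS_BANDS <- c("blue", "green", "red", "rededge", "nir")
CHANNEL_TAGS <- c("multispectral", "thermal", "dem")
ALL_SOURCES <- c(CHANNEL_TAGS, "genotype")

#' Construct one image instance
#'
#' One multi-channel pixel array with its channel tag and acquisition date:
#' a single instance of a plot's bag. Multispectral instances carry 5 bands
#' in the fixed order blue, green, red, rededge, nir; thermal and dem carry
#' a single band.
#'
#' @param channel One of `"multispectral"`, `"thermal"`, `"dem"`.
#' @param date Acquisition date (coerced with `as.Date`).
#' @param pixels Numeric array `height x width x bands` of finite values.
#' @return An object of class `image_instance`.
#' @export
image_instance <- function(channel, date, pixels) {
  channel <- match.arg(channel, CHANNEL_TAGS)
  date <- as.Date(date)
  if (is.na(date)) stopf("unparseable acquisition date")
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  if (length(dim(pixels)) != 3) stopf("pixels must be a height x width x bands array")
  nb <- dim(pixels)[3]
  expected <- if (channel == "multispectral") 5L else 1L
  if (nb != expected) {
    stopf("%s instances must have %d band(s), got %d", channel, expected, nb)
  }
  if (!all(is.finite(pixels))) stopf("pixel values must be finite")
  structure(list(channel = channel, date = date, pixels = pixels),
            class = "image_instance")
}

#' @export
print.image_instance <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_instance: %s %s, %dx%d px, %d band(s)\n",
              x$channel, format(x$date), d[1], d[2], d[3]))
  invisible(x)
}

#' Construct one plot sample
#'
#' A plot's bags of image instances (one list per channel), the line's
#' genotype dosage vector, its yield (which may be `NA` at prediction time)
#' and identifiers. Any channel may be empty and the genotype may be absent;
#' the model handles variable and missing data sources.
#'
#' @param plot_id,entry_id,trial_id Identifiers.
#' @param yield Plot yield in t/ha, or `NA`.
#' @param bags Named list with elements among `multispectral`, `thermal`,
#'   `dem`, each a (possibly empty) list of [image_instance()] objects.
#' @param genotype Named numeric dosage vector for the entry, or `NULL`.
#' @return An object of class `plot_sample`.
#' @export
plot_sample <- function(plot_id, entry_id, trial_id, yield = NA_real_,
                        bags = list(), genotype = NULL) {
  full <- list(multispectral = list(), thermal = list(), dem = list())
  for (ch in names(bags)) {
    ch2 <- match.arg(ch, CHANNEL_TAGS)
    for (inst in bags[[ch]]) {
      if (!inherits(inst, "image_instance")) stopf("bags must contain image_instance objects")
      if (inst$channel != ch2) stopf("instance channel %s filed under bag %s",
                                     inst$channel, ch2)
    }
    full[[ch2]] <- bags[[ch]]
  }
  structure(list(plot_id = as.character(plot_id),
                 entry_id = as.character(entry_id),
                 trial_id = as.character(trial_id),
                 yield = as.numeric(yield),
                 bags = full,
                 genotype = genotype),
            class = "plot_sample")
}

#' @export
print.plot_sample <- function(x, ...) {
  cat(sprintf("plot_sample %s (entry %s, trial %s): yield %s; MS %d, TH %d, DEM %d images; genotype %s\n",
              x$plot_id, x$entry_id, x$trial_id,
              ifelse(is.na(x$yield), "NA", sprintf("%.2f t/ha", x$yield)),
              length(x$bags$multispectral), length(x$bags$thermal),
              length(x$bags$dem),
              if (is.null(x$genotype)) "absent" else sprintf("%d markers", length(x$genotype))))
  invisible(x)
}

#' Read a phenotype table
#'
#' CSV with required columns `plot_id`, `entry_id`, `trial_id`, `yield`
#' (t/ha).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "entry_id", "trial_id", "yield")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("phenotype table %s lacks required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  df$plot_id <- as.character(df$plot_id)
  df$entry_id <- as.character(df$entry_id)
  df$trial_id <- as.character(df$trial_id)
  df$yield <- as.numeric(df$yield)
  df
}

read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' Load a dataset from a manifest
#'
#' Reads the manifest written by [generate_dataset()] (or an equivalent
#' hand-built one), parses every referenced image, attaches genotypes by
#' entry id when a genotype matrix is supplied, and assembles one
#' [plot_sample()] per plot. Missing genotype calls are mean-imputed before
#' attachment. An entry without a genotype triggers a warning and a
#' genotype-absent sample; a dangling image path is an error naming the plot.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param genotype_path Optional path to the dosage TSV (or a
#'   [genotype_matrix()] directly).
#' @return A named list of `plot_sample` objects.
#' @export
load_dataset <- function(manifest_path, genotype_path = NULL) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  root <- dirname(manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  X <- NULL
  if (!is.null(genotype_path)) {
    G <- if (inherits(genotype_path, "genotype_matrix")) genotype_path
         else read_genotype_matrix(genotype_path, "tsv")
    X <- impute_dosage(G)
  }
  samples <- vector("list", length(manifest))
  names(samples) <- names(manifest)
  for (pid in names(manifest)) {
    entry <- manifest[[pid]]
    bags <- list()
    for (ch in intersect(names(entry$channels), CHANNEL_TAGS)) {
      insts <- list()
      for (item in entry$channels[[ch]]) {
        img_path <- file.path(root, item$path)
        if (!file.exists(img_path)) {
          stopf("plot %s references a missing image: %s", pid, item$path)
        }
        insts[[length(insts) + 1]] <-
          image_instance(ch, item$date, read_image_tiff(img_path))
      }
      bags[[ch]] <- insts
    }
    genotype <- NULL
    if (!is.null(X)) {
      if (entry$entry_id %in% rownames(X)) {
        genotype <- X[entry$entry_id, ]
      } else {
        warnf("entry %s (plot %s) has no genotype; sample flagged genotype-absent",
              entry$entry_id, pid)
      }
    }
    samples[[pid]] <- plot_sample(pid, entry$entry_id, entry$trial_id,
                                  entry$yield %||% NA_real_, bags, genotype)
  }
  samples
}
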