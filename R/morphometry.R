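#' Binarize a grayscale micrograph into tissue and airspace
#'
#' Default is a global Otsu threshold; pixels darker than the threshold are
#' tissue (hematoxylin convention: tissue dark, airspace light). The IsoData
#' iterated intermeans threshold (the default auto-threshold of common image
#' software) is available as a robustness check, as is a plain mean-gray
#' threshold (which is biased on images whose tissue fraction is far from
#' one half and is provided for comparison only). For light-tissue inputs set
#' `dark_is_tissue = FALSE`, which inverts the image before thresholding and
#' yields the identical mask for an inverted-polarity copy.
#'
#' @param image a `histology_image` or a numeric matrix (gray levels in
#'   0-255 or 0-1).
#' @param method `"otsu"` (default), `"isodata"` or `"mean"`.
#' @param dark_is_tissue logical; default `TRUE`.
#' @return A logical matrix (`TRUE` = tissue) with attribute `threshold` (gray
#'   level on the 0-255 scale of the possibly inverted image).
#' @export
binarize <- function(image, method = c("otsu", "isodata", "mean"),
                     dark_is_tissue = TRUE) {
  method <- match.arg(method)
  m <- if (inherits(image, "histology_image")) image$pixels else image
  stopifnot(is.matrix(m), is.numeric(m))
  m <- m / if (max(m) > 1) 255 else 1
  if (!dark_is_tissue) m <- 1 - m
  if (diff(range(m)) < 1e-12)
    abort_lungfot("constant image: no threshold separates tissue from airspace",
                  "lungfot_morphometry_error")
  thr <- switch(method,
    otsu = EBImage::otsu(m, range = c(0, 1), levels = 256),
    isodata = {
      t0 <- mean(m)
      for (i in 1:100) {
        t1 <- (mean(m[m < t0]) + mean(m[m >= t0])) / 2
        if (abs(t1 - t0) < 1e-6) break
        t0 <- t1
      }
      t0
    },
    mean = mean(m))
  mask <- m < thr
  attr(mask, "threshold") <- thr * 255
  mask
}

#' Sample square measurement regions
#'
#' Axis-aligned square regions at uniform random positions (overlap allowed),
#' deterministic given the seed; mirrors the practice of photographing at
#' least 15 regions per animal. A deterministic `"grid"` mode tiling the image
#' as evenly as possible is available when full coverage matters more than
#' random sampling.
#'
#' @param dim_px image dimensions, `c(nrow, ncol)`, or a `histology_image`.
#' @param n number of regions (default 15).
#' @param size_px region side length in pixels (default 256).
#' @param seed integer seed (random mode only).
#' @param mode `"random"` (default) or `"grid"`.
#' @return A data frame with columns `row0`, `col0` (1-based top-left corner)
#'   and `size_px`; all regions lie fully inside the image.
#' @export
sample_regions <- function(dim_px, n = 15, size_px = 256, seed = 1,
                           mode = c("random", "grid")) {
  mode <- match.arg(mode)
  if (inherits(dim_px, "histology_image")) dim_px <- dim(dim_px$pixels)
  stopifnot(n >= 1, length(dim_px) == 2)
  if (size_px > min(dim_px))
    abort_lungfot("region size exceeds image dimensions",
                  "lungfot_morphometry_error")
  if (mode == "grid") {
    k <- ceiling(sqrt(n))
    pos <- function(extent) unique(round(seq(1, extent - size_px + 1,
                                             length.out = k)))
    g <- expand.grid(row0 = pos(dim_px[1]), col0 = pos(dim_px[2]))
    return(data.frame(g[seq_len(min(n, nrow(g))), ], size_px = size_px,
                      row.names = NULL))
  }
  set.seed(seed)
  data.frame(
    row0 = sample.int(dim_px[1] - size_px + 1L, n, replace = TRUE),
    col0 = sample.int(dim_px[2] - size_px + 1L, n, replace = TRUE),
    size_px = size_px)
}

#' Tissue fraction over sampled regions
#'
#' Per-region tissue fraction is the ratio of tissue (black) pixels to total
#' pixels in the region; per-animal summaries are the mean and sample SD of
#' the region fractions, in percent.
#'
#' @param mask logical tissue mask from [binarize()].
#' @param regions region data frame from [sample_regions()].
#' @param animal_id optional identifier carried into the result.
#' @return An object of class `tf_result`: list with `region_tfs` (fractions
#'   in 0-1), `tf_mean` and `tf_sd` (percent), `n_regions`, `threshold_used`,
#'   `region_size_px`, `animal_id`.
#' @export
tissue_fraction <- function(mask, regions, animal_id = NA_character_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (nrow(regions) == 0)
    abort_lungfot("empty region list", "lungfot_morphometry_error")
  tfs <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    mean(mask[r$row0:(r$row0 + r$size_px - 1L),
              r$col0:(r$col0 + r$size_px - 1L)])
  }, 0)
  structure(list(region_tfs = tfs,
                 tf_mean = 100 * mean(tfs),
                 tf_sd = 100 * stats::sd(tfs),
                 n_regions = length(tfs),
                 threshold_used = attr(mask, "threshold"),
                 region_size_px = regions$size_px[1],
                 animal_id = animal_id),
            class = "tf_result")
}

#' Measure tissue fraction for one animal
#'
#' Binarizes each of the animal's images and pools region measurements across
#' them (regions are split as evenly as possible over the images).
#'
#' @param images a single `histology_image` or a list of them.
#' @param n_regions total regions per animal (default 15).
#' @param size_px region side length (default 256).
#' @param seed integer seed for region placement.
#' @param method threshold method, see [binarize()].
#' @param animal_id optional identifier.
#' @return A `tf_result` pooled over all the animal's images.
#' @export
measure_tf <- function(images, n_regions = 15, size_px = 256, seed = 1,
                       method = "otsu", animal_id = NA_character_) {
  if (inherits(images, "histology_image")) images <- list(images)
  k <- length(images)
  per <- diff(round(seq(0, n_regions, length.out = k + 1)))
  tfs <- numeric(0); thr <- numeric(0)
  for (i in seq_len(k)) {
    if (per[i] == 0) next
    mask <- binarize(images[[i]], method = method)
    reg <- sample_regions(dim(mask), n = per[i], size_px = size_px,
                          seed = child_seed(seed, i))
    res <- tissue_fraction(mask, reg)
    tfs <- c(tfs, res$region_tfs); thr <- c(thr, res$threshold_used)
  }
  structure(list(region_tfs = tfs,
                 tf_mean = 100 * mean(tfs),
                 tf_sd = 100 * stats::sd(tfs),
                 n_regions = length(tfs),
                 threshold_used = mean(thr),
                 region_size_px = size_px,
                 animal_id = animal_id),
            class = "tf_result")
}

#' Tissue-fraction table for a synthetic histology cohort
#'
#' Generates `n` animals per requested grade and measures each with the
#' morphometry pipeline; one row per animal.
#'
#' @param grades named integer vector: animals per grade label, e.g.
#'   `c(A0_iso = 6, A1 = 4, A2 = 7, A3 = 6)`.
#' @param preset a `grade_presets` object.
#' @param seed master integer seed.
#' @param n_regions,size_px,method passed to [measure_tf()].
#' @return A data frame with columns `animal_id`, `grade`, `grade_num`,
#'   `tf_truth` (percent), `tf_mean`, `tf_sd` (percent), `n_regions`,
#'   `threshold`.
#' @export
tf_cohort_table <- function(grades, preset = default_presets(), seed = 1,
                            n_regions = 15, size_px = 256, method = "otsu") {
  rows <- list(); a <- 0L
  for (g in names(grades)) {
    for (k in seq_len(grades[[g]])) {
      a <- a + 1L
      id <- sprintf("%s_h%02d", g, k)
      img <- generate_histology(preset, g, seed = child_seed(seed, a))
      res <- measure_tf(img, n_regions = n_regions, size_px = size_px,
                        seed = child_seed(seed, 10000L + a), method = method,
                        animal_id = id)
      rows[[a]] <- data.frame(
        animal_id = id, grade = g, grade_num = grade_number(g),
        tf_truth = 100 * img$tf_truth, tf_mean = res$tf_mean,
        tf_sd = res$tf_sd, n_regions = res$n_regions,
        threshold = res$threshold_used, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
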