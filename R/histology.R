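#' Generate a synthetic lung micrograph with known tissue fraction
#'
#' Renders a morphological cartoon of an H&E lung section: an alveolar wall
#' network (Voronoi tessellation of random points), vessel/bronchiole rings
#' with open lumina, perivascular infiltrate annuli whose number and width
#' grow with rejection grade, and (for A3) generalized septal thickening via a
#' thicker wall base width. An internal bisection loop scales wall and annulus
#' widths jointly until the rendered tissue fraction is within `tol` of the
#' target, records the achieved fraction as `tf_truth`, then converts to
#' grayscale (tissue dark, airspace light), blurs (Gaussian sigma 1 px) and
#' adds pixel noise (sigma 8 gray levels).
#'
#' Per-animal targets default to a draw from the grade's tissue-fraction
#' distribution, truncated to (0.05, 0.95).
#'
#' @param preset a `grade_presets` object (uses its `histology` section).
#' @param grade grade label.
#' @param seed integer seed; images are bit-reproducible given the seed.
#' @param target_tf optional explicit target tissue fraction in (0,1).
#' @param size_px image side length (default from preset, 1024).
#' @param tol calibration tolerance on the rendered fraction (default 0.005).
#' @param max_iter calibration iteration cap (default 50).
#' @return An object of class `histology_image`: list with `pixels` (integer
#'   matrix, 0-255, 8-bit grayscale), `pixel_size_um`, `tf_truth` (realized
#'   pre-noise tissue fraction), `target_tf`, `grade_label`, `seed`.
#' @export
generate_histology <- function(preset, grade, seed, target_tf = NULL,
                               size_px = NULL, tol = 0.005, max_iter = 50) {
  stopifnot(inherits(preset, "grade_presets"))
  if (!grade %in% grade_levels())
    abort_lungfot(sprintf("unknown grade label '%s'", grade),
                  "lungfot_preset_error")
  hp <- preset$histology
  hg <- hp$grades[[grade]]
  S <- if (is.null(size_px)) hp$size_px else size_px
  set.seed(seed)
  if (is.null(target_tf)) {
    gp <- preset$grades[[grade]]
    target_tf <- rtruncnorm(1, gp$tf$mean, gp$tf$sd, 0.05, 0.95)
  }
  if (target_tf <= 0 || target_tf >= 1)
    abort_lungfot("target tissue fraction must lie strictly inside (0, 1)",
                  "lungfot_histology_error")

  xs <- seq_len(S); ys <- seq_len(S)
  px <- rep(xs, times = S)          # column index of each pixel
  py <- rep(ys, each = S)           # row index (column-major over matrix)

  # alveolar wall field: difference of distances to the two nearest points;
  # thresholding it at w gives a wall network of thickness ~w. Points are
  # drawn in a buffered frame around the canvas so border cells have the same
  # size statistics as interior ones (the tissue field is stationary, which
  # keeps uniform region sampling unbiased).
  pad <- 150
  npts <- round(hp$n_wall_points * ((S + 2 * pad) / S)^2)
  cx <- stats::runif(npts, 1 - pad, S + pad)
  cy <- stats::runif(npts, 1 - pad, S + pad)
  # Updates are confined to a window around each point: with 260 points on a
  # 1024^2 field the two nearest points are always far closer than 256 px, so
  # the window never changes the result, only the cost.
  R_loc <- 256L
  D1 <- matrix(Inf, S, S); D2 <- D1
  for (i in seq_len(npts)) {
    xr <- max(1L, as.integer(cx[i]) - R_loc):min(S, as.integer(cx[i]) + R_loc)
    yr <- max(1L, as.integer(cy[i]) - R_loc):min(S, as.integer(cy[i]) + R_loc)
    d <- outer((xr - cx[i])^2, (yr - cy[i])^2, "+")
    sub1 <- D1[xr, yr]
    D2[xr, yr] <- pmin(D2[xr, yr], pmax(d, sub1))  # second-nearest update
    D1[xr, yr] <- pmin(sub1, d)
  }
  wallfield <- as.numeric(sqrt(D2) - sqrt(D1))

  # vessels: ring walls, open lumina, and (for the first n_infiltrates)
  # perivascular infiltrate annuli of grade-dependent width
  nv <- hg$n_vessels
  vx <- stats::runif(nv, 1, S); vy <- stats::runif(nv, 1, S)
  vr <- stats::runif(nv, 12, 35)
  au <- stats::runif(nv, 0.6, 1.4)   # per-vessel annulus width multiplier
  ring_w <- hp$vessel_ring_px
  ring <- lumen <- rep(FALSE, S * S)
  dvi <- vector("list", nv)  # distance fields, kept only for infiltrate vessels
  for (j in seq_len(nv)) {
    dv <- sqrt((px - vx[j])^2 + (py - vy[j])^2)
    ring <- ring | (dv >= vr[j] - ring_w & dv < vr[j])
    lumen <- lumen | (dv < vr[j] - ring_w)
    if (j <= hg$n_infiltrates) dvi[[j]] <- dv - vr[j]  # radial excess
  }

  render <- function(s) {
    tissue <- wallfield < hg$wall_px * s
    for (j in seq_len(hg$n_infiltrates))
      tissue <- tissue | (dvi[[j]] >= 0 & dvi[[j]] < hg$annulus_px * s * au[j])
    (tissue | ring) & !lumen
  }

  lo <- 0.01; hi <- 1
  while (mean(render(hi)) < target_tf && hi < 64) hi <- hi * 2
  frac <- NA_real_; s_mid <- NA_real_; mask <- NULL
  for (it in seq_len(max_iter)) {
    s_mid <- (lo + hi) / 2
    mask <- render(s_mid)
    frac <- mean(mask)
    if (abs(frac - target_tf) <= tol) break
    if (frac < target_tf) lo <- s_mid else hi <- s_mid
  }
  if (abs(frac - target_tf) > tol)
    abort_lungfot(sprintf(
      "tissue-fraction calibration did not converge: achieved %.4f, target %.4f",
      frac, target_tf), "lungfot_histology_error")

  g <- matrix(ifelse(mask, hp$gray_tissue, hp$gray_air), S, S)
  g <- EBImage::gblur(g, sigma = hp$blur_sigma)
  g <- g + stats::rnorm(S * S, 0, hp$noise_sd)
  pixels <- matrix(as.integer(pmin(pmax(round(g), 0), 255)), S, S)

  structure(list(pixels = pixels, pixel_size_um = hp$pixel_size_um,
                 tf_truth = frac, target_tf = target_tf,
                 grade_label = grade, seed = seed),
            class = "histology_image")
}

#' Write / read a histology image with its metadata sidecar
#'
#' Images are written losslessly as 8-bit grayscale PNG or TIFF; the ground
#' truth tissue fraction and generator metadata travel in a JSON sidecar
#' (`<path>.json`). Reading an image without a sidecar yields `tf_truth = NA`
#' (unknown). TIFF inputs with more than 8 bits per sample are rescaled to
#' 8 bits with a warning.
#'
#' @param image a `histology_image`.
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return `write_image` returns `path` invisibly; `read_image` returns a
#'   `histology_image`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "histology_image"))
  ext <- tolower(tools::file_ext(path))
  m <- image$pixels / 255
  if (ext == "png") png::writePNG(m, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path, bits.per.sample = 8L)
  else abort_lungfot("only lossless PNG or TIFF output is supported",
                     "lungfot_histology_error")
  jsonlite::write_json(
    list(tf_truth = image$tf_truth, target_tf = image$target_tf,
         grade_label = image$grade_label, seed = image$seed,
         pixel_size_um = image$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(m, "bits.per.sample")
    if (!is.null(bits) && bits > 8)
      warning("TIFF has more than 8 bits per sample; rescaling to 8-bit")
  } else abort_lungfot("only PNG or TIFF input is supported",
                       "lungfot_histology_error")
  if (length(dim(m)) == 3) m <- m[, , 1]   # grayscale stored with channels
  pixels <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(tf_truth = NA_real_, target_tf = NA_real_,
                    grade_label = NA_character_, seed = NA_integer_,
                    pixel_size_um = NA_real_)
  structure(list(pixels = pixels, pixel_size_um = meta$pixel_size_um,
                 tf_truth = meta$tf_truth, target_tf = meta$target_tf,
                 grade_label = meta$grade_label, seed = meta$seed),
            class = "histology_image")
}
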