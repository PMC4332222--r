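#' Configuration for an end-to-end pipeline run
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param design cohort design, see [default_design()].
#' @param preset grade presets, see [default_presets()].
#' @param protocol forcing protocol, see [build_protocol()].
#' @param n_regions,region_size_px morphometry settings.
#' @param write_images write the synthetic micrographs as PNG (default
#'   `FALSE`: the tissue-fraction table is always written, the pixel data are
#'   bulky and reproducible from the seed).
#' @param make_plots render summary figures (PNG) of the index-vs-PEEP,
#'   TF-vs-E_low and grade-vs-E_het relations (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, design = default_design(),
                       preset = default_presets(),
                       protocol = build_protocol(),
                       n_regions = 15, region_size_px = 256,
                       write_images = FALSE, make_plots = TRUE) {
  structure(list(seed = seed, design = design, preset = preset,
                 protocol = protocol, n_regions = n_regions,
                 region_size_px = region_size_px,
                 write_images = write_images, make_plots = make_plots),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates the cohort, estimates impedance, extracts indices, generates and
#' measures histology, runs the statistical analyses, and writes everything to
#' `out_dir`: `protocol.json`, `animals.csv`, `indices.csv`, `tf.csv`,
#' `stats.json`, optional figures, and a `manifest.json` recording the seed
#' and output inventory. A directory containing partial output but no manifest
#' is refused unless `force = TRUE`. Re-running with the same config and seed
#' reproduces the outputs exactly.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if missing).
#' @param force overwrite a directory with partial previous output.
#' @return The path `out_dir`, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config = run_config(), out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir)) {
    has_files <- length(list.files(out_dir)) > 0
    if (has_files && !file.exists(file.path(out_dir, "manifest.json")) && !force)
      abort_lungfot("output directory has partial content and no manifest; use force = TRUE",
                    "lungfot_pipeline_error")
  } else dir.create(out_dir, recursive = TRUE)

  write_protocol(config$protocol, file.path(out_dir, "protocol.json"))

  cohort <- generate_cohort(config$design, config$preset, seed = config$seed,
                            protocol = config$protocol)
  utils::write.csv(cohort$animals, file.path(out_dir, "animals.csv"),
                   row.names = FALSE)

  idx <- index_table(cohort)
  utils::write.csv(idx, file.path(out_dir, "indices.csv"), row.names = FALSE)

  grades <- stats::setNames(cohort$design$groups$n, cohort$design$groups$grade)
  tf <- tf_cohort_table(grades, config$preset, seed = child_seed(config$seed, 777L),
                        n_regions = config$n_regions,
                        size_px = config$region_size_px)
  utils::write.csv(tf, file.path(out_dir, "tf.csv"), row.names = FALSE)
  if (config$write_images) {
    img_dir <- file.path(out_dir, "images"); dir.create(img_dir, showWarnings = FALSE)
    a <- 0L
    for (g in names(grades)) for (k in seq_len(grades[[g]])) {
      a <- a + 1L
      img <- generate_histology(config$preset, g, seed = child_seed(child_seed(config$seed, 777L), a))
      write_image(img, file.path(img_dir, sprintf("%s_h%02d.png", g, k)))
    }
  }

  # statistics at PEEP 4: TF vs log10(E_low), grade vs E_het, plus the
  # grade x PEEP comparison of E_low
  idx4 <- idx[idx$peep_cmH2O == 4, ]
  idx4 <- idx4[order(idx4$animal_id), ]
  tfo <- tf[order(tf$animal_id), ]
  # animals are generated in the same grade blocks in both tables
  stopifnot(nrow(idx4) == nrow(tfo))
  tf_elow <- correlate(tfo$tf_mean, idx4$E_low, log_y = TRUE)
  tfsd_ehet <- correlate(tfo$tf_sd, idx4$E_het, log_y = TRUE)
  grade_ehet <- grade_correlation(idx4)
  idx$peep_f <- factor(idx$peep_cmH2O)
  anova_gp <- tryCatch(
    compare_groups(idx, "E_low", c("grade", "peep_f"), block = "animal_id"),
    error = function(e) NULL)

  stats_out <- list(
    tf_vs_Elow = list(r2 = tf_elow$r2, r = tf_elow$r, n = tf_elow$n),
    sdTF_vs_Ehet = list(r2 = tfsd_ehet$r2, r = tfsd_ehet$r, n = tfsd_ehet$n),
    grade_vs_Ehet = list(r = grade_ehet$r, r_s = grade_ehet$r_s,
                         p_spearman = grade_ehet$p_spearman),
    anova_E_low = if (is.null(anova_gp)) "not estimable at this design size"
                  else anova_gp$anova_table)
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  if (config$make_plots) render_report_figures(idx, tfo, out_dir)

  manifest <- list(
    package = "lungfot",
    version = as.character(utils::packageVersion("lungfot")),
    seed = config$seed,
    n_animals = nrow(cohort$animals),
    n_records = length(cohort$records),
    n_tf_rows = nrow(tf),
    files = sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Summary figures: median index vs PEEP per grade; TF vs E_low (log scale);
# grade vs E_het (log scale).
render_report_figures <- function(idx, tf, out_dir) {
  grDevices::png(file.path(out_dir, "fig_indices_vs_peep.png"),
                 width = 1200, height = 400)
  graphics::par(mfrow = c(1, 3))
  for (v in c("R_high", "E_low", "E_het")) {
    med <- stats::aggregate(idx[[v]], list(grade = idx$grade, peep = idx$peep_cmH2O),
                            stats::median)
    graphics::plot(range(med$peep), range(med$x), type = "n",
                   xlab = "PEEP (cmH2O)", ylab = v, log = "y",
                   main = paste(v, "vs PEEP (group medians)"))
    grades <- unique(med$grade)
    for (i in seq_along(grades)) {
      m <- med[med$grade == grades[i], ]
      graphics::lines(m$peep, m$x, col = i, type = "b", pch = 19)
    }
    graphics::legend("topright", legend = grades, col = seq_along(grades),
                     lty = 1, pch = 19, cex = 0.8)
  }
  grDevices::dev.off()

  idx4 <- idx[idx$peep_cmH2O == 4, ]
  idx4 <- idx4[order(idx4$animal_id), ]
  grDevices::png(file.path(out_dir, "fig_tf_grade_relations.png"),
                 width = 800, height = 400)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(tf$tf_mean, idx4$E_low, log = "y", pch = 19,
                 xlab = "TF (%)", ylab = "E_low (cmH2O/mL, log scale)",
                 main = "TF vs E_low at PEEP 4")
  graphics::plot(idx4$grade_num, idx4$E_het, log = "y", pch = 19,
                 xlab = "A-grade (ordinal)", ylab = "E_het (cmH2O/mL, log scale)",
                 main = "Grade vs E_het at PEEP 4")
  grDevices::dev.off()
  invisible(NULL)
}
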