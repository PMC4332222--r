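test_that("binarization recovers a two-level image exactly and handles polarity", {
  set.seed(1)
  truth <- matrix(runif(200 * 200) < 0.3, 200, 200)
  img <- matrix(ifelse(truth, 40, 220), 200, 200)
  mask <- binarize(img)
  expect_equal(mask, truth, ignore_attr = TRUE)
  expect_true(attr(mask, "threshold") > 40 && attr(mask, "threshold") < 220)
  inv <- binarize(255 - img, dark_is_tissue = FALSE)
  expect_equal(inv, truth, ignore_attr = TRUE)
  expect_error(binarize(matrix(7, 10, 10)), class = "lungfot_morphometry_error")
})

test_that("binarized synthetic images recover the generator truth", {
  p <- default_presets(); p$histology$size_px <- 512
  img <- generate_histology(p, "A2", seed = 17)
  mask <- binarize(img)
  expect_lt(abs(mean(mask) - img$tf_truth), 0.02)
  # threshold robustness: Otsu vs IsoData intermeans changes TF by < 0.01
  expect_lt(abs(mean(binarize(img, method = "isodata")) - mean(mask)), 0.01)
})

test_that("grid-mode regions tile the image deterministically", {
  g <- sample_regions(c(1024, 1024), n = 16, size_px = 256, mode = "grid")
  expect_equal(nrow(g), 16)
  expect_true(all(g$row0 >= 1 & g$row0 + g$size_px - 1 <= 1024))
  expect_identical(g, sample_regions(c(1024, 1024), n = 16, size_px = 256,
                                     mode = "grid"))
  # 16 regions of 256 px tile a 1024 px canvas exactly
  expect_setequal(g$row0, c(1, 257, 513, 769))
})

test_that("region sampling is reproducible and respects bounds", {
  r <- sample_regions(c(1024, 1024), n = 15, size_px = 256, seed = 4)
  expect_equal(nrow(r), 15)
  expect_true(all(r$row0 >= 1 & r$row0 + r$size_px - 1 <= 1024))
  expect_true(all(r$col0 >= 1 & r$col0 + r$size_px - 1 <= 1024))
  expect_identical(r, sample_regions(c(1024, 1024), n = 15, size_px = 256, seed = 4))
  expect_error(sample_regions(c(100, 100), size_px = 256),
               class = "lungfot_morphometry_error")
  full <- sample_regions(c(300, 300), n = 1, size_px = 300, seed = 1)
  expect_equal(c(full$row0, full$col0), c(1, 1))
})

test_that("tissue fraction obeys exact closed forms on constructed masks", {
  all_tissue <- matrix(TRUE, 64, 64)
  r <- data.frame(row0 = 1, col0 = 1, size_px = 64)
  expect_equal(tissue_fraction(all_tissue, r)$region_tfs, 1.0)
  checker <- outer(1:64, 1:64, function(i, j) (i + j) %% 2 == 0)
  rs <- sample_regions(c(64, 64), n = 5, size_px = 32, seed = 2)
  res <- tissue_fraction(checker, rs)
  expect_equal(res$region_tfs, rep(0.5, 5))
  expect_equal(res$tf_mean, 50)
  expect_equal(res$tf_sd, 0)
  expect_error(tissue_fraction(checker, rs[0, ]),
               class = "lungfot_morphometry_error")
})

test_that("tissue fraction is invariant to rotation and mirroring", {
  p <- default_presets(); p$histology$size_px <- 512
  img <- generate_histology(p, "A1", seed = 19)
  mask <- binarize(img)
  regions <- sample_regions(dim(mask), n = 10, size_px = 128, seed = 6)
  tf0 <- tissue_fraction(mask, regions)$region_tfs
  # 90-degree rotation: (r, c) -> (c, N + 1 - r); transform the same regions
  rot <- t(mask[nrow(mask):1, ])
  attr(rot, "threshold") <- attr(mask, "threshold")
  reg_rot <- data.frame(row0 = regions$col0,
                        col0 = nrow(mask) + 1 - (regions$row0 + regions$size_px - 1),
                        size_px = regions$size_px)
  expect_equal(sort(tissue_fraction(rot, reg_rot)$region_tfs), sort(tf0),
               tolerance = 1e-12)
  mir <- mask[, ncol(mask):1]
  attr(mir, "threshold") <- attr(mask, "threshold")
  reg_mir <- data.frame(row0 = regions$row0,
                        col0 = ncol(mask) + 1 - (regions$col0 + regions$size_px - 1),
                        size_px = regions$size_px)
  expect_equal(sort(tissue_fraction(mir, reg_mir)$region_tfs), sort(tf0),
               tolerance = 1e-12)
})

test_that("per-animal measurement pools regions across images and recovers truth", {
  p <- default_presets(); p$histology$size_px <- 512
  imgs <- lapply(c(41, 42), function(s)
    generate_histology(p, "A3", seed = s, target_tf = 0.621))
  res <- measure_tf(imgs, n_regions = 16, size_px = 128, seed = 9, animal_id = "a3_01")
  expect_equal(res$n_regions, 16)
  truth <- 100 * mean(sapply(imgs, `[[`, "tf_truth"))
  expect_lt(abs(res$tf_mean - truth), 2)   # within 2 percentage points
  expect_equal(res$animal_id, "a3_01")
})

test_that("cohort recovery at default settings: per-animal errors bounded", {
  # default canvas (1024 px) and regions (15 x 256 px): region-sampling SE is
  # ~1-1.5 pp, so individual animals stay within ~2 pp of generator truth
  tab <- tf_cohort_table(c(A0_iso = 1, A1 = 1, A2 = 1, A3 = 1), seed = 5)
  err <- abs(tab$tf_mean - tab$tf_truth)
  expect_true(all(err < 2))
  expect_true(all(diff(tapply(tab$tf_truth, tab$grade_num, mean)) > 0))
})
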