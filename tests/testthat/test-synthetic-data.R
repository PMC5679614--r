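test_that("noiseless phantom signal equals the forward model voxel by voxel", {
  ph <- make_phantom(phantom_spec(seed = 31, snr = Inf, nav_amplitude = 0,
                                  b0_coef = c(const = 5, z = 2)))
  te <- echo_times(ph$image$acq)
  dz <- ph$image$acq$voxel_size[3]
  idx <- which(ph$image$brain_mask)[c(3, 77, 501, 900)]
  for (i in idx) {
    expected <- forward_signal(
      ph$truth$s0_map[i], ph$truth$r2t_star_map[i],
      zeta = ph$truth$zeta_map[i], delta_omega = ph$truth$delta_omega_map[i],
      g_through = ph$truth$g_through[i], slab_thickness = dz, te = te)
    mag_i <- matrix(ph$image$magnitude, nrow = prod(dim(ph$image$brain_mask)))[i, ]
    expect_equal(mag_i, expected, tolerance = 1e-12)
  }
})

test_that("phantom generation is bit-reproducible and requires a seed", {
  a <- make_phantom(phantom_spec(seed = 32))
  b <- make_phantom(phantom_spec(seed = 32))
  expect_identical(a$image$magnitude, b$image$magnitude)
  expect_identical(a$image$phase, b$image$phase)
  expect_identical(a$nav, b$nav)
  c <- make_phantom(phantom_spec(seed = 33))
  expect_false(identical(a$image$magnitude, c$image$magnitude))
  expect_error(phantom_spec(), "seed")
})

test_that("fluid and tissue classes separate cleanly after fitting at SNR 50", {
  regions <- data.frame(region_name = rep("hippocampus", 2),
                        hemisphere = c("left", "right"),
                        r2t_star = 17, stringsAsFactors = FALSE)
  ph <- make_phantom(phantom_spec(seed = 34, snr = 50, regions = regions))
  img <- navigator_correct(ph$image, ph$nav)
  qm <- fit_volume(img, estimate_field(img), fit_options())
  csf_id <- ph$label_map$label_table$label_id[
    ph$label_map$label_table$region_name == "csf"]
  csf_med <- region_median(qm$r2t_star_map, ph$label_map, csf_id,
                           qm$quality_mask)$median
  tis_ids <- setdiff(ph$label_map$label_table$label_id, csf_id)
  tis_med <- stats::median(unlist(lapply(tis_ids, function(id)
    region_median(qm$r2t_star_map, ph$label_map, id, qm$quality_mask)$median)))
  expect_lt(csf_med, 5)
  expect_gt(tis_med, 14)
  expect_gt(tis_med - csf_med, 10)
})

test_that("cohort generation is reproducible and matches the designed composition", {
  spec <- cohort_spec(seed = 41)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$summaries, b$summaries)

  co <- a$cohort
  expect_equal(unname(table(co$group)[c("HC", "RRMS", "SPMS", "PPMS")]),
               c(31L, 32L, 32L, 16L), ignore_attr = TRUE)
  expect_equal(sum(co$gender == "F" & co$group == "HC"), 21)
  expect_equal(sum(co$handedness == "right" & co$group != "HC"), 73)
  expect_true(all(is.na(co$lesion_load[co$group == "HC"])))
  expect_true(all(co$lesion_load[co$group != "HC"] > 0))
  # clinical scores exist only for patients
  expect_true(all(is.na(co$EDSS[co$group == "HC"])))
  expect_true(all(!is.na(co$SDMT[co$group != "HC"])))
  expect_true(all(co$EDSS[co$group != "HC"] >= 0 &
                  co$EDSS[co$group != "HC"] <= 10))
  expect_true(all(co$T25FW[co$group != "HC"] > 0))

  # one summary row per subject x region x hemisphere
  expect_equal(nrow(a$summaries), nrow(co) * 22)
})

test_that("cohort moments converge to designed values in a large cohort", {
  big <- make_cohort(cohort_spec(
    seed = 42,
    n_per_group = c(HC = 250L, SPMS = 250L),
    score_targets = NULL))
  sm <- big$summaries
  hc_ids <- big$cohort$subject_id[big$cohort$group == "HC"]
  cell <- sm[sm$region_name == "hippocampus" & sm$hemisphere == "left", ]
  # ages differ between groups, so compare age-adjusted means
  age <- big$cohort$age[match(cell$subject_id, big$cohort$subject_id)]
  is_hc <- cell$subject_id %in% hc_ids
  fit <- stats::lm(cell$median_r2t_star ~ is_hc + age)
  expect_equal(unname(coef(fit)["is_hcTRUE"]), 0.9, tolerance = 0.2)
  expect_equal(stats::sd(stats::residuals(fit)), 0.6, tolerance = 0.05)
})

test_that("null designed couplings produce centered partial correlations", {
  # target rho = 0 for every score: the empirical partial correlation of a
  # fixed cell across repeated cohorts must center at zero
  rs <- vapply(1:60, function(s) {
    cs <- make_cohort(cohort_spec(seed = 1000 + s, score_targets = NULL))
    sm <- cs$summaries
    ms <- cs$cohort[cs$cohort$group != "HC", ]
    cell <- sm[sm$region_name == "hippocampus" & sm$hemisphere == "left", ]
    x <- cell$median_r2t_star[match(ms$subject_id, cell$subject_id)]
    C <- cbind(ms$age, as.numeric(ms$gender == "M"), ms$lesion_load,
               ms$treatment)
    partial_pearson(x, ms$SDMT, C)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 / sqrt(60 * 74))  # ~2 SE of the null mean
  expect_lt(mean(abs(rs)), 3 * sqrt(1 / 74))
})

test_that("the end-to-end fixture writes a complete consumable study", {
  tdir <- withr::local_tempdir()
  fx <- make_end_to_end_fixture(
    tdir, seed = 51,
    cohort_args = list(n_per_group = c(HC = 4L, RRMS = 4L, SPMS = 4L)),
    region_set = c("hippocampus", "amygdala"))
  expect_true(file.exists(file.path(tdir, "cohort.tsv")))
  expect_true(file.exists(file.path(tdir, "labels.nii")))
  co <- read_tsv(file.path(tdir, "cohort.tsv"))
  expect_equal(nrow(co), 12)
  subj_files <- list.files(file.path(tdir, "subjects"))
  expect_equal(sum(grepl("_mag.nii$", subj_files)), 12)
  expect_equal(sum(grepl("_nav.tsv$", subj_files)), 12)

  # images round-trip and fit: one subject spot check against its truths
  sid <- co$subject_id[1]
  img <- read_multi_echo(file.path(tdir, "subjects", sid))
  expect_s3_class(img, "multi_echo_image")
  expect_equal(dim(img$magnitude), c(16, 16, 8, 10))
})
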