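# VOI quantification: organ activity, spillover correction, body volume,
# remainder-of-body activity.

test_that("organ activity is mean concentration times volume", {
  img <- uniform_image(1000)                 # 1000 Bq/mL, 1 mL voxels
  v <- cube_voi("pancreas")                  # 100 voxels = 100 mL
  expect_equal(as.numeric(organ_activity(img, v)), 0.1)   # MBq
  expect_identical(attr(organ_activity(img, v), "t_min"), 0)

  expect_equal(as.numeric(organ_activity(uniform_image(0), v)), 0)

  # brute-force voxel-sum oracle on a random image
  set.seed(42)
  g <- array(stats::runif(1000, 0, 5e4), c(10, 10, 10))
  img_r <- voxel_image(g, spacing_mm = c(3.18, 3.18, 3), t_min = 60)
  m <- array(FALSE, c(10, 10, 10)); m[2:7, 3:8, 2:9] <- TRUE
  v_r <- voi("kidneys", m, c(3.18, 3.18, 3))
  oracle <- sum(g[m]) * prod(c(3.18, 3.18, 3)) / 1000 / 1e6
  expect_equal(as.numeric(organ_activity(img_r, v_r)), oracle,
               tolerance = 1e-12)

  expect_error(voi("kidneys", array(FALSE, c(4, 4, 4))), "empty mask")
  expect_error(organ_activity(uniform_image(1, dim = c(4L, 4L, 4L)), v),
               "congruent")
})

test_that("organ activity is linear in intensity and additive over VOIs", {
  set.seed(7)
  g <- array(stats::runif(1000, 0, 1e4), c(10, 10, 10))
  img1 <- voxel_image(g); img3 <- voxel_image(3 * g)
  va <- cube_voi("pancreas", i = 1:4, spacing = c(3.18, 3.18, 3))
  vb <- cube_voi("liver", i = 6:9, spacing = c(3.18, 3.18, 3))
  img1 <- voxel_image(g, c(3.18, 3.18, 3))
  img3 <- voxel_image(3 * g, c(3.18, 3.18, 3))
  expect_equal(as.numeric(organ_activity(img3, va)),
               3 * as.numeric(organ_activity(img1, va)), tolerance = 1e-12)
  vab <- voi("spleen", va$mask | vb$mask, c(3.18, 3.18, 3))
  expect_equal(as.numeric(organ_activity(img1, vab)) * vab$volume_ml /
                 vab$volume_ml,
               as.numeric(organ_activity(img1, va)) +
                 as.numeric(organ_activity(img1, vb)), tolerance = 1e-12)
})

test_that("mask dilation works in physical millimetres", {
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  # 9 mm radius on 3x3x3 mm voxels: 3-voxel radius sphere
  d <- dilate_mask(m, c(3, 3, 3), 9)
  expect_true(d[6 + 3, 6, 6]); expect_true(d[6, 6, 6 - 3])
  expect_false(d[6 + 3, 6 + 3, 6])      # 12.7 mm away, outside
  expect_identical(dilate_mask(m, c(3, 3, 3), 0), m)
  # anisotropic spacing gives anisotropic voxel radii
  d2 <- dilate_mask(m, c(3, 3, 9), 9)
  expect_true(d2[6, 6, 6 + 1]); expect_false(d2[6, 6, 6 + 2])
})

test_that("spillover correction changes the mean, never the volume", {
  sp <- c(3.18, 3.18, 3)
  dimv <- c(20L, 20L, 12L)
  pan <- cube_voi("pancreas", dimv, i = 3:10, j = 8:12, k = 5:8, sp)
  kid <- cube_voi("left_kidney", dimv, i = 13:18, j = 8:12, k = 4:9, sp)

  # uniform pancreas concentration: imputing the clean mean is a no-op
  g <- array(0, dimv); g[pan$mask] <- 5000; g[kid$mask] <- 2e5
  img <- voxel_image(g, sp)
  expect_equal(as.numeric(spillover_correct_pancreas(img, pan, kid, 9)),
               as.numeric(organ_activity(img, pan)), tolerance = 1e-12)

  # zero dilation with disjoint masks: nothing excluded
  set.seed(1)
  g2 <- array(stats::runif(prod(dimv), 0, 1e4), dimv)
  img2 <- voxel_image(g2, sp)
  expect_equal(as.numeric(spillover_correct_pancreas(img2, pan, kid, 0)),
               as.numeric(organ_activity(img2, pan)), tolerance = 1e-12)

  # pancreas swallowed by the dilated kidney is a hard error
  tiny <- cube_voi("pancreas", dimv, i = 12:12, j = 9:10, k = 6:7, sp)
  expect_error(spillover_correct_pancreas(img2, tiny, kid, 20),
               "manual review")
})

test_that("with PSF blur the correction moves pancreas activity toward truth", {
  st <- generate_cohort(n = 1,
                        model = default_kinetics_model(psf_fwhm_mm = 6,
                                                       noise_scale = 0),
                        seed = 5, jitter_sdlog = 0)[[1]]
  r <- generate_phantom_image(st, 60)
  truth <- r$truth[["pancreas"]]
  unc <- as.numeric(organ_activity(r$image, r$vois$pancreas))
  cor <- as.numeric(spillover_correct_pancreas(r$image, r$vois$pancreas,
                                               r$vois$left_kidney, 9))
  expect_gt(unc, truth)                       # spill-in is positive
  expect_lt(abs(cor - truth), abs(unc - truth))
})

test_that("body volume follows the soft-tissue density rule", {
  expect_equal(body_volume(72.0), 72000 / 1.05)
  expect_equal(body_volume(72.0), 68571, tolerance = 1e-4)
  expect_equal(body_volume(1.05), 1000)
  expect_error(body_volume(0), "positive")
  expect_message(body_volume(70, height_cm = 180), "height")
})

test_that("remainder activity scales the background mean to the body", {
  sp <- c(10, 10, 10)                          # 1 mL voxels
  dimv <- c(10L, 10L, 10L)
  region <- cube_voi("scanned_region", dimv, i = 1:10, j = 1:10, k = 1:10, sp)
  src <- cube_voi("kidneys", dimv, i = 1:2, j = 1:2, k = 1:2, sp)

  # zero concentration outside the sources
  g <- array(0, dimv); g[src$mask] <- 1e5
  expect_equal(as.numeric(remainder_activity(voxel_image(g, sp), region,
                                             list(src), 60000)), 0)

  # uniform background c, no sources: c x V (unit conversion only)
  imgc <- voxel_image(array(250, dimv), sp)
  expect_equal(as.numeric(remainder_activity(imgc, region, list(), 60000)),
               250 * 60000 / 1e6, tolerance = 1e-12)

  # brute-force masked-mean oracle on a random phantom
  set.seed(9)
  g2 <- array(stats::runif(1000, 0, 2e3), dimv)
  img2 <- voxel_image(g2, sp)
  oracle <- mean(g2[region$mask & !src$mask]) * (60000 - src$volume_ml) / 1e6
  expect_equal(as.numeric(remainder_activity(img2, region, list(src), 60000)),
               oracle, tolerance = 1e-12)

  # region fully covered by sources is an error
  allsrc <- cube_voi("kidneys", dimv, i = 1:10, j = 1:10, k = 1:10, sp)
  expect_error(remainder_activity(img2, region, list(allsrc), 60000),
               "empty")

  # physical cap: cannot exceed the decayed injected activity
  hot <- voxel_image(array(1e5, dimv), sp, t_min = 0)
  expect_message(
    capped <- remainder_activity(hot, region, list(), 60000,
                                 injected_mbq = 100, nuclide = ga68()),
    "capped")
  expect_equal(as.numeric(capped), 100)
})

test_that("negative reconstruction values are clipped at load", {
  g <- array(c(-5, rep(2, 7)), c(2, 2, 2))
  expect_message(img <- voxel_image(g, c(1, 1, 1)), "clipped 1")
  expect_true(all(img$grid >= 0))
})
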