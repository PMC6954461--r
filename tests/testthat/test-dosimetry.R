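# MIRD dose engine: absorbed doses, effective dose, scaling, budgets,
# pediatric extrapolation, cohort statistics.

test_that("absorbed doses follow the MIRD sum", {
  ph <- phantom("adult_male", c(kidneys = 300, pancreas = 100), 70000,
                smatrix(data.frame(
                  target = c("pancreas", "pancreas", "kidneys", "kidneys",
                             "pancreas", "kidneys"),
                  source = c("kidneys", "pancreas", "kidneys", "pancreas",
                             "total_body", "total_body"),
                  s_mGy_per_MBq_h = c(0.9, 2.0, 1.5, 0.02, 0.01, 0.012)),
                  id = "toy"))
  nuc <- ga68()
  # all-zero TIACs give all-zero doses
  z <- absorbed_doses(tiac_set(c(kidneys = 0), 0, nuc), ph)
  expect_true(all(z == 0))
  # one source, no remainder: a single product
  d <- absorbed_doses(tiac_set(c(kidneys = 0.5), 0, nuc), ph)
  expect_equal(d[["pancreas"]], 0.45, tolerance = 1e-12)
  expect_equal(d[["kidneys"]], 0.75, tolerance = 1e-12)
  # unknown source organ is a named error
  expect_error(absorbed_doses(tiac_set(c(liver = 0.1), 0, nuc), ph),
               "liver")
})

test_that("whole-body source equals organ split plus remainder", {
  nuc <- ga68()
  for (seed in 1:100) {
    ph <- random_toy_phantom(seed)
    organs <- names(ph$organ_masses)
    x <- stats::runif(1, 0.1, 1.5)
    whole <- absorbed_doses(tiac_set(c(total_body = x), 0, nuc), ph)
    frac <- ph$organ_masses / ph$total_body_mass_g
    split <- absorbed_doses(
      tiac_set(stats::setNames(x * frac, organs),
               remainder_tiac_h = x * (1 - sum(frac)), nuclide = nuc), ph)
    expect_equal(split, whole, tolerance = 1e-9)
  }
})

test_that("doses are linear in the TIAC set", {
  nuc <- ga68()
  ph <- random_toy_phantom(123)
  organs <- names(ph$organ_masses)
  t1 <- tiac_set(stats::setNames(stats::runif(length(organs), 0, 0.1),
                                 organs), 0.2, nuc)
  t2 <- tiac_set(stats::setNames(stats::runif(length(organs), 0, 0.1),
                                 organs), 0.1, nuc)
  mix <- tiac_set(0.3 * t1$organ_tiacs_h + 0.7 * t2$organ_tiacs_h,
                  0.3 * t1$remainder_tiac_h + 0.7 * t2$remainder_tiac_h,
                  nuc)
  expect_equal(absorbed_doses(mix, ph),
               0.3 * absorbed_doses(t1, ph) + 0.7 * absorbed_doses(t2, ph),
               tolerance = 1e-9)
})

test_that("effective dose is the normalized tissue-weighted mean", {
  w <- icrp60_weights()
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  expect_error(tissue_weights(c(gonads = 0.5, lungs = 0.4)), "sum to 1")

  ph <- load_phantom("adult_male")
  targets <- smatrix_targets(ph$s_matrix)
  # uniform organ doses collapse to that dose
  u <- stats::setNames(rep(0.123, length(targets)), targets)
  expect_equal(effective_dose(u, w, ph, sex = "M"), 0.123,
               tolerance = 1e-9)
  expect_equal(effective_dose(0 * u, w, ph), 0)

  # brute-force weighted-sum oracle, remainder rule included
  set.seed(31)
  d <- stats::setNames(stats::runif(length(targets), 0, 1), targets)
  oracle <- 0
  for (tissue in names(w$weights)) {
    h <- if (tissue == "remainder") {
      rem <- intersect(w$remainder_tissues, names(ph$organ_masses))
      rem <- intersect(rem, names(d))
      sum(d[rem] * ph$organ_masses[rem]) / sum(ph$organ_masses[rem])
    } else if (tissue == "gonads") {
      d[["testes"]]
    } else {
      organ <- if (tissue %in% names(w$tissue_map))
        w$tissue_map[[tissue]] else tissue
      d[[organ]]
    }
    oracle <- oracle + w$weights[[tissue]] * h
  }
  expect_equal(effective_dose(d, w, ph, sex = "M"), unname(oracle),
               tolerance = 1e-12)
  # effective dose can never exceed the hottest organ
  expect_lte(effective_dose(d, w, ph, sex = "M"), max(d))

  # a weighted tissue with no dose anywhere is an error
  w_bad <- tissue_weights(c(lungs = 1))
  expect_error(effective_dose(d[setdiff(names(d), "lungs")], w_bad, ph),
               "lungs")
})

test_that("per-administration scaling is exact multiplication", {
  ref <- reference_dose_coefficients()
  get <- function(model, site) ref$mean[ref$model == model & ref$site == site]
  adult <- ref[ref$model == "adult" & ref$site != "effective_dose", ]
  rep_a <- dose_report("adult_female",
                       stats::setNames(adult$mean, adult$site),
                       get("adult", "effective_dose"),
                       provenance = list(s_matrix = "reference"))
  at100 <- scale_to_administered(rep_a, 100)
  expect_equal(at100$organ_doses_mgy[["kidneys"]], 47.2, tolerance = 1e-9)
  expect_equal(at100$organ_doses_mgy[["pancreas"]], 2.3, tolerance = 1e-9)
  expect_error(scale_to_administered(rep_a, 0), "positive")

  nb <- ref[ref$model == "newborn" & ref$site != "effective_dose", ]
  rep_n <- dose_report("newborn", stats::setNames(nb$mean, nb$site),
                       get("newborn", "effective_dose"))
  at20 <- scale_to_administered(rep_n, 20)
  expect_equal(at20$effective_dose_msv, 2.32, tolerance = 1e-9)
  expect_equal(at20$organ_doses_mgy[["pancreas"]], 10.6, tolerance = 1e-9)
})

test_that("examination budgets floor correctly", {
  expect_identical(exam_budget(0.71, 10), 14L)
  expect_identical(exam_budget(0.6, 250), 416L)
  expect_identical(exam_budget(2.5, 2.5), 1L)
  expect_error(exam_budget(0, 10), "> 0")
})

test_that("pediatric extrapolation reuses adult TIACs on child phantoms", {
  nuc <- ga68()
  w <- icrp60_weights()
  tiacs <- tiac_set(c(kidneys = 0.3, pancreas = 0.003,
                      small_intestine = 0.002), 0.75, nuc)

  # adult phantom is rejected
  expect_error(pediatric_report(tiacs, load_phantom("adult_male"), w),
               "pediatric")

  # zero TIACs give zero doses
  z <- pediatric_report(tiac_set(c(kidneys = 0), 0, nuc),
                        load_phantom("newborn"), w)
  expect_true(all(z$organ_doses_mgy_per_mbq == 0))

  # np-only mode: self-dose ratio between phantoms is the mass ratio
  kid_only <- tiac_set(c(kidneys = 0.3), 0, nuc)
  ad <- load_phantom("adult_male", mode = "np_only")
  nb <- load_phantom("newborn", mode = "np_only")
  d_ad <- absorbed_doses(kid_only, ad)[["kidneys"]]
  d_nb <- absorbed_doses(kid_only, nb)[["kidneys"]]
  expect_equal(d_nb / d_ad,
               organ_mass(ad, "kidneys") / organ_mass(nb, "kidneys"),
               tolerance = 1e-9)

  # fixed TIACs: pancreas dose ordering newborn > 1-y > 5-y > adult
  doses <- vapply(c("newborn", "one_year", "five_year", "adult_male"),
                  function(m) {
                    absorbed_doses(tiacs, load_phantom(m))[["pancreas"]]
                  }, 0)
  expect_true(all(diff(doses) < 0))
})

test_that("cohort summaries use the sample SD and a common target set", {
  mk <- function(k) {
    dose_report("adult_female", c(kidneys = k, pancreas = k / 20), k / 50)
  }
  same <- cohort_summary(list(mk(0.5), mk(0.5), mk(0.5)))
  expect_equal(same$sd, rep(0, 3))
  expect_equal(same$mean[same$site == "kidneys"], 0.5)

  two <- cohort_summary(list(mk(0.4), mk(0.6)))
  expect_equal(two$mean[two$site == "kidneys"], 0.5)
  expect_equal(two$sd[two$site == "kidneys"], 0.1414, tolerance = 1e-3)
  expect_equal(two$sd[two$site == "kidneys"], stats::sd(c(0.4, 0.6)),
               tolerance = 1e-12)

  expect_error(cohort_summary(list(mk(0.5))), "at least 2")
  other <- dose_report("adult_female", c(kidneys = 0.5), 0.01)
  expect_error(cohort_summary(list(mk(0.5), other)), "heterogeneous")
})

test_that("dose reports reject inconsistent weighting", {
  expect_error(dose_report("adult_male", c(kidneys = 0.1), 0.2),
               "effective dose exceeds")
})
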