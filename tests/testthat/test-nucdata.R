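# Nuclide data, S-value tables and the remainder-of-body algebra.

test_that("decay constant and mean lifetime are internally consistent", {
  nuc <- ga68()
  expect_equal(nuc$lambda_per_min * nuc$half_life_min, log(2),
               tolerance = 1e-12)
  # mean lifetime = half-life / ln 2
  expect_equal(mean_lifetime_h(nuc) * 60, nuc$half_life_min / log(2),
               tolerance = 1e-12)
  # invariant holds for arbitrary loaded nuclides too
  for (hl in c(0.5, 10, 67.71, 6 * 60, 8 * 24 * 60)) {
    n <- radionuclide("X", hl, 0.1)
    expect_equal(n$lambda_per_min * hl, log(2), tolerance = 1e-12)
  }
  expect_error(radionuclide("X", -1, 0.1), "positive")
  expect_error(radionuclide("X", 60, 0.1,
                            data.frame(energy_mev = 0.5, yield = 3)),
               "yield")
})

test_that("S-matrix CSV round-trips, and bad input fails loudly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("target,source,s_mGy_per_MBq_h",
               "kidneys,kidneys,0.9",
               "pancreas,kidneys,0.02",
               "kidneys,total_body,0.01"), path)
  sm <- load_smatrix(path)
  expect_equal(s_value(sm, "kidneys", "kidneys"), 0.9)
  expect_equal(s_value(sm, "pancreas", "kidneys"), 0.02)
  expect_equal(s_value(sm, "kidneys", "total_body"), 0.01)
  expect_warning(z <- s_value(sm, "liver", "kidneys"), "missing")
  expect_identical(z, 0)

  # header-only file: zero entries, every lookup 0 plus a warning
  writeLines("target,source,s_mGy_per_MBq_h", path)
  expect_warning(empty <- load_smatrix(path), "no entries")
  expect_equal(nrow(empty$entries), 0L)
  expect_warning(expect_identical(s_value(empty, "kidneys", "kidneys"), 0))

  writeLines(c("target,source,s_mGy_per_MBq_h", "kidneys,kidneys,-1"), path)
  expect_error(load_smatrix(path), "negative")

  writeLines(c("target,source,s_mGy_per_MBq_h", "kidneys,kidneys"), path)
  expect_error(load_smatrix(path), "line 2")
})

test_that("np-only self-dose S follows the unit conversion exactly", {
  # hand oracle: 1 MeV/decay into 1 kg
  #   1.602176634e-13 J/MeV x 3.6e9 decays/(MBq h) = 5.768e-4 Gy
  nuc1 <- radionuclide("X", 60, 1)
  expect_equal(approximate_self_s(1000, nuc1),
               1.602176634e-13 * 3.6e9 * 1000, tolerance = 1e-12)
  expect_equal(approximate_self_s(1000, nuc1), 0.5768, tolerance = 1e-3)
  # no non-penetrating emission, no self-dose
  expect_identical(approximate_self_s(500, radionuclide("Y", 60, 0)), 0)
  # S is inversely proportional to mass
  expect_equal(approximate_self_s(2000, nuc1),
               approximate_self_s(1000, nuc1) / 2)
  expect_error(approximate_self_s(0, nuc1), "> 0")
})

test_that("packaged phantoms satisfy the structural invariants", {
  for (m in c("adult_male", "adult_female", "newborn", "one_year",
              "five_year")) {
    ph <- load_phantom(m)
    expect_true(all(ph$organ_masses > 0))
    expect_lt(sum(ph$organ_masses), ph$total_body_mass_g)
    # self-dose dominates cross-dose for every target with a self entry
    e <- ph$s_matrix$entries
    for (tg in intersect(unique(e$target), unique(e$source))) {
      if (tg == "total_body") next
      self <- e$s_mGy_per_MBq_h[e$target == tg & e$source == tg]
      cross <- e$s_mGy_per_MBq_h[e$target == tg & e$source != tg &
                                   e$source != "total_body"]
      if (length(self) && length(cross)) {
        expect_true(all(self >= cross))
      }
    }
  }
})

test_that("remainder-of-body S-value algebra is exact, clamped, monotone", {
  # hand-arithmetic toy: (0.10 * 10000 - 0.50 * 1000) / 9000
  ph <- phantom("adult_male", c(kidneys = 1000, pancreas = 100), 10000,
                smatrix(data.frame(
                  target = c("pancreas", "pancreas"),
                  source = c("total_body", "kidneys"),
                  s_mGy_per_MBq_h = c(0.10, 0.50)), id = "toy"))
  expect_equal(rob_s("pancreas", ph, "kidneys"), 500 / 9000,
               tolerance = 1e-12)
  expect_equal(rob_s("pancreas", ph, "kidneys"), 0.0556, tolerance = 1e-3)

  # empty source set: identity with the total-body S-value
  expect_identical(rob_s("pancreas", ph, character()), 0.10)

  # a source hotter than the whole-body average lowers the remainder S
  expect_lt(rob_s("pancreas", ph, "kidneys"), rob_s("pancreas", ph))

  # negative algebra clamps at zero with a warning
  ph_neg <- phantom("adult_male", c(kidneys = 5000, pancreas = 100), 10000,
                    smatrix(data.frame(
                      target = c("pancreas", "pancreas"),
                      source = c("total_body", "kidneys"),
                      s_mGy_per_MBq_h = c(0.01, 0.50)), id = "toy"))
  expect_warning(z <- rob_s("pancreas", ph_neg, "kidneys"), "clamped")
  expect_identical(z, 0)

  # sources consuming the whole body mass are rejected
  # defensive guard for corrupted phantoms (the constructor itself
  # rejects organ masses reaching the body mass)
  ph_big <- ph
  ph_big$organ_masses <- c(kidneys = 9000, pancreas = 1000)
  expect_error(rob_s("pancreas", ph_big, c("kidneys", "pancreas")),
               "exceed")
  expect_error(phantom("adult_male", c(kidneys = 9000, pancreas = 1000),
                       10000, ph$s_matrix),
               "below the total-body mass")
})

test_that("organ aliases resolve to one canonical vocabulary", {
  expect_identical(canonical_organ(c("Duodenum", "left kidney", "colon")),
                   c("small_intestine", "kidneys",
                     "lower_large_intestine_wall"))
  expect_error(canonical_organ("flux_capacitor"), "unknown organ")
  expect_error(voi("total_body", array(TRUE, c(2, 2, 2))), "pseudo-organ")
  expect_error(voi("remainder", array(TRUE, c(2, 2, 2))), "pseudo-organ")
})
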