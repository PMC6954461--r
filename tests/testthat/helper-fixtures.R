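# Shared fixtures: toy phantoms with random S-matrices, and tiny images.

# Random toy phantom: a handful of organs, masses well below the body
# mass, S(T <- TB) drawn high enough that the remainder algebra never
# clamps (so algebraic identities are exercised, not the guard rail).
random_toy_phantom <- function(seed, n_organs = 4) {
  set.seed(seed)
  organs <- paste0("organ", seq_len(n_organs))
  # reuse real organ ids so canonicalization passes
  organs <- sample(c("kidneys", "pancreas", "liver", "spleen", "lungs",
                     "brain", "small_intestine"), n_organs)
  masses <- stats::setNames(stats::runif(n_organs, 100, 2000), organs)
  m_tb <- sum(masses) * stats::runif(1, 2, 5)
  grid <- expand.grid(target = c(organs, "total_body"),
                      source = c(organs, "total_body"),
                      stringsAsFactors = FALSE)
  s <- stats::runif(nrow(grid), 0, 0.1)
  s[grid$source == "total_body" | grid$target == "total_body"] <-
    stats::runif(sum(grid$source == "total_body" |
                       grid$target == "total_body"), 0.5, 1)
  phantom("adult_male", masses, m_tb,
          smatrix(data.frame(target = grid$target, source = grid$source,
                             s_mGy_per_MBq_h = s),
                  id = paste0("toy", seed)))
}

# Uniform cube image: value Bq/mL everywhere, cubic voxels.
uniform_image <- function(value, dim = c(10L, 10L, 10L),
                          spacing = c(10, 10, 10), t_min = 0) {
  voxel_image(array(value, dim), spacing_mm = spacing, t_min = t_min)
}

cube_voi <- function(label, dim = c(10L, 10L, 10L), i = 1:5, j = 1:5,
                     k = 1:4, spacing = c(10, 10, 10)) {
  m <- array(FALSE, dim)
  m[i, j, k] <- TRUE
  voi(label, m, spacing)
}

# Noise-free, blur-free single-patient study for exact-recovery tests.
clean_study <- function(seed = 11) {
  generate_cohort(n = 1,
                  model = default_kinetics_model(psf_fwhm_mm = 0,
                                                 noise_scale = 0),
                  seed = seed, jitter_sdlog = 0)[[1]]
}
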