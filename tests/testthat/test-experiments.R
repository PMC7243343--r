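# Sweep-level behavior. These tests probe consistency properties of the
# runners (not published equilibrium values), so they run on coarse intensity
# grids; the full published protocol lives in test-acceptance.R.

test_that("zero feedback gain reproduces the ablated circuit", {
  p <- msi_params(n_steps = 1500)
  sw <- run_lambda_sweep(p, lam_values = c(0, p$lam), n_intensities = 4L)
  r0 <- sw$records[sw$records$lam == 0 & sw$records$condition == "bimodal_full", ]
  roff <- sw$records[sw$records$lam == 0 &
                       sw$records$condition == "bimodal_no_cortex", ]
  r0 <- r0[order(r0$intensity), ]; roff <- roff[order(roff$intensity), ]
  expect_equal(r0$M, roff$M, tolerance = 1e-10)
  # the default gain's records match the plain inverse-effectiveness run
  base <- run_inverse_effectiveness(p, n_intensities = 4L)
  rl <- sw$records[sw$records$lam == p$lam &
                     sw$records$condition == "bimodal_full", ]
  rb <- base$records[base$records$condition == "bimodal_full", ]
  expect_equal(rl$M[order(rl$intensity)], rb$M[order(rb$intensity)],
               tolerance = 1e-12)
})

test_that("larger feedback gain never lowers the additivity index", {
  p <- msi_params(n_steps = 1500)
  sw <- run_lambda_sweep(p, lam_values = c(0, 0.2, 0.4), n_intensities = 4L)
  on <- sw$records[sw$records$condition == "bimodal_full" &
                     sw$records$intensity > 0, ]
  tab <- stats::reshape(on[, c("lam", "intensity", "additivity_index")],
                        idvar = "intensity", timevar = "lam",
                        direction = "wide")
  idx <- as.matrix(tab[, -1])
  expect_true(all(diff(t(idx)) >= -1e-9)) # non-decreasing across lam columns
})

test_that("zero offset in the spatial sweep equals the aligned sweep", {
  p <- msi_params(n_steps = 1500)
  sp <- run_spatial_principle(p, offsets_sigma = 0, n_intensities = 4L)
  base <- run_inverse_effectiveness(p, n_intensities = 4L)
  a <- sp$records[sp$records$condition == "bimodal_full", ]
  b <- base$records[base$records$condition == "bimodal_full", ]
  expect_equal(a$M[order(a$intensity)], b$M[order(b$intensity)],
               tolerance = 1e-12)
})

test_that("feedback-on response is at least the feedback-off response", {
  p <- msi_params(n_steps = 1500)
  sp <- run_spatial_principle(p, offsets_sigma = c(0, 2, 4),
                              n_intensities = 4L)
  on <- sp$records[sp$records$condition == "bimodal_full", ]
  off <- sp$records[sp$records$condition == "bimodal_no_cortex", ]
  key <- function(d) d[order(d$offset, d$intensity), ]
  expect_true(all(key(on)$M >= key(off)$M - 1e-12))
})

test_that("within-modality combination adds without strong enhancement", {
  p <- msi_params(n_steps = 2000)
  sw <- run_within_modality(p, offsets_sigma = c(0, 5), n_intensities = 3L)
  rec <- sw$records
  aligned <- rec[rec$offset == 0 & rec$intensity > 0, ]
  # combined response exceeds each single response but stays near-additive
  expect_true(all(aligned$M > aligned$A))
  expect_true(all(aligned$M > aligned$V))
  expect_true(all(aligned$additivity_index < 1.25))
  # a far-offset second stimulus suppresses below the single-input response
  far <- rec[rec$offset == 5 & rec$intensity >= 0.5, ]
  expect_true(all(far$M < far$A + far$V))
})

test_that("a zero-intensity partner reduces the combined run to unimodal", {
  p <- msi_params(n_steps = 1200)
  n <- p$n_neurons
  a <- stimulus_spec(8, 1, 0.6)
  comb <- simulate(build_within_modality_inputs(a, stimulus_spec(12, 1, 0), n), p)
  uni <- simulate(build_condition_inputs(
    condition_spec("unimodal_audio", audio = a), n), p)
  expect_equal(comb$final_state$r, uni$final_state$r, tolerance = 1e-12)
})

test_that("enhancement scatter is seeded and super-additivity needs feedback", {
  p <- msi_params(n_steps = 2000)
  s1 <- run_enhancement_scatter(p, n_samples = 6L, seed = 7L)
  s2 <- run_enhancement_scatter(p, n_samples = 6L, seed = 7L)
  expect_identical(s1, s2)
  s3 <- run_enhancement_scatter(p, n_samples = 6L, seed = 8L)
  expect_false(identical(s1$intensity, s3$intensity))
  off <- s1[!s1$feedback, ]
  expect_true(all(off$response_additivity <= 1e-6, na.rm = TRUE))
  # feedback-on must dominate feedback-off cell by cell
  on <- s1[s1$feedback, ]
  expect_true(all(on$M >= off$M - 1e-12))
})

test_that("crossover interpolation finds the first downward crossing", {
  expect_equal(crossover_intensity(c(0.1, 0.2, 0.3), c(1.4, 1.2, 0.6)),
               0.2 + 0.2 / 0.6 * 0.1)
  expect_true(is.na(crossover_intensity(c(0.1, 0.2), c(0.9, 0.8))))
  expect_true(is.na(crossover_intensity(0.5, 1.2)))
  # NA cells (zero response) are skipped
  expect_equal(crossover_intensity(c(0, 0.5, 1), c(NA, 1.5, 0.5)), 0.75)
})
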