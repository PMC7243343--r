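test_that("analytic posterior implements reliability weighting", {
  ana <- analytic_posterior(fusion_spec(8, 5, 1, 2))
  expect_equal(ana$w_a, 0.8)
  expect_equal(ana$w_v, 0.2)
  expect_equal(ana$mu_cp, 7.4)
  expect_equal(ana$sigma_cp, 0.894427, tolerance = 1e-6)
  # equal reliabilities average the means
  eq <- analytic_posterior(fusion_spec(8, 5, 1.5, 1.5))
  expect_equal(eq$w_a, 0.5)
  expect_equal(eq$mu_cp, 6.5)
  # an unreliable cue loses its vote
  wide <- analytic_posterior(fusion_spec(8, 5, 0.5, 100))
  expect_equal(wide$mu_cp, 8, tolerance = 1e-3)
  # fused uncertainty never exceeds the better cue
  set.seed(3)
  for (k in 1:50) {
    sa <- runif(1, 0.3, 3); sv <- runif(1, 0.3, 3)
    a <- analytic_posterior(fusion_spec(8, 6, sa, sv))
    expect_lte(a$sigma_cp, min(sa, sv) + 1e-12)
    expect_equal(a$w_a + a$w_v, 1, tolerance = 1e-12)
  }
})

test_that("posterior comparison is exact on matching moments and errors on empty", {
  ana <- analytic_posterior(fusion_spec(8, 5, 1, 2))
  emp <- structure(list(fused_locations = c(7, 8), mean = ana$mu_cp,
                        std = ana$sigma_cp, fused_fraction = 1),
                   class = "msi_empirical_posterior")
  cmpr <- compare_posteriors(emp, ana)
  expect_equal(cmpr$mean_error, 0)
  expect_equal(cmpr$variance_error, 0)
  none <- structure(list(fused_locations = numeric(0), mean = NA, std = NA),
                    class = "msi_empirical_posterior")
  expect_error(compare_posteriors(none, ana), "no fused trials")
})

test_that("Monte-Carlo sampling from the analytic posterior recovers it", {
  # oracle check of the comparison pipeline itself, no network involved:
  # draws from the optimal per-trial combination have mean mu_cp and sd
  # sigma_cp, so the posterior errors shrink as draws grow
  spec <- fusion_spec(8, 5, 1, 2)
  ana <- analytic_posterior(spec)
  set.seed(99)
  n <- 20000
  xa <- rnorm(n, spec$mu_a, spec$sigma_a)
  xv <- rnorm(n, spec$mu_v, spec$sigma_v)
  fused <- ana$w_a * xa + ana$w_v * xv
  emp <- structure(list(fused_locations = fused, mean = mean(fused),
                        std = sd(fused), fused_fraction = 1),
                   class = "msi_empirical_posterior")
  cmpr <- compare_posteriors(emp, ana)
  expect_lt(abs(cmpr$mean_error), 3 * ana$sigma_cp / sqrt(n))
  expect_lt(abs(cmpr$variance_error), 3 * ana$sigma_cp^2 * sqrt(2 / n))
})

test_that("network location readout is unbiased for unimodal stimuli", {
  p <- msi_params(n_steps = 1500)
  centers <- 2:17
  inputs <- lapply(centers, function(c0) {
    build_condition_inputs(
      condition_spec("unimodal_audio", audio = stimulus_spec(c0, 1, 0.5)), 20)
  })
  out <- simulate_batch(inputs, p)
  est <- apply(out$sc_rate, 2, ml_location)
  expect_identical(as.integer(est), as.integer(centers))
})

test_that("fusion experiment is deterministic and classifies coincident cues as fused", {
  p <- msi_params()
  spec <- fusion_spec(8, 8, 0.6, 0.6, n_draws = 8L, seed = 21L)
  e1 <- run_fusion_experiment(spec, p)
  e2 <- run_fusion_experiment(spec, p)
  expect_identical(e1$fused_locations, e2$fused_locations)
  expect_identical(e1$draws, e2$draws)
  expect_gt(e1$fused_fraction, 0.9) # near-coincident stimuli always fuse
  expect_equal(nrow(e1$draws), 8L)
  # all sampled centers stay inside the array after truncation
  expect_true(all(e1$draws$audio_center >= 0 & e1$draws$audio_center <= 19))
})

test_that("fusion probability drops with offset and respects feedback ordering", {
  p <- msi_params()
  fo <- run_fusion_vs_offset(p, offsets = c(0, 2, 6))
  for (fb in c(TRUE, FALSE)) {
    cur <- fo[fo$feedback == fb, ]
    cur <- cur[order(cur$offset), ]
    expect_equal(cur$fused_probability[1], 1) # aligned cues fuse
    expect_equal(cur$fused_probability[3], 0) # disjoint bumps never fuse
    expect_true(all(diff(cur$fused_probability) <= 0))
  }
  on <- fo[fo$feedback, ]; off <- fo[!fo$feedback, ]
  expect_true(all(on$fused_probability[order(on$offset)] >=
                    off$fused_probability[order(off$offset)]))
})

test_that("the spec grid spans the full mean/width cross", {
  specs <- fusion_spec_grid(n_draws = 10L, seed = 5L)
  expect_length(specs, 64L)
  tab <- do.call(rbind, lapply(specs, function(s)
    data.frame(mu_a = s$mu_a, mu_v = s$mu_v,
               sigma_a = s$sigma_a, sigma_v = s$sigma_v)))
  expect_setequal(unique(tab$mu_a), c(8, 14.5))
  expect_setequal(unique(tab$mu_v), c(5, 8))
  expect_setequal(unique(tab$sigma_a), c(0.5, 1, 2, 3))
  expect_identical(nrow(unique(tab)), 64L)
  seeds <- vapply(specs, `[[`, integer(1), "seed")
  expect_identical(anyDuplicated(seeds), 0L)
})
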