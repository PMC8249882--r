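test_that("pipeline runs are deterministic and cover all pairwise contrasts", {
  co <- generate_cohort(3, c(A = 0, B = 0), noise_spec("3T"), level = 2,
                        seed = 13, reparam = FALSE)
  r1 <- run_pipeline(co, "known", n_permutations = 120, seed = 3,
                     tests = "pairwise")
  r2 <- run_pipeline(co, "known", n_permutations = 120, seed = 3,
                     tests = "pairwise")
  expect_identical(r1$global, r2$global)
  expect_identical(as.numeric(r1$pairwise[["A.B.volume"]]$fwe_p),
                   as.numeric(r2$pairwise[["A.B.volume"]]$fwe_p))

  co4 <- generate_cohort(3, c(CN = 0, MCIS = 0.3, MCIC = 0.8, AD = 1),
                         level = 2, seed = 5, reparam = FALSE)
  r4 <- run_pipeline(co4, "known", n_permutations = 120, seed = 3,
                     tests = "pairwise")
  pair_names <- unique(sub("\\.(thickness|area|volume)$", "",
                           names(r4$pairwise)))
  expect_length(pair_names, 6L) # all 4-choose-2 group contrasts
  expect_equal(nrow(r4$global), 12L)
})

test_that("zero-noise subjects give perfectly consistent change maps", {
  res <- run_noise_experiment(n_subjects = 3,
                              noise_levels = list(noise_spec("none"),
                                                  noise_spec("none")),
                              level = 2, seed = 9)
  expect_equal(unname(res$median), rep(1, 3), tolerance = 1e-6)
  expect_true(all(res$per_subject$area >= -1 & res$per_subject$area <= 1))
})

test_that("cross-noise consistency vanishes without true atrophy", {
  # negative control: with zero effect the maps are pure measurement noise,
  # independent across noise levels, so consistency collapses toward zero
  null_res <- run_noise_experiment(n_subjects = 4, effect_scale = 0,
                                   level = 3, seed = 17)
  expect_lt(max(abs(null_res$median)), 0.35)
  sig_res <- run_noise_experiment(n_subjects = 4, effect_scale = 1,
                                  level = 3, seed = 17)
  expect_gt(min(sig_res$median), max(abs(null_res$median)))
})

test_that("sample-size experiment reports sane nested power estimates", {
  out <- run_samplesize_experiment(sample_sizes = c(4L, 8L), replicates = 2,
                                   effect_scale = 1, level = 2,
                                   n_permutations = 120, seed = 21)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$power >= 0 & out$power <= 1))
  expect_true(all(out$fp_rate >= 0 & out$fp_rate <= 1))
})
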