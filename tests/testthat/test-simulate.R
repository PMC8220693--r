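test_that("cohort generation is deterministic and honours the ground truth", {
  cfg <- sim_config(n_true_asvs = 6, n_contaminant_asvs_shared = 30,
                    n_contaminant_asvs_batch_specific = 12, n_batches = 3,
                    n_samples_per_batch = 6, n_dencs_per_batch = 4, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(unclass(s1$table), unclass(s2$table))
  s3 <- simulate_cohort(sim_config(n_true_asvs = 6,
                                   n_contaminant_asvs_shared = 30,
                                   n_contaminant_asvs_batch_specific = 12,
                                   n_batches = 3, n_samples_per_batch = 6,
                                   n_dencs_per_batch = 4, seed = 6))
  expect_false(identical(unclass(s1$table), unclass(s3$table)))

  # truth consistency: true signal never in a DENC
  denc <- s1$design$sample_id[s1$design$sample_type == "plasma_denc"]
  true_ids <- s1$truth$asv_id[s1$truth$label == "true_signal"]
  expect_true(all(unclass(s1$table)[true_ids, denc] == 0))
  # batch signature: batch-specific contaminants have no reads elsewhere
  bs <- s1$truth[s1$truth$label == "contaminant_batch", ]
  for (i in seq_len(nrow(bs))) {
    outside <- s1$design$sample_id[s1$design$extraction_batch !=
                                     bs$source_batches[i]]
    expect_true(all(unclass(s1$table)[bs$asv_id[i], outside] == 0))
  }
  # labels partition the ASVs
  expect_setequal(s1$truth$asv_id, asv_ids(s1$table))
})

test_that("replicate batches duplicate patients and no-dropout gives kappa 1", {
  sim <- simulate_cohort(sim_config(
    n_true_asvs = 10, n_contaminant_asvs_shared = 30,
    n_contaminant_asvs_batch_specific = 0, n_batches = 2,
    n_samples_per_batch = 10, n_dencs_per_batch = 4,
    detection_dropout = 0, seed = 8))
  pa <- sim$design$patient_id[sim$design$extraction_batch == "A" &
                                sim$design$sample_type == "plasma"]
  pb <- sim$design$patient_id[sim$design$extraction_batch == "B" &
                                sim$design$sample_type == "plasma"]
  expect_setequal(pa, pb)
  res <- replicate_agreement_filter(sim$table, sim$design, c("A", "B"))
  true_ids <- sim$truth$asv_id[sim$truth$label == "true_signal"]
  kap <- setNames(res$kappa, res$asv_id)[true_ids]
  expect_true(all(kap[!is.na(kap)] == 1))
})

test_that("DENC and plasma richness are comparable under the default cohort", {
  sim <- simulate_cohort(sim_config(seed = 33))
  ad <- alpha_diversity(sim$table)
  type <- sim$design$sample_type[match(ad$sample_id, sim$design$sample_id)]
  r_pl <- mean(ad$richness[type == "plasma"])
  r_dn <- mean(ad$richness[type == "plasma_denc"])
  expect_lt(abs(r_pl - r_dn) / r_pl, 0.25)
})

test_that("a signal-free cohort shows no plasma-vs-DENC structure", {
  sim <- simulate_cohort(sim_config(
    n_true_asvs = 0, n_contaminant_asvs_shared = 40,
    n_contaminant_asvs_batch_specific = 0, n_batches = 1,
    replicate_pair = FALSE, n_samples_per_batch = 10,
    n_dencs_per_batch = 10, contaminant_plasma_dropout = 0, seed = 13))
  r <- rarefy(sim$table, min(colSums(sim$table)), seed = 1)
  dm <- bray_curtis(transform_counts(r, "sqrt"))
  res <- permanova(dm, sim$design, "sample_type", n_perm = 199, seed = 2)
  expect_gt(res$p_value[1], 0.05)
})

test_that("mock communities share their bias across runs", {
  even <- simulate_mock_community(bias_sigma = 0, n_runs = 2, seed = 3)
  p <- transform_counts(even, "relative")
  se <- sqrt(0.05 * 0.95 / 50000)
  expect_lt(max(abs(p - 1 / 20)), 3 * se + 0.004)
  biased <- simulate_mock_community(bias_sigma = 1, n_runs = 2, seed = 4)
  expect_gte(cor(unclass(biased)[, 1], unclass(biased)[, 2],
                 method = "spearman"), 0.9)
  dropped <- simulate_mock_community(bias_sigma = 1, n_runs = 2, seed = 5,
                                     drop_strains = 7)
  expect_true(all(unclass(dropped)["strain07", ] == 0))
})

test_that("dilution series dilutes the target but not the contaminants", {
  conc <- 10^(4:-2)
  ser <- simulate_dilution_series(conc, n_contaminants = 25, seed = 9)
  frac_contam <- 1 - unclass(ser)["target.ecoli", ] / colSums(ser)
  expect_lt(frac_contam[1], frac_contam[length(conc)])
  expect_gt(cor(seq_along(conc), frac_contam, method = "spearman"), 0)
  pure <- simulate_dilution_series(10^(3:1), n_contaminants = 0, seed = 2)
  expect_equal(unname(unclass(pure)["target.ecoli", ] / colSums(pure)),
               rep(1, 3))
})

test_that("recovery scoring matches set arithmetic", {
  truth <- data.frame(asv_id = c(paste0("t", 1:4), paste0("c", 1:6)),
                      label = rep(c("true_signal", "contaminant_shared"),
                                  c(4, 6)),
                      source_batches = "A")
  perfect <- evaluate_recovery(truth, paste0("t", 1:4))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$false_pass_rate, 0)
  empty <- evaluate_recovery(truth, character(0))
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$false_pass_rate, 0)
  mixed <- evaluate_recovery(truth, c("t1", "t2", "c1"))
  expect_equal(mixed$sensitivity, 0.5)
  expect_equal(mixed$false_pass_rate, 1 / 3)
  # random lists recover true ASVs at the sampling rate
  set.seed(14)
  hits <- replicate(400, {
    pick <- sample(truth$asv_id, 5)
    evaluate_recovery(truth, pick)$sensitivity
  })
  expect_equal(mean(hits), 0.5, tolerance = 0.05)
  expect_error(evaluate_recovery(truth, "nope"), "unknown")
})
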