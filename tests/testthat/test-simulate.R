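test_that("simulation config validates its stated world", {
  cfg <- simulation_config()
  expect_equal(cfg$mean_depth, 314.2)
  expect_equal(cfg$covered_fraction, 0.97)
  expect_equal(sum(cfg$diagnosis_mix), 1)
  expect_error(simulation_config(n_patients = 0), "positive")
  expect_error(simulation_config(diagnosis_mix = c(solved_biallelic = 0.5,
                                                   digenic = 0.2,
                                                   modifier = 0.2,
                                                   monoallelic = 0.2,
                                                   unsolved = 0.2)), "sum to 1")
})

test_that("a cohort is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_patients = 12, seed = 11)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(simulation_config(n_patients = 12, seed = 12))
  expect_false(identical(s1$calls, s3$calls))
})

test_that("an all-unsolved cohort with no background emits no calls", {
  cfg <- simulation_config(
    n_patients = 8, background_rate = 0, seed = 2,
    diagnosis_mix = c(solved_biallelic = 0, digenic = 0, modifier = 0,
                      monoallelic = 0, unsolved = 1))
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$calls), 0)
  expect_true(all(sim$truth$patients$category == "unsolved"))
})

test_that("het allele fractions match the binomial closed form", {
  # 10^4 het draws at the published mean depth: the mean fraction must sit
  # within 3 standard errors of 0.5, where SE derives from the binomial
  # variance p(1-p)/depth averaged over the drawn depths
  cfg <- simulation_config(n_patients = 5500, background_rate = 0, seed = 31,
                           diagnosis_mix = c(solved_biallelic = 0, digenic = 1,
                                             modifier = 0, monoallelic = 0,
                                             unsolved = 0))
  sim <- simulate_cohort(cfg)
  hets <- sim$calls
  expect_gt(nrow(hets), 1e4)
  se <- sqrt(mean(0.25 / hets$depth) / nrow(hets))
  expect_lt(abs(mean(hets$alt_fraction) - 0.5), 3 * se)
})

test_that("homozygous fractions collapse out of band as error rate grows", {
  mk <- function(eps) {
    cfg <- simulation_config(
      n_patients = 400, background_rate = 0, error_rate = eps, seed = 13,
      prob_hom_biallelic = 1, covered_fraction = 1,
      diagnosis_mix = c(solved_biallelic = 1, digenic = 0, modifier = 0,
                        monoallelic = 0, unsolved = 0))
    sim <- simulate_cohort(cfg)
    mean(sim$calls$alt_fraction >= 0.8)
  }
  in_band <- vapply(c(0.01, 0.1, 0.2, 0.3), mk, numeric(1))
  expect_true(all(diff(in_band) <= 0))       # non-increasing in error rate
  expect_gt(in_band[1], 0.99)
  expect_lt(in_band[4], 0.5)
})

test_that("planted detectability matches its analytic expectation", {
  cfg0 <- simulation_config(covered_fraction = 1, homopolymer_miss_prob = 0)
  expect_equal(planted_detectability(
    list(variants = tibble::tibble(homopolymer_indel = c(TRUE, FALSE))), cfg0), 1)
  cfg1 <- simulation_config(covered_fraction = 0.97, homopolymer_miss_prob = 0.5)
  expect_equal(planted_detectability(
    list(variants = tibble::tibble(homopolymer_indel = TRUE)), cfg1),
    0.97 * 0.5)
  expect_equal(planted_detectability(
    list(variants = tibble::tibble(homopolymer_indel = FALSE)), cfg1), 0.97)
})

test_that("empirical dropout matches the coverage model at large n", {
  # ~10^5 planted single SNVs at covered_fraction 0.97, no homopolymers
  cfg <- simulation_config(
    n_patients = 1e5, background_rate = 0, seed = 17, prob_hom_biallelic = 1,
    diagnosis_mix = c(solved_biallelic = 0, digenic = 0, modifier = 0,
                      monoallelic = 1, unsolved = 0))
  sim <- simulate_cohort(cfg)
  tv <- sim$truth$variants
  snv <- tv[!tv$homopolymer_indel, ]
  frac <- mean(!snv$dropped)
  se <- sqrt(0.97 * 0.03 / nrow(snv))
  expect_gt(nrow(snv), 9e4)
  expect_lt(abs(frac - 0.97), 3 * se)
})

test_that("planted zygosity survives default QC with its true label", {
  # >= 10^3 covered planted variants at depth >= 30
  cfg <- simulation_config(n_patients = 1000, background_rate = 0, seed = 23,
                           diagnosis_mix = c(solved_biallelic = 0.7,
                                             digenic = 0.1, modifier = 0.1,
                                             monoallelic = 0.1, unsolved = 0))
  sim <- simulate_cohort(cfg)
  kept <- apply_qc_filters(sim$calls)
  tv <- sim$truth$variants[!sim$truth$variants$dropped, ]
  tv <- tv[match(paste(kept$patient_id, variant_key(kept$gene, kept$hgvs_c)),
                 paste(tv$patient_id, tv$key)), ]
  deep <- kept$depth >= 30
  expect_gt(sum(deep), 1e3)
  agree <- kept$zygosity[deep] == tv$zygosity[deep]
  expect_gte(mean(agree), 0.99)
})

test_that("planted diagnoses are recovered for fully observed patients", {
  for (seed in 1:10) {
    cfg <- simulation_config(n_patients = 15, seed = seed)
    sim <- simulate_cohort(cfg)
    res <- run_pipeline(sim$calls, patients = sim$truth$patients,
                        pedigrees = sim$pedigrees)
    tv <- sim$truth$variants
    surviving <- paste(res$filtered$patient_id,
                       variant_key(res$filtered$gene, res$filtered$hgvs_c))
    if (nrow(tv) > 0) {
      tv$observed <- paste(tv$patient_id, tv$key) %in% surviving
      complete <- tapply(tv$observed, tv$patient_id, all)
      ids <- as.numeric(names(complete))[complete]
    } else ids <- numeric(0)
    ids <- c(ids, sim$truth$patients$patient_id[
      sim$truth$patients$category == "unsolved"])
    truth_cat <- sim$truth$patients$category[
      match(ids, sim$truth$patients$patient_id)]
    expected <- ifelse(truth_cat == "modifier", "solved_biallelic", truth_cat)
    got <- res$diagnoses[match(ids, res$diagnoses$patient_id), ]
    expect_equal(got$category, expected)
    expect_true(all(got$n_modifiers[truth_cat == "modifier"] > 0))
  }
})
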