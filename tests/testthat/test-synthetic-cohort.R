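test_that("default parameters encode the target population structure", {
  p <- default_params()
  expect_s3_class(p, "generator_params")
  expect_identical(validate_params(p), p)
  expect_equal(p$noc_prevalence, 0.30)
  expect_equal(unname(p$noc_split), c(0.63, 0.27, 0.10), tolerance = 1e-9)
  expect_equal(sum(p$clinical_stage_probs), 1, tolerance = 1e-12)
  expect_equal(unname(p$clinical_stage_probs), c(0.443, 0.239, 0.318),
               tolerance = 1e-3)
  # log-normal parameters reproduce the stage-conditional mean/median pairs
  expect_equal(exp(p$psa_logmean_oc), 6.7, tolerance = 1e-9)
  expect_equal(exp(p$psa_logmean_oc + p$psa_logsd_oc^2 / 2), 7.6,
               tolerance = 1e-9)
  expect_equal(exp(p$psa_logmean_noc + p$psa_logsd_noc^2 / 2), 8.6,
               tolerance = 1e-9)
  # marginal transition triple approx (0.13, 0.53, 0.34) under the implied
  # biopsy GS mixture
  gs_mix <- 0.7 * p$biopsy_gs_probs_oc + 0.3 * p$biopsy_gs_probs_noc
  marg <- colSums(p$gs_transition * gs_mix)
  expect_equal(unname(marg), c(0.13, 0.53, 0.34), tolerance = 0.01)
})

test_that("invalid parameter sets are rejected before sampling", {
  p <- default_params(n = 10)
  p$noc_split <- c(0.5, 0.4, 0.4)
  expect_error(sample_cohort(p), "noc_split")
  p2 <- default_params(n = 10)
  p2$psa_clip <- c(10, 5)
  expect_error(validate_params(p2), "psa_clip")
  p3 <- default_params(n = 10)
  p3$noc_prevalence <- 1.2
  expect_error(validate_params(p3), "noc_prevalence")
})

test_that("sampling is reproducible and honours degenerate settings", {
  p <- default_params(n = 200, seed = 5)
  expect_identical(sample_cohort(p), sample_cohort(p))
  expect_equal(nrow(sample_cohort(default_params(n = 0))), 0)
  p_all <- default_params(n = 150, seed = 5)
  p_all$noc_prevalence <- 1 - 1e-12
  co <- sample_cohort(p_all)
  expect_true(all(co$path_stage != "OC"))
  expect_true(all(co$noc))
})

test_that("large cohorts recover the configured population moments", {
  p <- default_params(n = 10000, seed = 31)
  co <- sample_cohort(p)
  expect_equal(nrow(co), 10000)
  # prevalence within 3 binomial SE of 0.30
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(co$noc) - 0.30), 3 * se)
  # NOC split recovery
  split <- prop.table(table(co$path_stage[co$noc]))[c("ECE", "SVI", "LNI")]
  expect_equal(unname(as.numeric(split)), c(0.63, 0.27, 0.10),
               tolerance = 0.05)
  # PSA moments: stage-conditional means near 7.6 / 8.6
  expect_equal(mean(co$psa[!co$noc]), 7.6, tolerance = 3 * 4.1 / sqrt(7000))
  expect_equal(mean(co$psa[co$noc]), 8.6, tolerance = 3 * 4.9 / sqrt(3000))
  # clipping invariant
  expect_true(all(co$psa >= p$psa_clip[1] & co$psa <= p$psa_clip[2]))
  # ages inside the configured plausible range
  expect_true(all(co$age >= p$age_range[1] & co$age <= p$age_range[2]))
})

test_that("empirical NOC fraction covers the configured prevalence", {
  # 99% binomial interval coverage over independent seeds
  z <- qnorm(0.995)
  se <- sqrt(0.3 * 0.7 / 10000)
  hits <- vapply(1:5, function(s) {
    co <- sample_cohort(default_params(n = 10000, seed = 1000 + s))
    abs(mean(co$noc) - 0.30) <= z * se
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("grouped transition fractions recover the configured marginals", {
  p <- default_params(n = 10000, seed = 77)
  co <- sample_cohort(p)
  gt <- gleason_transition(co)
  gs_mix <- 0.7 * p$biopsy_gs_probs_oc + 0.3 * p$biopsy_gs_probs_noc
  target <- colSums(p$gs_transition * gs_mix)
  obs <- gt$counts[c("decrease", "no_change", "increase"), "Total"] / 10000
  for (i in 1:3) {
    se <- sqrt(target[i] * (1 - target[i]) / 10000)
    expect_lt(abs(obs[i] - target[i]), 3 * se)
  }
})

test_that("cohort CSV round-trips field-for-field and rejects bad records", {
  co <- sample_cohort(default_params(n = 5, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back, co, tolerance = 1e-12)

  lines <- readLines(f)
  bad_psa <- sub("^(P[0-9]+,[0-9]+,)[0-9.]+", "\\1-1", lines[2])
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], bad_psa, lines[-(1:2)]), f2)
  expect_error(read_cohort(f2), "psa.*row\\(s\\) 1")

  f3 <- withr::local_tempfile(fileext = ".csv")
  bad_gs <- lines
  bad_gs[3] <- sub("(,[^,]*,[^,]*,[^,]*,)[^,]*(,)", "\\1GS99\\2", lines[3])
  writeLines(bad_gs, f3)
  expect_error(read_cohort(f3), "biopsy_gs|prostatectomy_gs")
})
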