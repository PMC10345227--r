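test_that("cohort generation is reproducible and respects the config", {
  cfg <- cohort_config(n_subjects = 105, seed = 1)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)

  expect_equal(length(unique(coh1$subject_id)), 105)
  # 60/105 singletons, multi-visit mean 2 + 2*(2/9): expect ~170 visits
  expect_gt(nrow(coh1), 150)
  expect_lt(nrow(coh1), 190)
  # ages within range, visit index increasing with age within subject
  expect_true(all(coh1$age_months >= 2.9 & coh1$age_months <= 12))
  for (s in split(coh1, coh1$subject_id)) {
    expect_true(all(diff(s$age_months) > 0) || nrow(s) == 1)
    expect_identical(s$visit_index, seq_len(nrow(s)))
  }
  # A-tetra status constant within mother
  pos <- tapply(coh1$atetra_mgL > 0, coh1$subject_id, unique)
  expect_true(all(lengths(pos) == 1))
})

test_that("degenerate configs are honoured and invalid ones rejected", {
  one <- generate_cohort(cohort_config(n_subjects = 1, p_singleton = 1,
                                       seed = 5))
  expect_equal(nrow(one), 1L)
  expect_error(cohort_config(p_singleton = 1.2), "p_singleton")
  expect_error(cohort_config(max_visits = 0), "max_visits")
  expect_error(cohort_config(age_range_months = c(5, 13)),
               "age_range_months")
  expect_error(cohort_config(sigma_resid = -1), "sigma_resid")
  expect_error(cohort_config(true_gamma = c("nope:bif_longum" = 1)),
               "true_gamma")
})

test_that("HMO simulation has the configured trend signs and A-tetra rule", {
  set.seed(11)
  draw_mean <- function(age, atetra) {
    rowMeans(replicate(400, simulate_hmo(age, atetra)))
  }
  m3 <- draw_mean(3, TRUE)
  m10 <- draw_mean(10, TRUE)
  # increasing: 3-FL, 3'-SL, A-tetra; decreasing: the other five
  for (up in c("3fl", "3sl", "atetra")) expect_gt(m10[up], m3[up])
  for (dn in c("2fl", "6sl", "lnt", "lnnt", "lnfp1")) {
    expect_lt(m10[dn], m3[dn])
  }
  expect_equal(unname(simulate_hmo(5, FALSE)[["atetra"]]), 0)
  expect_error(simulate_hmo(-1, TRUE))
})

test_that("group offset reproduces the reported 3-FL mean difference", {
  coh <- generate_cohort(cohort_config(n_subjects = 2000, seed = 17))
  atetra_pos <- coh$atetra_mgL > 4.4
  m_pos <- mean(coh[["3fl_mgL"]][atetra_pos])
  m_neg <- mean(coh[["3fl_mgL"]][!atetra_pos])
  expect_lt(m_pos, m_neg)
  # calibrated to the reported group means 1243.26 / 1550.97 mg/L
  expect_equal(m_pos, 1243.26, tolerance = 0.10)
  expect_equal(m_neg, 1550.97, tolerance = 0.10)
})

test_that("microbiota compositions close to one and track calibration", {
  set.seed(3)
  draws <- t(replicate(500, simulate_microbiota(6)))
  expect_true(all(abs(rowSums(draws) - 1) < 1e-9))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_error(simulate_microbiota(5, base = c(a = -1, b = 2)))
  # symmetric weights, zero slopes: equal expected abundances
  sym <- t(replicate(2000, simulate_microbiota(
    6, base = setNames(rep(1 / 4, 4), letters[1:4]),
    slopes = setNames(numeric(4), letters[1:4]), concentration = 4)))
  expect_lt(diff(range(colMeans(sym))), 0.05)
  # cohort-level Bif. longum mean near the 0.38 target
  coh <- generate_cohort(cohort_config(n_subjects = 700, seed = 23))
  expect_gt(nrow(coh), 1000)
  expect_equal(mean(coh$ra_bif_longum), 0.38, tolerance = 0.08)
})

test_that("MSEL scores follow the random-intercept interaction model", {
  params <- list(
    intercepts = setNames(c(100, rep(50, 5)),
                          c("composite", "gross_motor", "visual_reception",
                            "fine_motor", "receptive_language",
                            "expressive_language")),
    true_beta = c(sex_male = 2),
    true_hmo_beta = c(lnt = 1.5),
    true_mb_beta = c(bif_longum = -1),
    true_gamma = c("lnt:bif_longum" = 0.5),
    sigma_resid = 0,
    composite_mode = "independent"
  )
  row <- c(sex_male = 1, lnt = 2, bif_longum = -1)
  sc <- simulate_msel(row, params, subject_intercept = 3)
  # 50 + 2 + 3 - (-1) + 0.5*2*(-1) + 3 = deterministic closed form
  expect_equal(unname(sc[["fine_motor"]]), 50 + 2 + 3 + 1 - 1 + 3)
  expect_equal(unname(sc[["composite"]]), 100 + 2 + 3 + 1 - 1 + 3)
  expect_error(simulate_msel(c(sex_male = 1), params, 0), "lnt")

  # derived composite is the configured linear combination of subdomains
  params$composite_mode <- "derived"
  sc2 <- simulate_msel(row, params, 0)
  sub4 <- c("visual_reception", "fine_motor", "receptive_language",
            "expressive_language")
  expect_equal(unname(sc2[["composite"]]),
               100 + 2 * (mean(sc2[sub4]) - 50))
})

test_that("OLS on generated data recovers a planted interaction", {
  cfg <- cohort_config(n_subjects = 1200, p_singleton = 0, max_visits = 2,
                       p_extra_visit = 0, seed = 31,
                       true_gamma = c("3sl:bif_bifidum" = 0.5),
                       sigma_subject = 0)
  coh <- generate_cohort(cfg)
  z1 <- standardize(coh[["3sl_mgL"]])
  z2 <- standardize(coh$ra_bif_bifidum)
  fit <- summary(lm(coh$msel_expressive_language ~ z1 * z2))
  est <- fit$coefficients["z1:z2", ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])
})

test_that("covariate marginals match their configured proportions", {
  coh <- generate_cohort(cohort_config(n_subjects = 2000, seed = 41))
  subj <- coh[!duplicated(coh$subject_id), ]
  expect_equal(mean(subj$sex == "male"), 0.38, tolerance = 0.1)
  expect_equal(mean(subj$delivery == "vaginal"), 0.79, tolerance = 0.06)
  expect_equal(mean(subj$maternal_education == "graduate"), 0.61,
               tolerance = 0.08)
  atetra_mother <- tapply(coh$atetra_mgL, coh$subject_id, max) > 0
  expect_equal(mean(atetra_mother), 36 / 105, tolerance = 0.12)
})
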