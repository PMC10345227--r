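test_that("double-MAD scores follow the definition on the worked series", {
  x <- c(10, 11, 11, 11, 12, 12, 12, 13, 13, 100)
  sc <- double_mad_scores(x)
  expect_equal(sc[10], 88 / 0.5)  # right MAD 0.5
  expect_equal(sc[1], 2 / 1)      # left MAD 1
  expect_equal(double_mad_scores(rep(5, 6)), rep(0, 6))
  sym <- double_mad_scores(1:5)
  expect_equal(sym[1], sym[5])
  expect_error(double_mad_scores(c(1, 2)), "3 non-missing")
  # zero side-MAD with nonzero deviation gives +Inf
  expect_true(is.infinite(double_mad_scores(c(0, 0, 0, 0, 1))[5]))
})

test_that("double-MAD scores match a brute-force reference on random data", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                rexp(n),
                round(rnorm(n), 1))  # ties included
    expect_identical(double_mad_scores(x), brute_double_mad(x))
  }
})

test_that("outlier flagging honours threshold and policies", {
  x <- c(10, 11, 11, 11, 12, 12, 12, 13, 13, 100)
  fl <- flag_outliers(x, threshold = 3, policy = "keep")
  expect_identical(which(fl$flag), 10L)
  expect_identical(fl$values, x)

  none <- flag_outliers(x, threshold = Inf, policy = "keep")
  expect_false(any(none$flag))

  miss <- flag_outliers(x, 3, "set_missing")
  expect_true(is.na(miss$values[10]))
  expect_identical(miss$values[-10], x[-10])

  wins <- flag_outliers(x, 3, "winsorize")
  expect_equal(wins$values[10], 12 + 3 * 0.5)
  expect_error(flag_outliers(x, threshold = -1), "positive")
})

test_that("species filter uses a strict sum threshold and is monotone", {
  tab <- cbind(common = rep(0.01, 170), rare = rep(0.005, 170),
               boundary = c(1.0, rep(0, 169)))
  expect_identical(filter_species(tab, 1), "common")  # 1.7 > 1; 0.85, 1.0 fail
  expect_identical(filter_species(tab, 0),
                   c("common", "rare", "boundary"))
  expect_error(filter_species(tab[0, , drop = FALSE]), "empty")
  expect_error(filter_species(tab * -1), "\\[0, 1\\]")
  # monotone: raising the threshold never adds species
  set.seed(5)
  ab <- matrix(runif(200, 0, 0.05), 20)
  colnames(ab) <- paste0("s", 1:10)
  prev <- filter_species(ab, 0)
  for (thr in c(0.1, 0.3, 0.5, 0.8)) {
    cur <- filter_species(ab, thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("standardization is exact, idempotent and affine invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(standardize(standardize(x)), standardize(x))
  expect_equal(standardize(3 * x + 7), standardize(x))
  xm <- x
  xm[c(4, 9)] <- NA
  z <- standardize(xm)
  expect_identical(which(is.na(z)), c(4L, 9L))
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(sd(z[!is.na(z)]), 1)
  expect_error(standardize(rep(2, 5)), "distinct")
})

test_that("age residualization removes linear trends exactly", {
  ages <- c(1, 2, 3)
  expect_equal(residualize_on_age(c(1, 2, 4), ages),
               c(1 / 6, -1 / 3, 1 / 6))
  expect_equal(residualize_on_age(2 + 3 * ages, ages), rep(0, 3))
  set.seed(2)
  a <- runif(30, 2.9, 12)
  v <- rnorm(30)
  r <- residualize_on_age(v, a)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(abs(sum(r * a)), 1e-10)
  expect_error(residualize_on_age(v, rep(5, 30)), "constant")
})

test_that("A-tetra and secretor classification use the printed rules", {
  expect_identical(atetra_status(c(4.4, 10, 0)),
                   c("negative", "positive", "negative"))
  expect_error(atetra_status(NA_real_), "missing")
  # reported cohort medians: ratio 1860/970 = 1.92 < 6.5827
  expect_identical(classify_secretor(1860, 970, rule = "ratio"),
                   "non_secretor")
  expect_identical(classify_secretor(7000, 970, rule = "ratio"), "secretor")
  expect_error(classify_secretor(10, 0, rule = "ratio"), "3-FL")
  expect_identical(classify_secretor(14.9, rule = "threshold"),
                   "non_secretor")
  expect_identical(classify_secretor(100, rule = "threshold"), "secretor")
})

test_that("cohort preprocessing output is coherent", {
  coh <- tiny_cohort(80, seed = 7)
  prep <- preprocess_cohort(coh)
  expect_true(all(prep$species %in% sub("^ra_", "",
                                        grep("^ra_", names(coh),
                                             value = TRUE))))
  # standardization before residualization: columns are centred
  for (cl in names(prep$z)) {
    expect_lt(abs(mean(prep$z[[cl]], na.rm = TRUE)), 1e-8)
  }
  expect_identical(length(prep$atetra), nrow(coh))
  # keep policy leaves raw values untouched
  keep <- preprocess_cohort(coh, preprocess_config(outlier_policy = "keep",
                                                   residualize_age = FALSE))
  expect_equal(keep$z$bif_longum, standardize(coh$ra_bif_longum))
})
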