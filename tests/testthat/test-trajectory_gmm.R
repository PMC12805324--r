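mk_series <- function(n_per_class, intercepts, slopes = 0, n_days = 50,
                      su = 3, se = 10) {
  slopes <- rep_len(slopes, length(intercepts))
  rows <- list(); pid <- 0
  for (k in seq_along(intercepts)) {
    for (i in seq_len(n_per_class[k])) {
      pid <- pid + 1
      u <- rnorm(1, 0, su)
      d <- 0:(n_days - 1)
      rows[[pid]] <- data.frame(
        patient_id = sprintf("P%03d", pid), truth_class = k, day = d,
        value = intercepts[k] + slopes[k] * d + u + rnorm(n_days, 0, se))
    }
  }
  do.call(rbind, rows)
}

test_that("a flat noiseless series is interpolated exactly by one class", {
  series <- data.frame(patient_id = "P1", day = 0:19, value = 70)
  fit <- fit_gmm(series, gmm_spec(n_classes = 1, n_restarts = 1))
  expect_equal(fit$classes$intercept, 70, tolerance = 1e-6)
  expect_equal(fit$classes$slope, 0, tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and classes come out sorted", {
  set.seed(12)
  series <- mk_series(c(15, 10), c(20, 60))
  fit <- fit_gmm(series, gmm_spec(n_classes = 2, seed = 3))
  expect_true(all(diff(fit$ll_trace) > -1e-6 * (1 + abs(fit$ll_trace[-1]))))
  expect_equal(fit$classes$intercept, sort(fit$classes$intercept))
  expect_equal(sum(fit$classes$proportion), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, fit$n_patients),
               tolerance = 1e-9)
  expect_equal(sum(fit$classes$modal_size), fit$n_patients)
})

test_that("a two-class structure is recovered with accurate intercepts", {
  set.seed(13)
  series <- mk_series(c(25, 12), c(18.4, 68.2), su = 4, se = 12)
  fit <- fit_gmm(series, gmm_spec(n_classes = 2, seed = 5))
  # compare against the realised class means (the estimable quantity at one
  # draw of the patient random intercepts)
  truth_means <- tapply(
    tapply(series$value, series$patient_id, mean),
    tapply(series$truth_class, series$patient_id, unique), mean)
  expect_lt(abs(fit$classes$intercept[1] - truth_means["1"]), 2)
  expect_lt(abs(fit$classes$intercept[2] - truth_means["2"]), 2)
  expect_lt(abs(fit$classes$intercept[1] - 18.4), 4)
  expect_lt(abs(fit$classes$intercept[2] - 68.2), 4)
  expect_equal(fit$classes$modal_size, c(25, 12))
  expect_true(all(fit$classes$p_intercept < 1e-6))
})

test_that("relabeling leaves the likelihood alone (canonical order check)", {
  set.seed(14)
  series <- mk_series(c(10, 10), c(20, 50))
  f1 <- fit_gmm(series, gmm_spec(n_classes = 2, seed = 1))
  # feeding the same data with patients shuffled must give the same model
  shuffled <- series[sample.int(nrow(series)), ]
  shuffled <- shuffled[order(shuffled$patient_id, shuffled$day), ]
  f2 <- fit_gmm(shuffled, gmm_spec(n_classes = 2, seed = 1))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$BIC, f2$BIC, tolerance = 1e-6)
  expect_equal(f1$classes$intercept, f2$classes$intercept, tolerance = 1e-6)
})

test_that("one-class fit matches the random-intercept mixed model", {
  set.seed(15)
  series <- mk_series(20, 40, slopes = 0.1, su = 5, se = 8)
  fit <- fit_gmm(series, gmm_spec(n_classes = 1, n_restarts = 1))
  lm4 <- lme4::lmer(value ~ day + (1 | patient_id), data = series, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-4)
  expect_equal(fit$classes$intercept, unname(lme4::fixef(lm4)[1]),
               tolerance = 1e-3)
  expect_equal(fit$classes$slope, unname(lme4::fixef(lm4)[2]),
               tolerance = 1e-4)
})

test_that("BIC selection: one class for one-class data, two for separated", {
  set.seed(16)
  s1 <- mk_series(30, 40)
  sel1 <- select_classes(s1, 2, gmm_spec(seed = 2))
  expect_equal(sel1$chosen_k, 1)
  s2 <- mk_series(c(20, 15), c(15, 65), su = 3, se = 10)
  sel2 <- select_classes(s2, 2, gmm_spec(seed = 2))
  expect_equal(sel2$chosen_k, 2)
  sel3 <- select_classes(s2, 1, gmm_spec(seed = 2))
  expect_equal(sel3$chosen_k, 1)             # K_max = 1 is trivially 1
})

test_that("posterior classification and entropy behave at the limits", {
  set.seed(17)
  # near-perfect separation -> entropy near 1
  s <- mk_series(c(15, 15), c(0, 200), su = 1, se = 5)
  f <- fit_gmm(s, gmm_spec(n_classes = 2, seed = 4))
  cp <- classify_posterior(f)
  expect_gt(cp$entropy, 0.99)
  expect_equal(sort(unique(cp$assignments$class)), 1:2)
  # a single class has entropy 1 by convention and assigns class 1
  f1 <- fit_gmm(s, gmm_spec(n_classes = 1, n_restarts = 1))
  cp1 <- classify_posterior(f1)
  expect_equal(cp1$entropy, 1)
  expect_true(all(cp1$assignments$class == 1))
  # symmetric 50/50 overlap: coincident components give memberships of 1/2
  # and relative entropy near 0
  post <- matrix(0.5 + rnorm(60, 0, 0.01), 30, 2)
  post <- post / rowSums(post)
  rownames(post) <- sprintf("P%03d", 1:30)
  cp0 <- classify_posterior(list(posterior = post))
  expect_lt(cp0$entropy, 0.01)
  expect_equal(cp0$assignments$max_posterior, rep(0.5, 30), tolerance = 0.05)
})

test_that("contracts: short series and oversized class counts error", {
  expect_error(fit_gmm(data.frame(patient_id = "P1", day = 0, value = 1),
                       gmm_spec(n_classes = 1)), "at least 2 days")
  s <- mk_series(3, 40, n_days = 5)
  expect_error(fit_gmm(s, gmm_spec(n_classes = 5)), "more classes")
})
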