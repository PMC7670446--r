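# small reusable latency dataset with a planted slope, built directly
# (no gaze simulation) for fast model-level checks
make_latency_data <- function(n_subj = 8, slope = -40, sd_subj = 30,
                              sd_res = 60, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                   throw = 2:10, stringsAsFactors = FALSE)
  b0 <- rnorm(n_subj, 0, sd_subj)[match(d$subject_id,
                                        sprintf("S%02d", seq_len(n_subj)))]
  d$throw_z <- z_standardize(d$throw)
  d$movement <- factor(ifelse(d$throw %% 2 == 0, "frozen", "moving"),
                       levels = c("frozen", "moving"))
  d$latency_ms <- -30 + b0 + slope * d$throw_z + rnorm(nrow(d), 0, sd_res)
  d
}

test_that("z-standardization forces mean 0 and sd 1", {
  z <- z_standardize(2:10)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  # idempotent on already-standardized input
  expect_equal(z_standardize(z), z, tolerance = 1e-12)
  # closed-form oracle on random data
  set.seed(2)
  x <- rnorm(57, 20, 7)
  expect_equal(z_standardize(x), (x - mean(x)) / sd(x))
  expect_error(z_standardize(rep(3, 10)), "degenerate")
})

test_that("the mixed model recovers planted fixed effects", {
  d <- make_latency_data(n_subj = 10, slope = -50, seed = 7)
  fit <- fit_lmm(d, "latency_ms", c("movement", "throw_z"))
  expect_s3_class(fit, "lmm_result")
  tab <- fit$terms
  sl <- tab[tab$term == "throw_z", ]
  expect_lt(abs(sl$estimate - (-50)), 2.5 * sl$se)
  expect_equal(fit$n_obs, 90L)
  expect_equal(fit$n_subjects, 10L)
  expect_true(all(tab$ci_lower < tab$estimate & tab$estimate < tab$ci_upper))
  # per-term and full-null LRT results are populated
  expect_true(all(!is.na(tab$p[tab$term != "(Intercept)"])))
  expect_equal(fit$full_null$df, 2)
})

test_that("single-subject data cannot identify the random effects", {
  d <- make_latency_data(n_subj = 1)
  expect_error(fit_lmm(d, "latency_ms", c("throw_z")), "2 subjects")
  d2 <- make_latency_data(n_subj = 5)
  d2$movement <- factor("frozen", levels = c("frozen", "moving"))
  expect_error(fit_lmm(d2, "latency_ms", c("movement", "throw_z")),
               "does not vary")
})

test_that("likelihood-ratio tests match direct log-likelihood subtraction", {
  d <- make_latency_data(n_subj = 8, seed = 11)
  full <- fit_lmm(d, "latency_ms", c("movement", "throw_z"))
  red <- fit_lmm(d, "latency_ms", "movement")
  out <- lrt(full, red)
  # oracle: explicit ML refits with the same uncorrelated random structure
  oracle <- 2 * (as.numeric(logLik(full$ml_fit)) -
                   as.numeric(logLik(red$ml_fit)))
  expect_equal(out$chisq, oracle, tolerance = 1e-8)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(oracle, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # identical models give chisq 0, p 1
  self <- lrt(full, full)
  expect_equal(self$chisq, 0, tolerance = 1e-8)
  expect_equal(self$df, 0)
  expect_equal(self$p, 1)
  # chi-squared quantile identity
  expect_equal(pchisq(qchisq(0.95, 1), 1, lower.tail = FALSE), 0.05)
  # non-nested models are refused
  only_z <- fit_lmm(d, "latency_ms", "throw_z")
  expect_error(lrt(only_z, red), "not nested")
})

test_that("p-values are invariant to rescaling of a covariate", {
  # note: a location shift is not tested - with uncorrelated random slopes
  # a shifted covariate genuinely changes the random-effects structure
  d <- make_latency_data(n_subj = 8, seed = 3)
  f1 <- fit_lmm(d, "latency_ms", c("movement", "throw_z"))
  d$throw_z <- 3.7 * d$throw_z
  f2 <- fit_lmm(d, "latency_ms", c("movement", "throw_z"))
  p1 <- f1$terms$p[f1$terms$term == "throw_z"]
  p2 <- f2$terms$p[f2$terms$term == "throw_z"]
  expect_equal(p1, p2, tolerance = 1e-4)
})

test_that("flipping the reference level negates the estimate, keeps its p", {
  d <- make_latency_data(n_subj = 8, seed = 5)
  f1 <- fit_lmm(d, "latency_ms", c("movement", "throw_z"))
  d$movement <- relevel(d$movement, "moving")
  f2 <- fit_lmm(d, "latency_ms", c("movement", "throw_z"))
  e1 <- f1$terms[f1$terms$term == "movementmoving", ]
  e2 <- f2$terms[f2$terms$term == "movementfrozen", ]
  expect_equal(e1$estimate, -e2$estimate, tolerance = 1e-4)
  expect_equal(e1$p, e2$p, tolerance = 1e-4)
})

test_that("leave-one-subject-out stability brackets the full-data estimate", {
  d <- make_latency_data(n_subj = 9, seed = 13)
  fit <- stability_loso(fit_lmm(d, "latency_ms", c("movement", "throw_z")))
  expect_equal(nrow(fit$loso), 9L)   # one refit per subject
  tab <- fit$terms
  # exchangeable simulated subjects: ranges stay near the estimate
  expect_true(all(tab$stability_min <= tab$estimate + 1e-9))
  expect_true(all(tab$stability_max >= tab$estimate - 1e-9))
  expect_error(stability_loso(fit_lmm(make_latency_data(2), "latency_ms",
                                      "throw_z")),
               "at least 3")
})

test_that("an outlier subject widens the stability range", {
  d <- make_latency_data(n_subj = 9, seed = 17)
  base <- stability_loso(fit_lmm(d, "latency_ms", "throw_z"))
  d2 <- d
  out_rows <- d2$subject_id == "S01"
  d2$latency_ms[out_rows] <- d2$latency_ms[out_rows] + 400 * d2$throw_z[out_rows]
  pert <- stability_loso(fit_lmm(d2, "latency_ms", "throw_z"))
  w0 <- base$terms$stability_max - base$terms$stability_min
  w1 <- pert$terms$stability_max - pert$terms$stability_min
  expect_gt(w1[base$terms$term == "throw_z"],
            w0[base$terms$term == "throw_z"])
})

test_that("VIFs equal the 1/(1 - R^2) regression oracle", {
  # orthogonal balanced design
  d <- make_latency_data(n_subj = 8, seed = 19)
  v <- vif_fixed(d, c("movement", "throw_z"))
  expect_equal(unname(v), c(1, 1), tolerance = 0.02)

  # correlated design vs oracle and vs the car package
  set.seed(29)
  n <- 120
  dd <- data.frame(a = rnorm(n))
  dd$b <- 0.7 * dd$a + rnorm(n, 0, 0.5)
  dd$c <- rnorm(n)
  v2 <- vif_fixed(dd, c("a", "b", "c"))
  r2a <- summary(lm(a ~ b + c, dd))$r.squared
  expect_equal(unname(v2["a"]), 1 / (1 - r2a), tolerance = 1e-10)
  dd$y <- rnorm(n)
  expect_equal(unname(v2), unname(car::vif(lm(y ~ a + b + c, dd))),
               tolerance = 1e-8)

  # duplicated column -> rank deficiency
  dd$b2 <- dd$b
  expect_error(vif_fixed(dd, c("b", "b2", "c")), "rank")
  expect_error(vif_fixed(dd, "a"), "two fixed terms")
})
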