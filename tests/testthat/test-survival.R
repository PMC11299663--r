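make_scores <- function(x, ids = sprintf("c%03d", seq_along(x))) {
  data.frame(case_id = ids, max_cs = x, stringsAsFactors = FALSE)
}

test_that("cox_univariate recovers a planted effect and respects affine equivariance", {
  set.seed(101)
  n <- 300
  x <- rnorm(n)
  scores <- make_scores(x)
  beta <- -0.5
  times <- rexp(n, rate = 0.01 * exp(beta * x))
  clin <- data.frame(case_id = scores$case_id, time = times, event = 1L)
  fit <- cox_univariate(scores, clin, standardize = FALSE)
  expect_lt(abs(fit$beta - beta), 3 * fit$se)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_gt(fit$hr, 0)
  expect_equal(fit$n, n)

  # x -> a + b x (b > 0): identical p, beta scaled by 1/b
  scores2 <- make_scores(5 + 2 * x, ids = scores$case_id)
  fit2 <- cox_univariate(scores2, clin, standardize = FALSE)
  expect_equal(fit2$p, fit$p, tolerance = 1e-8)
  expect_equal(fit2$beta, fit$beta / 2, tolerance = 1e-8)
  # standardization makes the two parameterizations identical
  expect_equal(cox_univariate(scores, clin)$beta,
               cox_univariate(scores2, clin)$beta, tolerance = 1e-8)
})

test_that("cox_univariate rejects degenerate inputs explicitly", {
  scores <- make_scores(rnorm(20))
  clin_noev <- data.frame(case_id = scores$case_id, time = rexp(20, 0.01),
                          event = 0L)
  expect_error(cox_univariate(scores, clin_noev), "no events")
  clin <- rand_clinical(scores$case_id)
  expect_error(cox_univariate(make_scores(rep(2, 20)), clin),
               "zero variance")
  expect_error(cox_univariate(scores[1:4, ], clin), "need >= 10")
})

test_that("log-rank on the hand-enumerated toy matches the risk-table oracle", {
  # groups A {1,2,3} and B {4,5,6}, all events: O_A = 3, E_A = 1.15,
  # V = 0.6775 -> chisq = (3 - 1.15)^2 / 0.6775
  clin <- data.frame(case_id = paste0("c", 1:6), time = 1:6, event = 1L)
  part <- list(upper = paste0("c", 1:3), lower = paste0("c", 4:6))
  km <- km_logrank(part, clin)
  expect_equal(km$chisq, 3.4225 / 0.6775, tolerance = 1e-6)
  expect_equal(km$p, pchisq(3.4225 / 0.6775, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(km$n_upper, 3)
  expect_equal(km$n_lower, 3)
})

test_that("identical survival in both groups gives log-rank p = 1 and empty groups error", {
  clin <- data.frame(case_id = paste0("c", 1:10),
                     time = rep(c(5, 10, 15, 20, 25), 2), event = 1L)
  part <- list(upper = paste0("c", 1:5), lower = paste0("c", 6:10))
  km <- km_logrank(part, clin)
  expect_equal(km$chisq, 0, tolerance = 1e-10)
  expect_equal(km$p, 1, tolerance = 1e-10)
  expect_error(km_logrank(list(upper = character(0), lower = "c1"), clin),
               "'upper' is empty")
  expect_error(km_logrank(list(upper = "c1", lower = character(0)), clin),
               "'lower' is empty")
})

test_that("KM curves step down by 1/n at each distinct all-event time and never increase", {
  set.seed(71)
  n <- 20
  clin <- data.frame(case_id = paste0("c", 1:n),
                     time = sample(1000, n), event = 1L)
  part <- list(upper = paste0("c", 1:10), lower = paste0("c", 11:20))
  km <- km_logrank(part, clin)
  for (g in c("upper", "lower")) {
    cv <- km$curves[km$curves$group == g, ]
    cv <- cv[order(cv$time), ]
    expect_equal(cv$surv, 1 - seq_len(10) / 10, tolerance = 1e-12)
    expect_true(all(diff(cv$surv) <= 0))
  }
})

test_that("log-rank p agrees with the Cox score test of the group indicator", {
  set.seed(83)
  for (rep in 1:5) {
    n <- 60
    ids <- sprintf("r%d_%02d", rep, 1:n)
    clin <- data.frame(case_id = ids, time = rexp(n, 0.02),
                       event = as.integer(runif(n) < 0.8))
    part <- list(upper = ids[1:30], lower = ids[31:60])
    km <- km_logrank(part, clin)
    d <- data.frame(time = clin$time, event = clin$event,
                    g = rep(1:0, each = 30))
    sc <- summary(survival::coxph(survival::Surv(time, event) ~ g,
                                  data = d))$sctest
    expect_equal(km$chisq, unname(sc["test"]), tolerance = 1e-6)
  }
})

test_that("expression-independent strata reproduce the unstratified association", {
  set.seed(97)
  n <- 400
  x <- rnorm(n)
  scores <- make_scores(x)
  times <- rexp(n, 0.01 * exp(-0.4 * x))
  clin <- data.frame(case_id = scores$case_id, time = times, event = 1L)
  expr_vals <- setNames(rnorm(n), scores$case_id)   # independent of everything
  res <- expression_stratified_cox(scores, clin, expr_vals,
                                   split_percentile = 50)
  full <- cox_univariate(scores, clin)
  expect_false(isTRUE(res$upper$not_evaluable))
  expect_false(isTRUE(res$lower$not_evaluable))
  expect_lt(abs(res$upper$beta - full$beta), 3.5 * res$upper$se)
  expect_lt(abs(res$lower$beta - full$beta), 3.5 * res$lower$se)
  expect_equal(res$n_upper + res$n_lower, n)
})

test_that("stratified analysis flags small strata and rejects empty upper stratum", {
  set.seed(103)
  scores <- make_scores(rnorm(30))
  clin <- rand_clinical(scores$case_id)
  ev <- setNames(c(rep(0, 25), 1:5), scores$case_id)
  res <- expression_stratified_cox(scores, clin, ev, split_percentile = 90)
  expect_true(isTRUE(res$upper$not_evaluable))   # 3 cases above the cut
  expect_match(res$upper$reason, "stratum")
  ev_const <- setNames(rep(1, 30), scores$case_id)
  expect_error(expression_stratified_cox(scores, clin, ev_const),
               "upper expression stratum is empty")
})

test_that("forest_table preserves order and rejects empty input", {
  set.seed(107)
  scores <- make_scores(rnorm(40))
  clin <- rand_clinical(scores$case_id)
  r1 <- cox_univariate(scores, clin)
  r2 <- cox_univariate(make_scores(rnorm(40), scores$case_id), clin)
  ft <- forest_table(list(full = r1, shuffled = r2))
  expect_equal(ft$label, c("full", "shuffled"))
  expect_equal(ft$hr[1], r1$hr)
  expect_true(all(ft$ci_low <= ft$hr & ft$hr <= ft$ci_high))
  expect_error(forest_table(list()), "empty")
  pdf_file <- tempfile(fileext = ".pdf")
  plot_forest(ft, file = pdf_file)
  expect_true(file.exists(pdf_file))
})
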