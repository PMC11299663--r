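test_that("generators are deterministic in the seed and independent of call order", {
  cfg <- sim_config(n_cases = 15, seed = 99)
  r1 <- simulate_repertoires(cfg)
  a1 <- simulate_antigen(cfg)
  r2 <- simulate_repertoires(cfg)   # antigen drawn in between must not matter
  expect_identical(r1, r2)
  expect_identical(a1, simulate_antigen(cfg))
  r3 <- simulate_repertoires(sim_config(n_cases = 15, seed = 100))
  expect_false(identical(r1$cdr3_aa, r3$cdr3_aa))
})

test_that("repertoires respect configured ranges and validate cleanly", {
  cfg <- sim_config(n_cases = 25, cdr3_per_case = c(2, 6),
                    cdr3_length = c(8, 24), seed = 3)
  reps <- simulate_repertoires(cfg)
  lens <- nchar(reps$cdr3_aa)
  expect_true(all(lens >= 8 & lens <= 24))
  per_case <- table(reps$case_id)
  expect_true(all(per_case >= 2 & per_case <= 6))
  expect_equal(length(per_case), 25)
  expect_true(all(reps$chain %in% c("TRA", "TRB")))
  for (s in reps$cdr3_aa[1:10]) expect_silent(validate_sequence(s))
})

test_that("charge enrichment drives between-case score spread; zero removes it", {
  cfg_flat <- sim_config(n_cases = 40, charge_enrichment = 0,
                         planted_length = 0, seed = 17)
  cfg_rich <- sim_config(n_cases = 40, charge_enrichment = 0.4,
                         planted_length = 0, seed = 17)
  ant <- simulate_antigen(cfg_flat)
  sd_flat <- sd(score_cases(simulate_repertoires(cfg_flat), ant)$max_cs)
  sd_rich <- sd(score_cases(simulate_repertoires(cfg_rich), ant)$max_cs)
  expect_gt(sd_rich, sd_flat)
})

test_that("the planted block is acidic and sits at the configured coordinates", {
  cfg <- sim_config(seed = 23, planted_acidity = 1)
  ant <- simulate_antigen(cfg)
  expect_equal(nchar(ant$sequence), 342)
  expect_equal(ant$planted_interval, c(220, 239))
  block <- strsplit(substr(ant$sequence, 220, 239), "")[[1]]
  expect_true(all(block %in% c("D", "E")))
})

test_that("survival generator hits the censoring target and zero censoring means all events", {
  cfg <- sim_config(n_cases = 2000, censoring_rate = 0.3, seed = 31)
  scores <- data.frame(case_id = sprintf("c%04d", 1:2000),
                       max_cs = rnorm(2000, 10, 2))
  surv <- simulate_survival(scores, cfg)
  expect_equal(mean(surv$event == 0), 0.3, tolerance = 0.05)
  expect_true(all(surv$time >= 0))
  cfg0 <- sim_config(n_cases = 50, censoring_rate = 0, seed = 31)
  surv0 <- simulate_survival(scores[1:50, ], cfg0)
  expect_true(all(surv0$event == 1))
})

test_that("expression generator has the right shape and converges to the target correlation", {
  n <- 800
  cfg <- sim_config(n_cases = n, expr_rho = 0.99, n_genes = 4, seed = 41)
  scores <- data.frame(case_id = sprintf("c%04d", 1:n),
                       max_cs = rnorm(n, 8, 3))
  m <- simulate_expression(scores, cfg)
  expect_equal(dim(m), c(4, n))
  expect_equal(colnames(m), scores$case_id)
  expect_true(all(m >= 0))
  for (g in 1:4) expect_gt(cor(m[g, ], scores$max_cs), 0.95)
  # rho can vary per gene
  cfg2 <- sim_config(n_cases = n, expr_rho = c(0.8, 0), n_genes = 2,
                     seed = 43)
  m2 <- simulate_expression(scores, cfg2)
  expect_gt(cor(m2[1, ], scores$max_cs), 0.6)
  expect_lt(abs(cor(m2[2, ], scores$max_cs)), 0.15)
})

test_that("fixture bundles round-trip through the pipeline readers with a valid truth file", {
  cfg <- sim_config(n_cases = 12, n_genes = 5, seed = 53)
  dir <- file.path(tempdir(), "bundle_a")
  paths <- make_fixture_bundle(cfg, dir)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  reps <- read_cdr3_table(paths["cdr3"])
  expect_equal(sort(unique(reps$case_id)), sprintf("case_%04d", 1:12))
  ant <- read_antigen_fasta(paths["antigen"])
  expect_equal(nchar(ant$sequence), 342)
  clin <- read_clinical_table(paths["clinical"])
  expect_setequal(clin$case_id, unique(reps$case_id))
  expr <- read_expression_matrix(paths["expression"])
  expect_equal(dim(expr), c(5, 12))
  truth <- read_truth(paths["truth"])
  expect_equal(truth$cox_beta, cfg$cox_beta)
  expect_equal(truth$planted_interval, c(220, 239))
  expect_length(truth$expr_rho, 5)
  # different seed, different repertoire file
  dir_b <- file.path(tempdir(), "bundle_b")
  make_fixture_bundle(sim_config(n_cases = 12, n_genes = 5, seed = 54), dir_b)
  expect_false(identical(readLines(paths["cdr3"]),
                         readLines(file.path(dir_b, "cdr3.tsv"))))
})

test_that("sim_config rejects invalid settings", {
  expect_error(sim_config(censoring_rate = 1))
  expect_error(sim_config(expr_rho = 1))
  expect_error(sim_config(cdr3_length = c(3, 10)))
  expect_error(sim_config(planted_start = 340, planted_length = 20))
})
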