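test_that("KM median follows the step-function definition", {
  # uncensored {1..5}: survival drops to 0.4 at t=3, so median = 3
  m <- km_median(1:5, rep(1, 5))
  expect_equal(m$median, 3)
  expect_equal(m$n, 5)

  # single censored observation: curve never reaches 0.5
  m2 <- km_median(10, 0)
  expect_true(is.na(m2$median))

  # all-censored input: median NA, no error
  m3 <- km_median(c(5, 8, 12), c(0, 0, 0))
  expect_true(is.na(m3$median))

  expect_error(km_median(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(km_median(1:3, c(1, 2, 1)), "0/1")
})

test_that("KM median recovers the closed-form exponential median", {
  set.seed(14)
  lambda <- log(2) / 14          # median 14 months
  t <- rexp(5000, rate = lambda)
  m <- km_median(t, rep(1, 5000))
  expect_lt(abs(m$median - 14), 0.5)
  expect_true(m$lower <= m$median && m$median <= m$upper)
})

test_that("Cox HR: reference is 1, inversion on reference swap, null case", {
  set.seed(3)
  n <- 300
  g <- rep(c("A", "B"), each = n)
  t <- c(rexp(n, log(2) / 30), rexp(n, log(2) / 15))
  e <- rep(1, 2 * n)
  hr <- cox_hr(t, e, g, reference = "B")
  expect_equal(hr$hr[hr$group == "B"], 1)
  expect_true(hr$hr[hr$group == "A"] < 1)   # A lives longer
  expect_true(all(hr$lower <= hr$hr & hr$hr <= hr$upper, na.rm = TRUE))

  hr2 <- cox_hr(t, e, g, reference = "A")
  expect_equal(hr2$hr[hr2$group == "B"], 1 / hr$hr[hr$group == "A"],
               tolerance = 1e-8)

  # identical distributions: CI contains 1
  set.seed(4)
  t0 <- rexp(2 * n, log(2) / 20)
  hr0 <- cox_hr(t0, e, g, reference = "A")
  expect_true(hr0$lower[2] < 1 && 1 < hr0$upper[2])

  # zero-event group flagged unstable (coxph also warns about divergence)
  e2 <- e; e2[g == "A"] <- 0
  w <- capture_warnings(hru <- cox_hr(t, e2, g, reference = "B"))
  expect_true(any(grepl("zero events", w)))
  expect_true(hru$unstable[hru$group == "A"])
})

test_that("Cox CI covers a planted HR of 0.32 in at least 90% of seeds", {
  # mirrors the magnitude of the grade-4 IDH-mutant astrocytoma vs
  # glioblastoma contrast
  covered <- logical(100)
  for (s in 1:100) {
    set.seed(s)
    n <- 400
    t <- c(rexp(n, log(2) / 14), rexp(n, 0.32 * log(2) / 14))
    g <- rep(c("GBM", "ASTRO4"), each = n)
    hr <- cox_hr(t, rep(1, 2 * n), g, reference = "GBM")
    i <- hr$group == "ASTRO4"
    covered[s] <- hr$lower[i] <= 0.32 && 0.32 <= hr$upper[i]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("Cox log-HR recovery across a grid of true ratios", {
  set.seed(9)
  n <- 1000
  for (true_hr in c(0.25, 0.5, 1, 2)) {
    est <- vapply(1:10, function(r) {
      t <- c(rexp(n, log(2) / 20), rexp(n, true_hr * log(2) / 20))
      g <- rep(c("ref", "cmp"), each = n)
      hr <- cox_hr(t, rep(1, 2 * n), g, reference = "ref")
      log(hr$hr[hr$group == "cmp"])
    }, numeric(1))
    if (true_hr == 1) {
      expect_lt(abs(mean(est)), 0.05)
    } else {
      expect_lt(abs(mean(est) - log(true_hr)) / abs(log(true_hr)), 0.1)
    }
  }
})

test_that("pairwise log-rank produces C(G,2) pairs with symmetric matrices", {
  set.seed(12)
  g7 <- rep(paste0("g", 1:7), each = 40)
  t7 <- rexp(length(g7), log(2) / (10 + 10 * as.integer(factor(g7))))
  pw7 <- pairwise_logrank(t7, rep(1, length(g7)), g7)
  expect_equal(nrow(pw7$pairs), choose(7, 2))   # 21 pairs
  g6 <- g7[g7 != "g7"]; t6 <- t7[g7 != "g7"]
  pw6 <- pairwise_logrank(t6, rep(1, length(g6)), g6)
  expect_equal(nrow(pw6$pairs), choose(6, 2))   # 15 pairs

  expect_true(isSymmetric(pw7$p))
  off <- upper.tri(pw7$hr)
  expect_equal(pw7$hr[off], 1 / t(pw7$hr)[off], tolerance = 1e-10)

  # two copies of one sample set: identical curves, log-rank not significant
  set.seed(13)
  t0 <- rexp(100, log(2) / 20)
  pw0 <- pairwise_logrank(c(t0, t0), rep(1, 200),
                          rep(c("x", "y"), each = 100))
  expect_gt(pw0$pairs$p[1], 0.9)

  # BH adjustment never decreases a p-value
  pwbh <- pairwise_logrank(t7, rep(1, length(g7)), g7, adjust = "BH")
  expect_true(all(pwbh$pairs$p_adjusted >= pwbh$pairs$p - 1e-12))
})

test_that("significant fraction is exact arithmetic and order-invariant", {
  pw <- pw_from_pvalues(c(rep(0.01, 12), rep(0.5, 9)))
  sf <- significant_fraction(pw)
  expect_equal(sf$n_sig, 12); expect_equal(sf$n_pairs, 21)
  expect_equal(sf$percent, 57L)

  pw2 <- pw_from_pvalues(c(rep(0.04, 11), rep(0.9, 4)))
  expect_equal(significant_fraction(pw2)$percent, 73L)

  expect_equal(significant_fraction(pw_from_pvalues(rep(0.9, 8)))$percent, 0L)

  # invariant to pair order
  pw3 <- pw_from_pvalues(rev(c(rep(0.01, 12), rep(0.5, 9))))
  expect_equal(significant_fraction(pw3), sf)

  expect_error(significant_fraction(pw_from_pvalues(numeric(0))), "pairs")
})

test_that("KM estimate is a right-continuous non-increasing step from 1", {
  set.seed(15)
  t <- rexp(80, 0.05); e <- rbinom(80, 1, 0.7)
  fit <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_true(all(diff(fit$surv) <= 1e-12))
  expect_true(fit$surv[1] <= 1)
})

test_that("risk split recovers a planted score-driven hazard", {
  set.seed(20)
  n <- 300
  genes <- c("FN1", "ITGA5", "OSMR", "NGFR")
  expr <- matrix(rlnorm(4 * n, 5, 0.5), 4, n,
                 dimnames = list(genes, sprintf("p%03d", 1:n)))
  coefs <- c(FN1 = 0.4, ITGA5 = 0.3, OSMR = 0.2, NGFR = 0.1)
  score <- drop(crossprod(expr, coefs))
  z <- (score - mean(score)) / sd(score)
  t <- rexp(n, rate = log(2) / 14 * exp(0.7 * z))   # log-HR 0.7 per SD
  rs <- risk_split(coefs, expr, t, rep(1, n))
  expect_gt(rs$hr, 1)
  expect_lt(rs$p, 0.05)
  expect_equal(as.vector(table(rs$risk)), c(150, 150))

  # order invariance
  perm <- sample(n)
  rs2 <- risk_split(coefs, expr[, perm], t[perm], rep(1, n))
  expect_equal(rs2$hr, rs$hr, tolerance = 1e-9)

  # degenerate inputs
  expect_error(risk_split(c(FN1 = 0, ITGA5 = 0), expr, t, rep(1, n)),
               "zero")
  expect_error(risk_split(c(GHOST = 1), expr, t, rep(1, n)), "GHOST")
  const <- matrix(1, 1, n, dimnames = list("FN1", colnames(expr)))
  expect_error(risk_split(c(FN1 = 1), const, t, rep(1, n)), "identical")
})

test_that("survival_summary assembles medians, HRs and the pairwise grid", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 30)
  keep <- !sim$truth$truth_category %in%
    c("EXCLUDED_UNKNOWN_HISTOLOGY", "PEDIATRIC_H3_K27", "PEDIATRIC_H3_G34")
  grp <- sub("_.*", "", sim$truth$class_key[keep])
  ss <- survival_summary(sim$features$os_time[keep],
                         sim$features$os_event[keep], grp,
                         reference = "GBM")
  expect_s3_class(ss, "survival_summary")
  expect_equal(ss$cox$hr[ss$cox$group == "GBM"], 1)
  expect_equal(nrow(ss$pairwise$pairs), choose(length(unique(grp)), 2))
  expect_output(print(ss), "reference = GBM")
})
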