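mkTab <- function(participants, artery, side, d, source) {
  measurementTable(data.frame(
    participant_id = participants, artery = artery, side = side,
    diameter_mm = d, source = source, stringsAsFactors = FALSE))
}

test_that("detection classification matches hand-enumerated patterns", {
  man <- mkTab(paste0("p", 1:4), "ICA", "L", c(4.0, NA, 3.8, NA), "manual")
  aut <- mkTab(paste0("p", 1:4), "ICA", "L", c(4.1, NA, NA, 4.4), "auto")
  cts <- classifyDetection(man, aut)
  row <- cts[cts$artery == "ICA", ]
  expect_equal(unlist(row[c("tp", "tn", "fn", "fp")]),
               c(tp = 1, tn = 1, fn = 1, fp = 1))
  rates <- detectionRates(row)
  expect_equal(rates$pct_tp_tn, 50)
  expect_equal(rates$pct_fn, 25)
  expect_equal(rates$pct_fp, 25)

  # identical tables with no missing: all tp
  all_tp <- classifyDetection(man[c(1, 3), ], man[c(1, 3), ] |>
                                transform(source = "auto"))
  expect_equal(all_tp$tp[all_tp$artery == "ICA"], 2)
  r2 <- detectionRates(all_tp[all_tp$artery == "ICA", ])
  expect_equal(r2$pct_tp_tn, 100)

  # a key present in one table but absent in the other is an error
  expect_error(classifyDetection(man, aut[1:3, ]), "keys")

  # n = 0 is an error
  expect_error(detectionRates(data.frame(artery = "x", tp = 0, tn = 0,
                                         fn = 0, fp = 0)), "zero")
})

test_that("detection counts partition a hand-tallied 20-record table", {
  set.seed(61)
  n <- 20
  man_d <- ifelse(runif(n) < 0.7, runif(n, 2, 5), NA)
  aut_d <- ifelse(runif(n) < 0.8, runif(n, 2, 5), NA)
  man <- mkTab(paste0("p", 1:n), "PCom", "R", man_d, "manual")
  aut <- mkTab(paste0("p", 1:n), "PCom", "R", aut_d, "auto")
  cts <- classifyDetection(man, aut)[1, ]
  expect_equal(cts$tp, sum(!is.na(man_d) & !is.na(aut_d)))
  expect_equal(cts$tn, sum(is.na(man_d) & is.na(aut_d)))
  expect_equal(cts$fn, sum(!is.na(man_d) & is.na(aut_d)))
  expect_equal(cts$fp, sum(is.na(man_d) & !is.na(aut_d)))
  expect_equal(cts$tp + cts$tn + cts$fn + cts$fp, n)
})

test_that("ROC sweep behaves at the separable, random and reversed extremes", {
  n <- 60
  pres <- rep(c(TRUE, FALSE), each = n / 2)
  sep <- ifelse(pres, runif(n, 3, 5), NA)
  man <- mkTab(paste0("p", 1:n), "ICA", "L",
               ifelse(pres, 4, NA), "manual")
  aut_sep <- mkTab(paste0("p", 1:n), "ICA", "L", sep, "auto")
  roc <- rocPoints(man, aut_sep)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(rocAuc(roc), 1)

  # scores independent of the reference: area near 1/2
  set.seed(5)
  areas <- replicate(40, {
    aut_r <- mkTab(paste0("p", 1:n), "ICA", "L", runif(n, 1, 5), "auto")
    rocAuc(rocPoints(man, aut_r))
  })
  expect_lt(abs(mean(areas) - 0.5), 3 * sd(areas) / sqrt(length(areas)) + 0.02)

  # reversed scores: area near 0 (missing scored 0 stays at the bottom)
  aut_rev <- mkTab(paste0("p", 1:n), "ICA", "L",
                   ifelse(pres, NA, runif(n, 3, 5)), "auto")
  expect_lt(rocAuc(rocPoints(man, aut_rev)), 0.05)

  # no negatives in the reference is an error
  man_all <- mkTab(paste0("p", 1:4), "ICA", "L", c(4, 4, 4, 4), "manual")
  aut4 <- mkTab(paste0("p", 1:4), "ICA", "L", c(4, 4, 4, 4), "auto")
  expect_error(rocPoints(man_all, aut4), "present and missing")
})

test_that("paired differences keep only true-positive records", {
  man <- mkTab(paste0("p", 1:4), "BA", NA, c(3.0, 2.5, NA, 2.8), "manual")
  aut <- mkTab(paste0("p", 1:4), "BA", NA, c(3.4, NA, 2.0, 3.0), "auto")
  dt <- diffTable(man, aut)
  expect_equal(nrow(dt), 2)
  expect_equal(dt$diff, c(0.4, 0.2), tolerance = 1e-12)

  # empty overlap gives an empty table
  man2 <- mkTab("p1", "BA", NA, NA, "manual")
  aut2 <- mkTab("p1", "BA", NA, 3, "auto")
  expect_equal(nrow(diffTable(man2, aut2)), 0)
})

test_that("withinThreshold counts and stays monotone in the threshold", {
  expect_equal(withinThreshold(c(0.1, -0.6, 0.4), 0.5), 100 * 2 / 3)
  expect_equal(withinThreshold(rep(0, 5), 0.5), 100)
  expect_true(is.na(withinThreshold(numeric(), 0.5)))
  set.seed(3)
  d <- rnorm(200, 0, 0.4)
  expect_lte(withinThreshold(d, 0.5), withinThreshold(d, 1.0))
})

test_that("signed-rank margin test: exact case, null case, brute-force equality", {
  # all |d| = 0 against margin 0.5 with n = 10: p = 2^-10
  expect_equal(wilcoxonVsMargin(rep(0, 10), 0.5), 1 / 1024)

  # |d| symmetric around the margin: p near 1/2
  d <- 0.5 + c(-0.2, -0.1, -0.05, 0.05, 0.1, 0.2, -0.15, 0.15)
  p <- wilcoxonVsMargin(d, 0.5)
  expect_gt(p, 0.3)
  expect_lt(p, 0.7)

  # exact branch equals enumeration over all 2^n sign patterns
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    d <- runif(n, 0, 1.2)
    expect_equal(wilcoxonVsMargin(d, 0.5), bruteWilcoxonLess(d, 0.5),
                 tolerance = 1e-12)
  }
  # with ties in the absolute deviations too
  d <- c(0.1, 0.1, 0.3, 0.8, 0.9, 0.9, 0.2)
  expect_equal(wilcoxonVsMargin(d, 0.5), bruteWilcoxonLess(d, 0.5),
               tolerance = 1e-12)

  # the two directions are complementary-ish and n < 5 errors
  expect_error(wilcoxonVsMargin(c(0, 0.1, 0.2, 0.9), 0.5), "at least 5")
  dl <- runif(30, 0, 0.4)  # clearly within the margin
  expect_lt(wilcoxonVsMargin(dl, 0.5), 0.001)
  expect_gt(wilcoxonVsMargin(dl, 0.5, direction = "greater"), 0.999)
})

test_that("large-sample signed-rank branch approximates the exact one", {
  set.seed(23)
  d <- runif(26, 0, 1.1)  # just past the exact cutoff
  p_norm <- wilcoxonVsMargin(d, 0.5)
  x <- abs(d) - 0.5
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  p_exact <- cowmeter:::.signrankCdf(r, w)
  expect_equal(p_norm, p_exact, tolerance = 0.01)
})

test_that("Bonferroni caps and scales with the declared family size", {
  expect_equal(bonferroni(c(0.01, 0.2), 2), c(0.02, 0.4))
  expect_equal(bonferroni(0.9, 5), 1)
  expect_equal(bonferroni(0.0005, 60), 0.03)
  expect_error(bonferroni(c(0.1, 0.2), 1))
})

test_that("Spearman correlation: closed forms, exact p, invariances", {
  expect_equal(spearmanCor(1:6, c(2, 4, 6, 7, 9, 12))$rho, 1)
  expect_equal(spearmanCor(1:6, -(1:6))$rho, -1)
  # worked example: rho = 1 - 6*8/120 = 0.6
  ex <- spearmanCor(1:5, c(3, 1, 2, 5, 4))
  expect_equal(ex$rho, 0.6)
  # exact permutation p agrees with cor.test for small untied samples
  ct <- suppressWarnings(cor.test(1:5, c(3, 1, 2, 5, 4), method = "spearman"))
  expect_equal(ex$p, ct$p.value, tolerance = 1e-12)

  # t-approximation branch agrees with cor.test for larger n
  set.seed(31)
  x <- rnorm(40)
  y <- x + rnorm(40)
  got <- spearmanCor(x, y)
  ct2 <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ct2$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct2$p.value, tolerance = 0.02)

  # invariance under strictly monotone transforms
  expect_equal(spearmanCor(exp(x), y)$rho, got$rho)
  expect_equal(spearmanCor(x, y^3 + 5 * y)$rho, got$rho)

  # zero variance: missing, small n: error
  expect_true(is.na(spearmanCor(rep(1, 5), 1:5)$rho))
  expect_error(spearmanCor(1:2, 1:2), "at least 3")
})

test_that("regression summary recovers exact and noisy linear relations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- linregSummary(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse, 0)

  fit2 <- linregSummary(0.8 * x + 0.3, x)
  expect_equal(fit2$slope, 0.8)
  expect_equal(fit2$intercept, 0.3)
  expect_equal(fit2$r2, 1)
  expect_equal(fit2$rmse, 0, tolerance = 1e-12)

  set.seed(41)
  xx <- runif(200, 1, 5)
  yy <- 0.8 * xx + 0.3 + rnorm(200, 0, 0.2)
  fit3 <- linregSummary(yy, xx)
  se <- 0.2 / sqrt(sum((xx - mean(xx))^2))
  expect_lt(abs(fit3$slope - 0.8), 3 * se)

  expect_error(linregSummary(c(1, 2, 3), c(2, 2, 2)), "variance")
})

test_that("Shapiro-Wilk wrapper matches base behavior and rejects bad input", {
  set.seed(51)
  x <- rnorm(100)
  got <- shapiroWilk(x)
  ref <- shapiro.test(x)
  expect_equal(got$W, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_gt(got$W, 0)
  expect_lte(got$W, 1)

  bim <- c(rnorm(250, -3, 0.3), rnorm(250, 3, 0.3))
  expect_lt(shapiroWilk(bim)$p, 0.001)

  expect_error(shapiroWilk(rep(1, 10)), "variance")
  expect_error(shapiroWilk(c(1, 2)), "3 <= n")
})

test_that("the agreement report assembles all statistics per artery and size", {
  n <- 40
  rows <- do.call(rbind, lapply(1:n, function(i) {
    tr <- makeCowPhantom(voxel_mm = 0.625, seed = 1000 + i)$truth
    tr$participant <- paste0("p", i)
    tr
  }))
  man <- measurementTable(data.frame(
    participant_id = rows$participant, artery = rows$artery,
    side = rows$side,
    diameter_mm = rows$true_diameter_mm, source = "manual"))
  # a perfect automated source: every statistic collapses to its ideal
  aut <- man
  aut$source <- "auto"
  rep1 <- buildReport(man, list(`0.625` = aut))
  expect_equal(nrow(rep1), 6)
  expect_true(all(rep1$mean_diff_mm == 0))
  expect_true(all(rep1$pct_within_0.5 == 100))
  expect_equal(rep1$spearman_rho, rep(1, 6))
  expect_equal(rep1$slope, rep(1, 6))
  expect_equal(attr(rep1, "bonferroni_m"), 6 * 1 * 2)

  # unbiased noisy source: mean difference near zero at 1/sqrt(n) scale
  set.seed(8)
  aut2 <- aut
  aut2$diameter_mm <- aut2$diameter_mm + rnorm(nrow(aut2), 0, 0.25)
  rep2 <- buildReport(man, list(a = aut, b = aut2), bonferroni_m = 60)
  expect_equal(nrow(rep2), 12)
  mb <- rep2$mean_diff_mm[rep2$resolution == "b"]
  expect_true(all(abs(mb) < 4 * 0.25 / sqrt(n)))
  expect_true(all(rep2$wilcoxon_p_0.5_adj >= rep2$wilcoxon_p_0.5, na.rm = TRUE))
  expect_equal(attr(rep2, "bonferroni_m"), 60)
})
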