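## The bundled 3x3 serum comparison counts (100 residual serum samples).
serumCounts <- function() exampleComparisonTable("serum")

test_that("limit of blank follows the EP17 construction", {
  dl <- limitOfBlank(mean = 0.5, sd = 0.2)
  expect_equal(dl$lob, 0.829, tolerance = 1e-12)
  expect_equal(round(dl$lob, 2), 0.83)
  expect_equal(limitOfBlank(mean = 0.5, sd = 0)$lob, 0.5)
  expect_error(limitOfBlank(0.4), "at least 2")
  ## Monte-Carlo blanks at the published blank distribution
  set.seed(42)
  blanks <- rnorm(20, 0.5, 0.2)
  expect_lt(abs(limitOfBlank(blanks)$lob - 0.83), 0.15)
})

test_that("limit of detection adds the low-level spread to the LoB", {
  dl <- limitOfDetection(limitOfBlank(mean = 0.5, sd = 0.2), sdLow = 2.5)
  expect_equal(dl$lod, 0.829 + 1.645 * 2.5, tolerance = 1e-12)  # 4.9415
  expect_equal(limitOfDetection(0.829, sdLow = 0)$lod, 0.829)
  set.seed(8)
  lows <- rnorm(20, 5, 2.5)
  dl2 <- limitOfDetection(limitOfBlank(mean = 0.5, sd = 0.2),
                          lowReplicates = lows)
  expect_equal(dl2$lod, dl2$lob + 1.645 * sd(lows))
})

test_that("percent agreement reproduces the bundled serum comparison", {
  pa <- percentAgreement(serumCounts())
  expect_equal(pa$overall, 97.0, tolerance = 1e-9)
  expect_equal(round(unname(pa$perCategory), 1), c(93.3, 97.4, 97.8))
  ## identity table
  pid <- percentAgreement(diag(c(5, 5, 5)))
  expect_equal(pid$overall, 100)
  expect_equal(unname(pid$perCategory), c(100, 100, 100))
  ## an empty reference category is undefined, not zero
  tab <- matrix(c(3, 0, 0, 1, 0, 0, 0, 0, 0), 3)
  expect_true(is.na(percentAgreement(tab)$perCategory[3]))
})

test_that("overall agreement is the column-total-weighted per-category mean", {
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 6), 3)
    if (sum(tab) == 0 || any(colSums(tab) == 0)) next
    pa <- percentAgreement(tab)
    expect_equal(pa$overall,
                 sum(pa$perCategory * colSums(tab)) / sum(tab),
                 tolerance = 1e-9)
  }
})

test_that("Wilson intervals reproduce closed-form printed bounds", {
  cases <- list(list(x = 14, n = 15, lo = 70.2, hi = 98.8),
                list(x = 45, n = 46, lo = 88.7, hi = 99.6),
                list(x = 12, n = 12, lo = 75.8, hi = 100.0),
                list(x = 6,  n = 7,  lo = 48.7, hi = 97.4),
                list(x = 3,  n = 3,  lo = 43.9, hi = 100.0))
  for (cs in cases) {
    ci <- 100 * wilsonCI(cs$x, cs$n)
    expect_equal(round(unname(ci[1]), 1), cs$lo)
    expect_equal(round(unname(ci[2]), 1), cs$hi)
  }
  expect_equal(unname(wilsonCI(0, 10)[1]), 0)
  expect_equal(unname(wilsonCI(10, 10)[2]), 1)
})

test_that("Wilson intervals match the score interval from prop.test", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:200, 1)
    x <- sample(0:n, 1)
    ours <- wilsonCI(x, n)
    ref <- suppressWarnings(prop.test(x, n, correct = FALSE)$conf.int)
    expect_equal(unname(ours[1]), ref[1], tolerance = 1e-7)
    expect_equal(unname(ours[2]), ref[2], tolerance = 1e-7)
  }
})

test_that("kappa matches the bundled comparison and its invariances", {
  tab <- serumCounts()
  expect_equal(round(cohenKappa(tab), 3), 0.951)
  ## independent oracle
  skip_if_not_installed("e1071")
  expect_equal(cohenKappa(tab), e1071::classAgreement(tab)$kappa,
               tolerance = 1e-12)
})

test_that("kappa boundary behaviour: perfection, chance and permutations", {
  expect_equal(cohenKappa(diag(c(4, 6, 3))), 1)
  ## outer product of marginals = chance-only agreement
  r <- c(2, 3, 5); s <- c(4, 1, 5)
  expect_equal(cohenKappa(outer(r, s)), 0, tolerance = 1e-12)
  ## consistent relabeling leaves unweighted kappa unchanged
  set.seed(9)
  tab <- matrix(rpois(9, 5) + 1, 3)
  perm <- c(3, 1, 2)
  expect_equal(cohenKappa(tab[perm, perm]), cohenKappa(tab),
               tolerance = 1e-12)
  ## all mass in one agreeing cell: perfect agreement, not 0/0
  one <- matrix(c(0, 0, 0, 0, 7, 0, 0, 0, 0), 3)
  expect_equal(cohenKappa(one), 1)
  ## a single off-diagonal cell: no agreement and none expected by
  ## chance under identity weights, so kappa is exactly zero
  off <- matrix(c(0, 0, 0, 5, 0, 0, 0, 0, 0), 3)
  expect_equal(cohenKappa(off), 0)
})

test_that("weighted kappa discounts near-miss disagreements", {
  tab <- serumCounts()
  kl <- cohenKappa(tab, "linear")
  kq <- cohenKappa(tab, "quadratic")
  ku <- cohenKappa(tab, "none")
  ## every off-diagonal cell here is a one-step miss on a 3-level scale:
  ## weighting should soften the penalty
  expect_gt(kl, ku)
  expect_gt(kq, kl)
  ## on a 2-level scale linear weights reduce to identity weights
  t2 <- matrix(c(8, 2, 1, 9), 2)
  expect_equal(cohenKappa(t2, "linear"), cohenKappa(t2, "none"),
               tolerance = 1e-12)
})

test_that("Pearson r and Welch CI behave on exact and simulated data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonR2(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonR2(x, 2 * x + 1)$r2, 1)
  expect_equal(pearsonR2(x, -x)$r, -1)
  expect_error(pearsonR2(x, rep(2, 5)), "zero variance")
  ci <- welchCI(x, x)
  expect_equal(ci$estimate, 0)
  expect_lt(ci$lo, 0); expect_gt(ci$hi, 0)
  expect_error(welchCI(1, x), "length")
  ## coverage of a true +5 shift across seeded simulations
  set.seed(123)
  cover <- replicate(200, {
    a <- rnorm(25, 30, 2); b <- rnorm(25, 25, 2)
    ci <- welchCI(a, b)
    ci$lo <= 5 && 5 <= ci$hi
  })
  expect_gte(mean(cover), 0.93)
})

test_that("the agreement report assembles all statistics coherently", {
  rep_ <- agreementReport(serumCounts())
  expect_equal(rep_$overall, 97.0)
  expect_equal(round(rep_$kappa, 3), 0.951)
  expect_equal(round(unname(rep_$perCategoryCI["deficient", ]), 1),
               c(70.2, 98.8))
  ## point estimates sit inside their intervals
  for (j in 1:3) {
    expect_gte(rep_$perCategory[j], rep_$perCategoryCI[j, 1] - 1e-9)
    expect_lte(rep_$perCategory[j], rep_$perCategoryCI[j, 2] + 1e-9)
  }
  expect_output(print(rep_), "overall agreement: 97.0%")
})
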