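# Dependent overlapping comparison: ten procedures.

OVERLAP_Z <- c("pearson1898", "olkin1967", "dunn1969", "steiger1980",
               "meng1992", "hittner2003")
OVERLAP_T <- c("hotelling1940", "williams1959", "hendrickson1970")

test_that("overlap statistics reproduce the reference example", {
  cmp <- cmp_overlap_ex()
  expect_equal(round(stat_of(cmp, "pearson1898"), 4), -2.7914)
  expect_equal(round(p_of(cmp, "pearson1898"), 4), 0.0052)
  expect_equal(round(stat_of(cmp, "hotelling1940"), 4), -2.8066)
  expect_equal(round(p_of(cmp, "hotelling1940"), 4), 0.0053)
  expect_equal(round(stat_of(cmp, "williams1959"), 4), -2.7743)
  expect_equal(round(p_of(cmp, "williams1959"), 4), 0.0059)
  expect_equal(round(stat_of(cmp, "dunn1969"), 4), -2.7595)
  expect_equal(round(p_of(cmp, "dunn1969"), 4), 0.0058)
  expect_equal(round(stat_of(cmp, "steiger1980"), 4), -2.7513)
  expect_equal(round(p_of(cmp, "steiger1980"), 4), 0.0059)
  expect_equal(round(p_of(cmp, "hendrickson1970"), 4), 0.0053)
  expect_equal(round(p_of(cmp, "meng1992"), 4), 0.0061)
  expect_equal(round(p_of(cmp, "hittner2003"), 4), 0.0059)
  expect_equal(round(ci_of(cmp, "meng1992"), 4), c(-0.3925, -0.0654))
  expect_equal(round(ci_of(cmp, "zou2007"), 4), c(-0.3689, -0.0630))

  for (lab in OVERLAP_T) expect_identical(df_of(cmp, lab), 288L)
  for (lab in names(cmp$tests)) expect_true(rejected(cmp, lab))
})

test_that("Olkin's z coincides with the Pearson-Filon z", {
  # the two published denominator forms are algebraically identical
  set.seed(11)
  for (i in 1:25) {
    r <- runif(3, -0.6, 0.6)
    cmp <- compare_corr_overlap(r[1], r[2], r[3], n = 50,
                                test = c("pearson1898", "olkin1967"))
    expect_equal(stat_of(cmp, "olkin1967"), stat_of(cmp, "pearson1898"),
                 tolerance = 1e-12)
  }
})

test_that("all ten procedures are null-centred and antisymmetric", {
  eq <- compare_corr_overlap(0.4, 0.4, 0.2, n = 80)
  for (lab in c(OVERLAP_Z, OVERLAP_T)) {
    expect_equal(stat_of(eq, lab), 0, info = lab)
    expect_equal(p_of(eq, lab), 1, info = lab)
  }
  # averaging-based variants collapse onto Dunn & Clark at equality
  expect_equal(stat_of(eq, "steiger1980"), stat_of(eq, "dunn1969"))
  expect_equal(stat_of(eq, "hittner2003"), stat_of(eq, "dunn1969"))
  # interval procedures symmetric about 0 at equality
  expect_equal(ci_of(eq, "zou2007")[1], -ci_of(eq, "zou2007")[2],
               tolerance = 1e-12)
  expect_equal(ci_of(eq, "meng1992")[1], -ci_of(eq, "meng1992")[2],
               tolerance = 1e-12)

  set.seed(22)
  for (i in 1:10) {
    r <- runif(3, -0.5, 0.5)
    a <- compare_corr_overlap(r[1], r[2], r[3], n = 60)
    b <- compare_corr_overlap(r[2], r[1], r[3], n = 60)
    for (lab in c(OVERLAP_Z, OVERLAP_T)) {
      expect_equal(stat_of(b, lab), -stat_of(a, lab), tolerance = 1e-10,
                   info = lab)
      expect_equal(p_of(b, lab), p_of(a, lab), tolerance = 1e-10, info = lab)
    }
  }
})

test_that("Meng's interval is centred on the Fisher-z difference", {
  cmp <- cmp_overlap_ex()
  dz <- atanh(EX_O$r.jk) - atanh(EX_O$r.jh)
  expect_equal(mean(ci_of(cmp, "meng1992")), dz, tolerance = 1e-12)
})

test_that("Zou's overlap interval reduces to the independent form at c = 0", {
  # r.kh chosen so the estimated correlation between r.jk and r.jh vanishes
  r.jk <- 0.3; r.jh <- 0.2; n <- 120
  # solve cov numerator = 0 for r.kh numerically
  f <- function(kh) kh * (1 - r.jk^2 - r.jh^2) -
    0.5 * r.jk * r.jh * (1 - r.jk^2 - r.jh^2 - kh^2)
  kh0 <- uniroot(f, c(0, 0.2), tol = 1e-14)$root
  ov <- compare_corr_overlap(r.jk, r.jh, kh0, n, test = "zou2007")
  ind <- compare_corr_indep(r.jk, r.jh, n, n, test = "zou2007")
  expect_equal(ci_of(ov, "zou2007"), ci_of(ind, "zou2007"), tolerance = 1e-10)
})

test_that("degenerate dependence structures raise computational errors", {
  # jointly impossible correlations can push the estimated correlation
  # between the two sample correlations past 1
  expect_warning(
    expect_error(
      compare_corr_overlap(0.99, 0.99, -0.99, n = 50, test = "dunn1969"),
      "2 - 2c"),
    "positive semi-definite")
  expect_warning(
    compare_corr_overlap(0.9, -0.9, 0.9, n = 50, test = "pearson1898"),
    "jointly impossible")
})
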