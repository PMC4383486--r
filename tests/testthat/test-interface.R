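# Raw-data front end, dispatch, selection, rendering, extraction methods.

test_that("pearson_correlation computes r with the documented guards", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1)
  set.seed(101)
  x <- rnorm(1e5); y <- rnorm(1e5)
  expect_lt(abs(pearson_correlation(x, y)), 0.02)
  expect_error(pearson_correlation(1:10, rep(1, 10)), "zero-variance")
  expect_error(pearson_correlation(1:3, 3:1), "at least 4")
  # incomplete pairs are dropped
  x[1:5] <- NA
  expect_equal(pearson_correlation(x, y),
               cor(x, y, use = "complete.obs"))
})

test_that("variable pairs dispatch to the correct case", {
  apt <- make_aptitude_fixture(seed = 7)

  ind <- compare_corr(~logic + intelligence.a | logic + intelligence.a, apt)
  expect_identical(ind$case, "independent")
  expect_named(ind$tests, c("fisher1925", "zou2007"))
  expect_identical(unname(ind$n), c(291L, 334L))

  ov <- compare_corr(~knowledge + intelligence.a | logic + intelligence.a,
                     apt$sample1)
  expect_identical(ov$case, "overlap")
  expect_identical(ov$var.map$j, "intelligence.a")  # shared variable is j
  expect_identical(ov$var.map$k, "knowledge")
  expect_identical(ov$var.map$h, "logic")
  expect_length(ov$tests, 10)

  nv <- compare_corr(~knowledge + intelligence.a | logic + intelligence.b,
                     apt$sample1)
  expect_identical(nv$case, "nonoverlap")
  expect_length(nv$tests, 6)

  expect_error(compare_corr(~logic + knowledge | knowledge + logic,
                            apt$sample1), "identical")
  expect_error(compare_corr(~logic + nonesuch | logic + knowledge,
                            apt$sample1), "nonesuch")
  # string form of the pair specification is equivalent
  ov2 <- compare_corr("~knowledge + intelligence.a | logic + intelligence.a",
                      apt$sample1)
  expect_equal(ov2$tests, ov$tests, tolerance = 1e-15)
})

test_that("a grouping column gives the same result as two tables", {
  apt <- make_aptitude_fixture(seed = 19)
  pooled <- rbind(cbind(apt$sample1, group = "g1"),
                  cbind(apt$sample2, group = "g2"))
  a <- compare_corr(~logic + intelligence.a | logic + intelligence.a,
                    pooled, by = "group")
  b <- compare_corr(~logic + intelligence.a | logic + intelligence.a,
                    apt$sample1, data2 = apt$sample2)
  expect_equal(a$tests, b$tests, tolerance = 1e-15)
})

test_that("raw-data and coefficient paths agree to numerical precision", {
  apt <- make_aptitude_fixture(seed = 3)
  d <- apt$sample1

  ov <- compare_corr(~knowledge + intelligence.a | logic + intelligence.a, d)
  ov_coef <- compare_corr_overlap(
    r.jk = pearson_correlation(d$intelligence.a, d$knowledge),
    r.jh = pearson_correlation(d$intelligence.a, d$logic),
    r.kh = pearson_correlation(d$knowledge, d$logic),
    n = nrow(d))
  expect_equal(ov$tests, ov_coef$tests, tolerance = 1e-12)

  nv <- compare_corr(~knowledge + intelligence.a | logic + intelligence.b, d)
  nv_coef <- compare_corr_nonoverlap(
    r.jk = pearson_correlation(d$knowledge, d$intelligence.a),
    r.hm = pearson_correlation(d$logic, d$intelligence.b),
    r.jh = pearson_correlation(d$knowledge, d$logic),
    r.jm = pearson_correlation(d$knowledge, d$intelligence.b),
    r.kh = pearson_correlation(d$intelligence.a, d$logic),
    r.km = pearson_correlation(d$intelligence.a, d$intelligence.b),
    n = nrow(d))
  expect_equal(nv$tests, nv_coef$tests, tolerance = 1e-12)

  ind <- compare_corr(~logic + intelligence.a | logic + intelligence.a, apt)
  ind_coef <- compare_corr_indep(
    r1.jk = pearson_correlation(apt$sample1$logic, apt$sample1$intelligence.a),
    r2.hm = pearson_correlation(apt$sample2$logic, apt$sample2$intelligence.a),
    n1 = 291, n2 = 334)
  expect_equal(ind$tests, ind_coef$tests, tolerance = 1e-12)
})

test_that("listwise deletion uses the union of the involved variables", {
  apt <- make_aptitude_fixture(seed = 5)
  d <- apt$sample1
  d$knowledge[1:10] <- NA   # rows missing only one variable of the three
  ov <- compare_corr(~knowledge + intelligence.a | logic + intelligence.a, d)
  expect_identical(unname(ov$n), 281L)  # all correlations share one n
})

test_that("the rendered report carries the documented lines", {
  txt_i <- format(cmp_indep_ex())
  expect_true(any(grepl("Group sizes: n1 = 291, n2 = 334", txt_i, fixed = TRUE)))
  expect_true(any(grepl("fisher1925: Fisher's z (1925)", txt_i, fixed = TRUE)))

  txt_o <- format(cmp_overlap_ex())
  expect_true(any(grepl("Difference: r.jk—r.jh = -0.2175", txt_o,
                        fixed = TRUE)))
  expect_true(any(grepl("Related correlation: r.kh = 0.0257", txt_o,
                        fixed = TRUE)))
  expect_true(any(grepl("Null hypothesis rejected (Interval does not include 0)",
                        txt_o, fixed = TRUE)))
  expect_true(any(grepl("Alternative hypothesis: r.jk is not equal to r.jh (two-sided)",
                        txt_o, fixed = TRUE)))

  # rendering is pure: same object, same text
  expect_identical(txt_o, format(cmp_overlap_ex()))

  # a zero-difference comparison retains every null hypothesis
  txt_eq <- format(compare_corr_overlap(0.3, 0.3, 0.1, 100))
  expect_false(any(grepl("rejected", txt_eq)))
  expect_true(any(grepl("Null hypothesis retained", txt_eq)))
})

test_that("test selection and threshold hypotheses shape the result set", {
  one <- cmp_overlap_ex(test = "zou2007")
  expect_length(one$tests, 1)
  two <- cmp_overlap_ex(test = c("hittner2003", "dunn1969"))
  # canonical report order is kept regardless of request order
  expect_named(two$tests, c("dunn1969", "hittner2003"))
  expect_error(cmp_overlap_ex(test = "fisher1925"), "valid labels")

  thr <- cmp_overlap_ex(null.value = 0.5)
  expect_named(thr$tests, "zou2007")
  expect_false(rejected(thr, "zou2007"))
  expect_true(any(grepl("absolute difference", format(thr))))
})

test_that("extraction methods expose statistics, intervals and the table", {
  cmp <- cmp_overlap_ex()
  tab <- as.data.frame(cmp)
  expect_identical(nrow(tab), 10L)
  expect_identical(tab$test[1], "pearson1898")
  expect_true(all(tab$rejected))
  expect_identical(tab$statistic.name[tab$test == "hotelling1940"], "t")
  expect_true(is.na(tab$statistic[tab$test == "zou2007"]))

  ci <- confint(cmp)
  expect_identical(rownames(ci), c("meng1992", "zou2007"))
  expect_identical(unname(attr(ci, "scale")), c("fisher.z", "r"))

  s <- summary(cmp)
  expect_s3_class(s, "summary.corcmp")
  expect_identical(s$table, tab)
})
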