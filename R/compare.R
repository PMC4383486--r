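# Coefficient-level comparison functions and assembly of "corcmp" objects.

.test_labels <- list(
  independent = c("fisher1925", "zou2007"),
  overlap = c("pearson1898", "hotelling1940", "williams1959", "olkin1967",
              "dunn1969", "hendrickson1970", "steiger1980", "meng1992",
              "hittner2003", "zou2007"),
  nonoverlap = c("pearson1898", "dunn1969", "steiger1980", "raghunathan1996",
                 "silver2004", "zou2007")
)

.test_descriptions <- c(
  fisher1925 = "Fisher's z (1925)",
  zou2007 = "Zou's (2007) confidence interval",
  pearson1898 = "Pearson and Filon's z (1898)",
  hotelling1940 = "Hotelling's t (1940)",
  williams1959 = "Williams' t (1959)",
  olkin1967 = "Olkin's z (1967)",
  dunn1969 = "Dunn and Clark's z (1969)",
  hendrickson1970 = paste("Hendrickson, Stanley, and Hills' (1970)",
                          "modification of Williams' t (1959)"),
  steiger1980 = paste("Steiger's (1980) modification of Dunn and Clark's z",
                      "(1969) using average correlations"),
  meng1992 = "Meng, Rosenthal, and Rubin's z (1992)",
  hittner2003 = paste("Hittner, May, and Silver's (2003) modification of",
                      "Dunn and Clark's z (1969) using a backtransformed",
                      "average Fisher's (1921) Z procedure"),
  raghunathan1996 = paste("Raghunathan, Rosenthal, and Rubin's (1996)",
                          "modification of Pearson and Filon's z (1898)"),
  silver2004 = paste("Silver, Hittner, and May's (2004) modification of",
                     "Dunn and Clark's z (1969) using a backtransformed",
                     "average Fisher's (1921) Z procedure")
)

.resolve_tests <- function(test, case, null.value) {
  valid <- .test_labels[[case]]
  if (null.value != 0) {
    # a nonzero threshold on |rho1 - rho2| is only testable through Zou's
    # interval; run it alone
    return("zou2007")
  }
  if (identical(test, "all") || is.null(test)) return(valid)
  test <- unique(as.character(test))
  bad <- setdiff(test, valid)
  if (length(bad)) {
    stop("unknown test label(s) for the ", case, " case: ",
         paste(bad, collapse = ", "), "\n  valid labels: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  valid[valid %in% test]  # keep canonical report order
}

.check_settings <- function(alternative, alpha, conf.level, null.value) {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  .check_prob(alpha, "alpha")
  .check_prob(conf.level, "conf.level")
  .check_null_value(null.value)
  list(alternative = alternative, alpha = alpha, conf.level = conf.level,
       null.value = null.value)
}

# Attach decision(s) to a kernel result.  p-based decisions compare p to
# alpha; CI-based decisions test whether the interval excludes the null
# difference (0, or the band [-null.value, null.value] when a threshold
# hypothesis is requested).
.finish_result <- function(res, label, settings) {
  res$label <- label
  res$description <- unname(.test_descriptions[label])
  if (!is.null(res$p.value)) {
    res$rejected <- res$p.value < settings$alpha
  }
  if (!is.null(res$conf.int)) {
    nv <- if (identical(res$conf.scale, "fisher.z")) 0 else settings$null.value
    l <- res$conf.int[1]; u <- res$conf.int[2]
    if (nv == 0) {
      res$ci.rejected <- l > 0 || u < 0
      res$ci.note <- if (res$ci.rejected) "Interval does not include 0"
                     else "Interval includes 0"
    } else {
      res$ci.rejected <- l > nv || u < -nv
      band <- paste0("[", format(-nv), ", ", format(nv), "]")
      res$ci.note <- if (res$ci.rejected)
        paste0("Interval lies outside ", band)
      else paste0("Interval does not lie outside ", band)
    }
    if (is.null(res$p.value)) res$rejected <- res$ci.rejected
  }
  res
}

.new_corcmp <- function(case, r, n, settings, tests, results,
                        labels1, labels2, var.map = NULL, data.name = NULL) {
  structure(list(case = case, r = r, n = n,
                 alternative = settings$alternative, alpha = settings$alpha,
                 conf.level = settings$conf.level,
                 null.value = settings$null.value,
                 difference = unname(r[[1]] - r[[2]]),
                 label1 = labels1, label2 = labels2,
                 var.map = var.map, data.name = data.name,
                 tests = results[tests]),
            class = "corcmp")
}

#' Compare two correlations from independent groups
#'
#' Tests the null hypothesis \eqn{\rho_1 = \rho_2} for two Pearson
#' correlations estimated in two disjoint samples.  Available procedures are
#' Fisher's (1925) z test on the Fisher-transformed difference and Zou's
#' (2007) confidence interval for \eqn{r_1 - r_2}.
#'
#' @param r1.jk Correlation between variables j and k in group 1.
#' @param r2.hm Correlation between variables h and m in group 2.
#' @param n1,n2 Group sizes; each must exceed 3.
#' @param alternative `"two.sided"` (default), `"greater"` (\eqn{\rho_1 >
#'   \rho_2}) or `"less"`.
#' @param test Character vector of test labels, or `"all"` (default).
#' @param alpha Significance level, default 0.05.
#' @param conf.level Confidence level for interval procedures, default 0.95.
#' @param null.value Hypothesised lower bound for the absolute difference
#'   \eqn{|\rho_1 - \rho_2|}.  When nonzero, only Zou's interval is computed
#'   and the null hypothesis \eqn{|\rho_1 - \rho_2| \le} `null.value` is
#'   rejected when the interval lies entirely outside
#'   `[-null.value, null.value]`.
#' @return An object of class `"corcmp"`; see [print.corcmp()].
#' @examples
#' compare_corr_indep(r1.jk = 0.3213, r2.hm = 0.2024, n1 = 291, n2 = 334)
#' @export
compare_corr_indep <- function(r1.jk, r2.hm, n1, n2,
                               alternative = "two.sided", test = "all",
                               alpha = 0.05, conf.level = 0.95,
                               null.value = 0) {
  .check_corr(r1.jk, "r1.jk"); .check_corr(r2.hm, "r2.hm")
  n1 <- .check_n(n1, "n1"); n2 <- .check_n(n2, "n2")
  settings <- .check_settings(alternative, alpha, conf.level, null.value)
  tests <- .resolve_tests(test, "independent", settings$null.value)

  results <- list(
    fisher1925 = .stat_fisher1925(r1.jk, r2.hm, n1, n2, settings$alternative),
    zou2007 = .stat_zou2007_indep(r1.jk, r2.hm, n1, n2, settings$conf.level)
  )
  results <- Map(.finish_result, results, names(results),
                 MoreArgs = list(settings = settings))

  .new_corcmp("independent", list(r1.jk = r1.jk, r2.hm = r2.hm),
              c(n1 = n1, n2 = n2), settings, tests, results,
              "r1.jk", "r2.hm")
}

#' Compare two dependent overlapping correlations
#'
#' Tests \eqn{\rho_{jk} = \rho_{jh}} for two correlations measured in the
#' same group that share the variable j.  The dependence between the two
#' sample correlations is driven by the related correlation \eqn{r_{kh}}.
#' Ten procedures are available; see [corcmp-package] for the list.
#'
#' A warning is issued when the implied 3x3 correlation matrix over
#' (j, k, h) is not positive semi-definite: such inputs are jointly
#' impossible as correlations of real data, although the test statistics
#' remain computable.
#'
#' @param r.jk,r.jh The two correlations being compared (shared variable j).
#' @param r.kh Related correlation between the non-shared variables k and h.
#' @param n Group size; must exceed 3.
#' @inheritParams compare_corr_indep
#' @return An object of class `"corcmp"`.
#' @examples
#' compare_corr_overlap(r.jk = 0.1038, r.jh = 0.3213, r.kh = 0.0257, n = 291)
#' @export
compare_corr_overlap <- function(r.jk, r.jh, r.kh, n,
                                 alternative = "two.sided", test = "all",
                                 alpha = 0.05, conf.level = 0.95,
                                 null.value = 0) {
  .check_corr(r.jk, "r.jk"); .check_corr(r.jh, "r.jh"); .check_corr(r.kh, "r.kh")
  n <- .check_n(n, "n")
  settings <- .check_settings(alternative, alpha, conf.level, null.value)
  tests <- .resolve_tests(test, "overlap", settings$null.value)

  R <- matrix(c(1, r.jk, r.jh,
                r.jk, 1, r.kh,
                r.jh, r.kh, 1), 3, 3,
              dimnames = list(c("j", "k", "h"), c("j", "k", "h")))
  if (!check_psd(R)) {
    warning("the supplied correlations do not form a positive semi-definite ",
            "3x3 matrix; they are jointly impossible as correlations of ",
            "real data", call. = FALSE)
  }

  alt <- settings$alternative
  kernels <- list(
    pearson1898 = function() .stat_pearson1898_overlap(r.jk, r.jh, r.kh, n, alt),
    hotelling1940 = function() .stat_hotelling1940(r.jk, r.jh, r.kh, n, alt),
    williams1959 = function() .stat_williams1959(r.jk, r.jh, r.kh, n, alt),
    olkin1967 = function() .stat_olkin1967(r.jk, r.jh, r.kh, n, alt),
    dunn1969 = function() .stat_dunn1969_overlap(r.jk, r.jh, r.kh, n, alt),
    hendrickson1970 = function() .stat_hendrickson1970(r.jk, r.jh, r.kh, n, alt),
    steiger1980 = function() .stat_steiger1980_overlap(r.jk, r.jh, r.kh, n, alt),
    meng1992 = function() .stat_meng1992(r.jk, r.jh, r.kh, n, alt,
                                         settings$conf.level),
    hittner2003 = function() .stat_hittner2003(r.jk, r.jh, r.kh, n, alt),
    zou2007 = function() .stat_zou2007_overlap(r.jk, r.jh, r.kh, n,
                                               settings$conf.level)
  )
  # only the selected kernels run, so a degeneracy in an unselected test
  # cannot abort the comparison
  results <- lapply(stats::setNames(tests, tests), function(lab) kernels[[lab]]())
  results <- Map(.finish_result, results, names(results),
                 MoreArgs = list(settings = settings))

  .new_corcmp("overlap", list(r.jk = r.jk, r.jh = r.jh, r.kh = r.kh),
              c(n = n), settings, tests, results, "r.jk", "r.jh")
}

#' Compare two dependent nonoverlapping correlations
#'
#' Tests \eqn{\rho_{jk} = \rho_{hm}} for two correlations measured in the
#' same group over four distinct variables (j, k) and (h, m).  The
#' dependence between the two sample correlations is driven by the four
#' related correlations \eqn{r_{jh}, r_{jm}, r_{kh}, r_{km}}, which must be
#' supplied by name.  Six procedures are available; see [corcmp-package].
#'
#' A warning is issued when the implied 4x4 correlation matrix over
#' (j, k, h, m) is not positive semi-definite.
#'
#' @param r.jk,r.hm The two correlations being compared.
#' @param r.jh,r.jm,r.kh,r.km The four related correlations.
#' @param n Group size; must exceed 3.
#' @inheritParams compare_corr_indep
#' @return An object of class `"corcmp"`.
#' @examples
#' compare_corr_nonoverlap(r.jk = 0.1038, r.hm = 0.2679, r.jh = 0.0257,
#'                         r.jm = 0.1713, r.kh = 0.3213, r.km = 0.4731,
#'                         n = 291)
#' @export
compare_corr_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km, n,
                                    alternative = "two.sided", test = "all",
                                    alpha = 0.05, conf.level = 0.95,
                                    null.value = 0) {
  for (nm in c("r.jk", "r.hm", "r.jh", "r.jm", "r.kh", "r.km")) {
    .check_corr(get(nm), nm)
  }
  n <- .check_n(n, "n")
  settings <- .check_settings(alternative, alpha, conf.level, null.value)
  tests <- .resolve_tests(test, "nonoverlap", settings$null.value)

  R <- matrix(c(1,    r.jk, r.jh, r.jm,
                r.jk, 1,    r.kh, r.km,
                r.jh, r.kh, 1,    r.hm,
                r.jm, r.km, r.hm, 1), 4, 4,
              dimnames = list(c("j", "k", "h", "m"), c("j", "k", "h", "m")))
  if (!check_psd(R)) {
    warning("the supplied correlations do not form a positive semi-definite ",
            "4x4 matrix; they are jointly impossible as correlations of ",
            "real data", call. = FALSE)
  }

  alt <- settings$alternative
  kernels <- list(
    pearson1898 = function() .stat_pearson1898_nonoverlap(r.jk, r.hm, r.jh,
                                                          r.jm, r.kh, r.km,
                                                          n, alt),
    dunn1969 = function() .stat_dunn1969_nonoverlap(r.jk, r.hm, r.jh, r.jm,
                                                    r.kh, r.km, n, alt),
    steiger1980 = function() .stat_steiger1980_nonoverlap(r.jk, r.hm, r.jh,
                                                          r.jm, r.kh, r.km,
                                                          n, alt),
    raghunathan1996 = function() .stat_raghunathan1996(r.jk, r.hm, r.jh, r.jm,
                                                       r.kh, r.km, n, alt),
    silver2004 = function() .stat_silver2004(r.jk, r.hm, r.jh, r.jm, r.kh,
                                             r.km, n, alt),
    zou2007 = function() .stat_zou2007_nonoverlap(r.jk, r.hm, r.jh, r.jm,
                                                  r.kh, r.km, n,
                                                  settings$conf.level)
  )
  results <- lapply(stats::setNames(tests, tests), function(lab) kernels[[lab]]())
  results <- Map(.finish_result, results, names(results),
                 MoreArgs = list(settings = settings))

  .new_corcmp("nonoverlap",
              list(r.jk = r.jk, r.hm = r.hm, r.jh = r.jh, r.jm = r.jm,
                   r.kh = r.kh, r.km = r.km),
              c(n = n), settings, tests, results, "r.jk", "r.hm")
}
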