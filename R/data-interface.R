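# Raw-data front end: Pearson correlation, variable-pair formula parsing,
# and case dispatch.

#' Pearson product-moment correlation
#'
#' Sample Pearson correlation between two numeric vectors, with the input
#' checks the comparison front end relies on: at least 4 complete pairs and
#' nonzero variance in both variables.  Incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The sample correlation.
#' @examples
#' pearson_correlation(1:10, (1:10)^2)
#' @export
pearson_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("'x' and 'y' must be numeric")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("at least 4 complete paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("cannot compute a correlation for a zero-variance variable")
  }
  stats::cor(x, y)
}

# Parse "~a + b | c + d" (formula object or string) into two variable pairs.
.parse_pairs <- function(formula) {
  s <- if (inherits(formula, "formula")) {
    paste(deparse(formula), collapse = " ")
  } else if (is.character(formula) && length(formula) == 1L) {
    formula
  } else {
    stop("'formula' must be a formula or a single string like '~a + b | c + d'")
  }
  s <- sub("^\\s*~", "", s)
  halves <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("the variable-pair specification must contain exactly one '|' ",
         "separating the two pairs")
  }
  pairs <- lapply(halves, function(h) {
    v <- trimws(strsplit(h, "+", fixed = TRUE)[[1]])
    v <- v[nzchar(v)]
    if (length(v) != 2L || anyDuplicated(v)) {
      stop("each side of '|' must name exactly two distinct variables")
    }
    v
  })
  names(pairs) <- c("pair1", "pair2")
  pairs
}

.corr_from <- function(data, v1, v2) {
  pearson_correlation(data[[v1]], data[[v2]])
}

.check_columns <- function(data, vars, label) {
  if (!is.data.frame(data)) stop("'", label, "' must be a data frame")
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("variable(s) not found in ", label, ": ",
         paste(missing, collapse = ", "))
  }
  invisible(data)
}

#' Compare two correlations computed from raw data
#'
#' Computes the required Pearson correlations from one or two data sets and
#' dispatches to the matching coefficient-level comparison.  The variables
#' entering each correlation are given as a pair specification
#' `~var1 + var2 | var3 + var4` (formula or string), with `|` separating the
#' two pairs.
#'
#' Dispatch follows the structure of the input:
#' * two data sets (via `data2`, a two-element list in `data`, or a `by`
#'   grouping column) — **independent groups**: the first pair is correlated
#'   in the first group, the second pair in the second group;
#' * one data set, pairs sharing exactly one variable — **dependent
#'   overlapping** comparison, with the shared variable as j;
#' * one data set, disjoint pairs — **dependent nonoverlapping** comparison;
#' * one data set, identical pairs — an error (nothing to compare).
#'
#' For the dependent cases all correlations, including the related ones, are
#' computed on the rows that are complete for the union of the involved
#' variables (listwise deletion), so that every coefficient shares the same
#' group size — as the dependent-test derivations assume.
#'
#' @param formula Pair specification, e.g. `~knowledge + intelligence.a |
#'   logic + intelligence.a`.
#' @param data A data frame, or a list of two data frames for the
#'   independent case.
#' @param data2 Optional second data frame (independent case).
#' @param by Optional name of a two-level grouping column in `data`
#'   (independent case from a single table).
#' @inheritParams compare_corr_indep
#' @return An object of class `"corcmp"`.  The report echoes which data
#'   variables play the roles j, k, h, m.
#' @examples
#' apt <- make_aptitude_fixture(seed = 1)
#' compare_corr(~knowledge + intelligence.a | logic + intelligence.a,
#'              apt$sample1)
#' @export
compare_corr <- function(formula, data, data2 = NULL, by = NULL,
                         alternative = "two.sided", test = "all",
                         alpha = 0.05, conf.level = 0.95, null.value = 0) {
  pairs <- .parse_pairs(formula)
  p1 <- pairs$pair1; p2 <- pairs$pair2

  data.name <- NULL
  if (is.data.frame(data)) {
    if (!is.null(by)) {
      .check_columns(data, by, "data")
      g <- data[[by]]
      lev <- unique(g[!is.na(g)])
      if (length(lev) != 2L) {
        stop("grouping column '", by, "' must have exactly 2 levels, found ",
             length(lev))
      }
      data2 <- data[g == lev[2] & !is.na(g), , drop = FALSE]
      data <- data[g == lev[1] & !is.na(g), , drop = FALSE]
      data.name <- paste0(by, " = ", as.character(lev))
    }
  } else if (is.list(data) && length(data) == 2L &&
             all(vapply(data, is.data.frame, TRUE))) {
    data.name <- names(data)
    if (is.null(data.name) || !all(nzchar(data.name))) {
      data.name <- c("sample1", "sample2")
    }
    data2 <- data[[2]]
    data <- data[[1]]
  } else {
    stop("'data' must be a data frame or a list of two data frames")
  }

  if (!is.null(data2)) {
    # independent groups: pair1 in group 1, pair2 in group 2
    .check_columns(data, p1, "data")
    .check_columns(data2, p2, "data2")
    d1 <- data[stats::complete.cases(data[p1]), p1, drop = FALSE]
    d2 <- data2[stats::complete.cases(data2[p2]), p2, drop = FALSE]
    out <- compare_corr_indep(
      r1.jk = .corr_from(d1, p1[1], p1[2]),
      r2.hm = .corr_from(d2, p2[1], p2[2]),
      n1 = nrow(d1), n2 = nrow(d2),
      alternative = alternative, test = test, alpha = alpha,
      conf.level = conf.level, null.value = null.value)
    out$var.map <- list(j = p1[1], k = p1[2], h = p2[1], m = p2[2])
    out$data.name <- data.name %||% c("sample1", "sample2")
    return(out)
  }

  common <- intersect(p1, p2)
  if (length(common) == 2L) {
    stop("the two variable pairs are identical; there is nothing to compare")
  }
  vars <- union(p1, p2)
  .check_columns(data, vars, "data")
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]

  if (length(common) == 1L) {
    # overlap: shared variable is j, the partners are k and h
    j <- common
    k <- setdiff(p1, j)
    h <- setdiff(p2, j)
    out <- compare_corr_overlap(
      r.jk = .corr_from(d, j, k),
      r.jh = .corr_from(d, j, h),
      r.kh = .corr_from(d, k, h),
      n = nrow(d),
      alternative = alternative, test = test, alpha = alpha,
      conf.level = conf.level, null.value = null.value)
    out$var.map <- list(j = j, k = k, h = h)
  } else {
    j <- p1[1]; k <- p1[2]; h <- p2[1]; m <- p2[2]
    out <- compare_corr_nonoverlap(
      r.jk = .corr_from(d, j, k),
      r.hm = .corr_from(d, h, m),
      r.jh = .corr_from(d, j, h),
      r.jm = .corr_from(d, j, m),
      r.kh = .corr_from(d, k, h),
      r.km = .corr_from(d, k, m),
      n = nrow(d),
      alternative = alternative, test = test, alpha = alpha,
      conf.level = conf.level, null.value = null.value)
    out$var.map <- list(j = j, k = k, h = h, m = m)
  }
  out$data.name <- data.name %||% "data"
  out
}
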