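# S3 methods for "corcmp" objects: report rendering and extraction.

.fmt4 <- function(x) sprintf("%.4f", x)

# raw differences are shown rounded to 4 decimals with trailing zeros
# trimmed (so -0.1640 renders as -0.164)
.fmt_diff <- function(x) {
  format(round(x, 4), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

.case_header <- c(
  independent = "Results of a comparison of two correlations based on independent groups",
  overlap = "Results of a comparison of two overlapping correlations based on dependent groups",
  nonoverlap = "Results of a comparison of two nonoverlapping correlations based on dependent groups"
)

.alt_phrase <- function(alternative, l1, l2) {
  switch(alternative,
         two.sided = paste0(l1, " is not equal to ", l2, " (two-sided)"),
         greater = paste0(l1, " is greater than ", l2, " (one-sided)"),
         less = paste0(l1, " is less than ", l2, " (one-sided)"))
}

#' Render a correlation-comparison report as text
#'
#' Produces the plain-text report for a `"corcmp"` object as a character
#' vector of lines: a header identifying the case, the compared correlations
#' and their difference, the related correlation(s), the variable-to-role
#' mapping when the comparison was computed from raw data, the group
#' size(s), the hypotheses and alpha, and one block per test with its
#' statistic, degrees of freedom, p-value, confidence interval and decision.
#' Statistics, p-values and interval bounds are shown to 4 decimal places.
#' Rendering is deterministic: identical objects give identical text.
#'
#' @param x A `"corcmp"` object.
#' @param ... Unused.
#' @return Character vector of report lines.
#' @export
format.corcmp <- function(x, ...) {
  l1 <- x$label1; l2 <- x$label2
  dash <- "—"  # em dash separating the two labels in difference lines
  pair_lab <- paste0(l1, dash, l2)

  vn <- function(role) x$var.map[[role]]
  paren <- function(a, b) {
    if (is.null(x$var.map)) "" else paste0(" (", a, ", ", b, ")")
  }
  lines <- c(
    paste0("  ", .case_header[[x$case]]),
    "",
    if (x$case == "independent") {
      paste0("Comparison between ", l1, paren(vn("j"), vn("k")), " = ",
             .fmt4(x$r[[1]]), " and ", l2, paren(vn("h"), vn("m")), " = ",
             .fmt4(x$r[[2]]))
    } else if (x$case == "overlap") {
      paste0("Comparison between ", l1, paren(vn("j"), vn("k")), " = ",
             .fmt4(x$r[[1]]), " and ", l2, paren(vn("j"), vn("h")), " = ",
             .fmt4(x$r[[2]]))
    } else {
      paste0("Comparison between ", l1, paren(vn("j"), vn("k")), " = ",
             .fmt4(x$r[[1]]), " and ", l2, paren(vn("h"), vn("m")), " = ",
             .fmt4(x$r[[2]]))
    },
    paste0("Difference: ", pair_lab, " = ", .fmt_diff(x$difference))
  )

  if (x$case == "overlap") {
    lines <- c(lines, paste0("Related correlation: r.kh = ", .fmt4(x$r$r.kh)))
  } else if (x$case == "nonoverlap") {
    lines <- c(lines, paste0(
      "Related correlations: r.jh = ", .fmt4(x$r$r.jh),
      ", r.jm = ", .fmt4(x$r$r.jm),
      ", r.kh = ", .fmt4(x$r$r.kh),
      ", r.km = ", .fmt4(x$r$r.km)))
  }

  if (!is.null(x$var.map)) {
    if (x$case == "independent") {
      dn <- x$data.name %||% c("sample1", "sample2")
      lines <- c(lines, paste0(
        "Data: ", dn[1], ": j = ", vn("j"), ", k = ", vn("k"),
        "; ", dn[2], ": h = ", vn("h"), ", m = ", vn("m")))
    } else {
      dn <- (x$data.name %||% "data")[1]
      roles <- if (x$case == "overlap") c("j", "k", "h") else c("j", "k", "h", "m")
      lines <- c(lines, paste0(
        "Data: ", dn, ": ",
        paste(vapply(roles, function(r) paste0(r, " = ", vn(r)), ""),
              collapse = ", ")))
    }
  }

  lines <- c(lines,
             if (x$case == "independent") {
               paste0("Group sizes: n1 = ", x$n[["n1"]], ", n2 = ", x$n[["n2"]])
             } else {
               paste0("Group size: n = ", x$n[["n"]])
             })

  if (x$null.value == 0) {
    lines <- c(lines,
               paste0("Null hypothesis: ", l1, " is equal to ", l2),
               paste0("Alternative hypothesis: ",
                      .alt_phrase(x$alternative, l1, l2)))
  } else {
    nv <- format(x$null.value)
    lines <- c(lines,
               paste0("Null hypothesis: the absolute difference between ", l1,
                      " and ", l2, " is equal to or less than ", nv),
               paste0("Alternative hypothesis: the absolute difference between ",
                      l1, " and ", l2, " is greater than ", nv))
  }
  lines <- c(lines, paste0("Alpha: ", format(x$alpha)))

  pct <- format(100 * x$conf.level, drop0trailing = TRUE)
  for (res in x$tests) {
    lines <- c(lines, "", paste0(res$label, ": ", res$description))
    if (!is.null(res$statistic)) {
      stat_name <- names(res$statistic)
      piece <- paste0(stat_name, " = ", .fmt4(res$statistic))
      if (!is.null(res$df)) piece <- paste0(piece, ", df = ", res$df)
      piece <- paste0(piece, ", p-value = ", .fmt4(res$p.value))
      lines <- c(lines, paste0("  ", piece),
                 paste0("  Null hypothesis ",
                        if (res$rejected) "rejected" else "retained"))
    }
    if (!is.null(res$conf.int)) {
      ci_lab <- if (identical(res$conf.scale, "fisher.z")) {
        paste0(pair_lab, " (Fisher z scale)")
      } else pair_lab
      lines <- c(lines,
                 paste0("  ", pct, "% confidence interval for ", ci_lab, ": ",
                        .fmt4(res$conf.int[1]), " ", .fmt4(res$conf.int[2])),
                 paste0("  Null hypothesis ",
                        if (res$ci.rejected) "rejected" else "retained",
                        " (", res$ci.note, ")"))
    }
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname format.corcmp
#' @export
print.corcmp <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Tabulate the results of a correlation comparison
#'
#' @param x A `"corcmp"` object.
#' @param row.names,optional,... Passed on conventionally; unused.
#' @return A data frame with one row per test: `test`, `statistic.name`,
#'   `statistic`, `df`, `p.value`, `ci.lower`, `ci.upper`, `ci.scale`,
#'   `rejected`.
#' @export
as.data.frame.corcmp <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$tests, function(res) {
    data.frame(
      test = res$label,
      statistic.name = if (is.null(res$statistic)) NA_character_
                       else names(res$statistic),
      statistic = if (is.null(res$statistic)) NA_real_
                  else unname(res$statistic),
      df = if (is.null(res$df)) NA_integer_ else as.integer(res$df),
      p.value = res$p.value %||% NA_real_,
      ci.lower = if (is.null(res$conf.int)) NA_real_ else res$conf.int[1],
      ci.upper = if (is.null(res$conf.int)) NA_real_ else res$conf.int[2],
      ci.scale = res$conf.scale %||% NA_character_,
      rejected = res$rejected,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.corcmp <- function(object, ...) {
  structure(list(report = object, table = as.data.frame(object)),
            class = "summary.corcmp")
}

#' @export
print.summary.corcmp <- function(x, ...) {
  print(x$report)
  cat("\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Confidence intervals from a correlation comparison
#'
#' Extracts the interval procedures (Zou's interval on the correlation-
#' difference scale and, for the overlapping case, Meng's interval on the
#' Fisher-z difference scale) from a `"corcmp"` object.
#'
#' @param object A `"corcmp"` object.
#' @param parm Unused (all available intervals are returned).
#' @param level Unused; intervals are computed at the `conf.level` the
#'   comparison was run with.
#' @param ... Unused.
#' @return A matrix with one row per interval procedure and columns
#'   `lower` and `upper`; the row name carries the test label, and the
#'   attribute `"scale"` records the scale of each row.
#' @export
confint.corcmp <- function(object, parm = NULL, level = NULL, ...) {
  keep <- Filter(function(res) !is.null(res$conf.int), object$tests)
  if (!length(keep)) {
    stop("no confidence-interval procedure among the computed tests")
  }
  out <- t(vapply(keep, function(res) res$conf.int, numeric(2)))
  colnames(out) <- c("lower", "upper")
  structure(out, conf.level = object$conf.level,
            scale = vapply(keep, function(res) res$conf.scale, ""))
}
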