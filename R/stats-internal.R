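# Test-statistic kernels.  Each takes plain numeric inputs (already
# validated) and returns list(statistic, df, p.value, conf.int, conf.scale).
# The sign convention throughout is first correlation minus second.

# determinant of the 3x3 correlation matrix of (j, k, h)
.det3 <- function(r.jk, r.jh, r.kh) {
  1 - r.jk^2 - r.jh^2 - r.kh^2 + 2 * r.jk * r.jh * r.kh
}

# Estimated correlation between the sample correlations r.jk and r.jh
# (overlapping case).  Evaluated at arbitrary correlation arguments so the
# Steiger/Hittner variants can plug in averaged values.
.cov_overlap <- function(r.jk, r.jh, r.kh) {
  num <- r.kh * (1 - r.jk^2 - r.jh^2) -
    0.5 * r.jk * r.jh * (1 - r.jk^2 - r.jh^2 - r.kh^2)
  num / ((1 - r.jk^2) * (1 - r.jh^2))
}

# Pearson-Filon covariance term for nonoverlapping r.jk and r.hm, and the
# corresponding correlation between the two sample correlations.
.psi_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km) {
  0.5 * r.jk * r.hm * (r.jh^2 + r.jm^2 + r.kh^2 + r.km^2) +
    r.jh * r.km + r.jm * r.kh -
    (r.jk * r.jh * r.jm + r.jk * r.kh * r.km +
       r.hm * r.jh * r.kh + r.hm * r.jm * r.km)
}

.cov_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km) {
  .psi_nonoverlap(r.jk, r.hm, r.jh, r.jm, r.kh, r.km) /
    ((1 - r.jk^2) * (1 - r.hm^2))
}

.z_result <- function(z, alternative) {
  list(statistic = c(z = z), df = NULL,
       p.value = p_from_statistic(z, "z", alternative = alternative),
       conf.int = NULL, conf.scale = NULL)
}

.t_result <- function(t, df, alternative) {
  list(statistic = c(t = t), df = df,
       p.value = p_from_statistic(t, "t", df = df, alternative = alternative),
       conf.int = NULL, conf.scale = NULL)
}

# Dunn & Clark style z from a Fisher-Z difference and a correlation c
# between the two sample correlations.
.dunn_z <- function(z1, z2, c, n, label) {
  if (2 - 2 * c <= 0) {
    stop("cannot compute ", label, ": estimated correlation between the two ",
         "sample correlations is ", format(c),
         ", giving a non-positive variance term 2 - 2c", call. = FALSE)
  }
  (z1 - z2) * sqrt((n - 3) / (2 - 2 * c))
}

# Zou (2007) MOVER interval for a difference of two correlations whose
# estimates have correlation c (c = 0 gives the independent-groups interval).
.zou_interval <- function(r1, r2, l1, u1, l2, u2, c) {
  lower <- r1 - r2 -
    sqrt((r1 - l1)^2 + (u2 - r2)^2 - 2 * c * (r1 - l1) * (u2 - r2))
  upper <- r1 - r2 +
    sqrt((u1 - r1)^2 + (r2 - l2)^2 - 2 * c * (u1 - r1) * (r2 - l2))
  c(lower, upper)
}

# --- independent groups ----------------------------------------------------

.stat_fisher1925 <- function(r1.jk, r2.hm, n1, n2, alternative) {
  z <- (fisher_r_to_z(r1.jk) - fisher_r_to_z(r2.hm)) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  .z_result(z, alternative)
}

.stat_zou2007_indep <- function(r1.jk, r2.hm, n1, n2, conf.level) {
  ci1 <- single_corr_ci(r1.jk, n1, conf.level)
  ci2 <- single_corr_ci(r2.hm, n2, conf.level)
  ci <- .zou_interval(r1.jk, r2.hm, ci1[1], ci1[2], ci2[1], ci2[2], c = 0)
  list(statistic = NULL, df = NULL, p.value = NULL,
       conf.int = ci, conf.scale = "r")
}

# --- dependent groups, overlapping variables -------------------------------

.stat_pearson1898_overlap <- function(r.jk, r.jh, r.kh, n, alternative) {
  k <- r.kh * (1 - r.jk^2 - r.jh^2) -
    0.5 * r.jk * r.jh * (1 - r.jk^2 - r.jh^2 - r.kh^2)
  z <- sqrt(n) * (r.jk - r.jh) /
    sqrt((1 - r.jk^2)^2 + (1 - r.jh^2)^2 - 2 * k)
  .z_result(z, alternative)
}

.stat_hotelling1940 <- function(r.jk, r.jh, r.kh, n, alternative) {
  d <- .det3(r.jk, r.jh, r.kh)
  if (d <= 0) {
    stop("cannot compute hotelling1940: the 3x3 correlation matrix has ",
         "non-positive determinant ", format(d), call. = FALSE)
  }
  t <- (r.jk - r.jh) * sqrt((n - 3) * (1 + r.kh)) / sqrt(2 * d)
  .t_result(t, n - 3L, alternative)
}

.stat_williams1959 <- function(r.jk, r.jh, r.kh, n, alternative) {
  d <- .det3(r.jk, r.jh, r.kh)
  r.bar <- (r.jk + r.jh) / 2
  denom <- 2 * d * (n - 1) / (n - 3) + r.bar^2 * (1 - r.kh)^3
  if (denom <= 0) {
    stop("cannot compute williams1959: non-positive variance term", call. = FALSE)
  }
  t <- (r.jk - r.jh) * sqrt((n - 1) * (1 + r.kh)) / sqrt(denom)
  .t_result(t, n - 3L, alternative)
}

.stat_olkin1967 <- function(r.jk, r.jh, r.kh, n, alternative) {
  z <- (r.jk - r.jh) * sqrt(n) /
    sqrt((1 - r.jk^2)^2 + (1 - r.jh^2)^2 - 2 * r.kh^3 -
           (2 * r.kh - r.jk * r.jh) * (1 - r.jk^2 - r.jh^2 - r.kh^2))
  .z_result(z, alternative)
}

.stat_dunn1969_overlap <- function(r.jk, r.jh, r.kh, n, alternative) {
  c <- .cov_overlap(r.jk, r.jh, r.kh)
  z <- .dunn_z(fisher_r_to_z(r.jk), fisher_r_to_z(r.jh), c, n, "dunn1969")
  .z_result(z, alternative)
}

.stat_hendrickson1970 <- function(r.jk, r.jh, r.kh, n, alternative) {
  d <- .det3(r.jk, r.jh, r.kh)
  denom <- 2 * d + (r.jk - r.jh)^2 * (1 - r.kh)^3 / (4 * (n - 1))
  if (denom <= 0) {
    stop("cannot compute hendrickson1970: non-positive variance term",
         call. = FALSE)
  }
  t <- (r.jk - r.jh) * sqrt((n - 3) * (1 + r.kh)) / sqrt(denom)
  .t_result(t, n - 3L, alternative)
}

.stat_steiger1980_overlap <- function(r.jk, r.jh, r.kh, n, alternative) {
  r.bar <- (r.jk + r.jh) / 2
  c <- .cov_overlap(r.bar, r.bar, r.kh)
  z <- .dunn_z(fisher_r_to_z(r.jk), fisher_r_to_z(r.jh), c, n, "steiger1980")
  .z_result(z, alternative)
}

.stat_meng1992 <- function(r.jk, r.jh, r.kh, n, alternative, conf.level) {
  r.sq.bar <- (r.jk^2 + r.jh^2) / 2
  f <- (1 - r.kh) / (2 * (1 - r.sq.bar))
  if (f > 1) f <- 1  # cap per the original reference
  h <- (1 - f * r.sq.bar) / (1 - r.sq.bar)
  dz <- fisher_r_to_z(r.jk) - fisher_r_to_z(r.jh)
  v <- 2 * (1 - r.kh) * h / (n - 3)
  z <- dz / sqrt(v)
  q <- stats::qnorm((1 + conf.level) / 2)
  res <- .z_result(z, alternative)
  # interval on the Fisher-Z difference scale; its midpoint is exactly dz
  res$conf.int <- c(dz - q * sqrt(v), dz + q * sqrt(v))
  res$conf.scale <- "fisher.z"
  res
}

.stat_hittner2003 <- function(r.jk, r.jh, r.kh, n, alternative) {
  r.bar <- fisher_z_to_r((fisher_r_to_z(r.jk) + fisher_r_to_z(r.jh)) / 2)
  c <- .cov_overlap(r.bar, r.bar, r.kh)
  z <- .dunn_z(fisher_r_to_z(r.jk), fisher_r_to_z(r.jh), c, n, "hittner2003")
  .z_result(z, alternative)
}

.stat_zou2007_overlap <- function(r.jk, r.jh, r.kh, n, conf.level) {
  c <- .cov_overlap(r.jk, r.jh, r.kh)
  ci1 <- single_corr_ci(r.jk, n, conf.level)
  ci2 <- single_corr_ci(r.jh, n, conf.level)
  ci <- .zou_interval(r.jk, r.jh, ci1[1], ci1[2], ci2[1], ci2[2], c)
  list(statistic = NULL, df = NULL, p.value = NULL,
       conf.int = ci, conf.scale = "r")
}

# --- dependent groups, nonoverlapping variables ----------------------------

.stat_pearson1898_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km,
                                         n, alternative) {
  psi <- .psi_nonoverlap(r.jk, r.hm, r.jh, r.jm, r.kh, r.km)
  z <- sqrt(n) * (r.jk - r.hm) /
    sqrt((1 - r.jk^2)^2 + (1 - r.hm^2)^2 - 2 * psi)
  .z_result(z, alternative)
}

.stat_dunn1969_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km,
                                      n, alternative) {
  c <- .cov_nonoverlap(r.jk, r.hm, r.jh, r.jm, r.kh, r.km)
  z <- .dunn_z(fisher_r_to_z(r.jk), fisher_r_to_z(r.hm), c, n, "dunn1969")
  .z_result(z, alternative)
}

.stat_steiger1980_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km,
                                         n, alternative) {
  r.bar <- (r.jk + r.hm) / 2
  c <- .cov_nonoverlap(r.bar, r.bar, r.jh, r.jm, r.kh, r.km)
  z <- .dunn_z(fisher_r_to_z(r.jk), fisher_r_to_z(r.hm), c, n, "steiger1980")
  .z_result(z, alternative)
}

.stat_raghunathan1996 <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km,
                                  n, alternative) {
  c <- .cov_nonoverlap(r.jk, r.hm, r.jh, r.jm, r.kh, r.km)
  if (1 - c <= 0) {
    stop("cannot compute raghunathan1996: estimated correlation between the ",
         "two sample correlations is ", format(c), call. = FALSE)
  }
  z <- sqrt((n - 3) / 2) * (fisher_r_to_z(r.jk) - fisher_r_to_z(r.hm)) /
    sqrt(1 - c)
  .z_result(z, alternative)
}

.stat_silver2004 <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km,
                             n, alternative) {
  r.bar <- fisher_z_to_r((fisher_r_to_z(r.jk) + fisher_r_to_z(r.hm)) / 2)
  c <- .cov_nonoverlap(r.bar, r.bar, r.jh, r.jm, r.kh, r.km)
  z <- .dunn_z(fisher_r_to_z(r.jk), fisher_r_to_z(r.hm), c, n, "silver2004")
  .z_result(z, alternative)
}

.stat_zou2007_nonoverlap <- function(r.jk, r.hm, r.jh, r.jm, r.kh, r.km,
                                     n, conf.level) {
  c <- .cov_nonoverlap(r.jk, r.hm, r.jh, r.jm, r.kh, r.km)
  ci1 <- single_corr_ci(r.jk, n, conf.level)
  ci2 <- single_corr_ci(r.hm, n, conf.level)
  ci <- .zou_interval(r.jk, r.hm, ci1[1], ci1[2], ci2[1], ci2[2], c)
  list(statistic = NULL, df = NULL, p.value = NULL,
       conf.int = ci, conf.scale = "r")
}
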