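# Worked-example inputs used across the test files.

# independent groups: logic vs intelligence.a in two samples
EX_I <- list(r1.jk = 0.3213, r2.hm = 0.2024, n1 = 291, n2 = 334)

# dependent overlapping: r.jk vs r.jh sharing j, n = 291
EX_O <- list(r.jk = 0.1038, r.jh = 0.3213, r.kh = 0.0257, n = 291)

# dependent nonoverlapping: r.jk vs r.hm with four related correlations
EX_N <- list(r.jk = 0.1038, r.hm = 0.2679, r.jh = 0.0257, r.jm = 0.1713,
             r.kh = 0.3213, r.km = 0.4731, n = 291)

cmp_indep_ex <- function(...) do.call(compare_corr_indep, c(EX_I, list(...)))
cmp_overlap_ex <- function(...) do.call(compare_corr_overlap, c(EX_O, list(...)))
cmp_nonoverlap_ex <- function(...) do.call(compare_corr_nonoverlap, c(EX_N, list(...)))

stat_of <- function(cmp, label) unname(cmp$tests[[label]]$statistic)
p_of <- function(cmp, label) cmp$tests[[label]]$p.value
ci_of <- function(cmp, label) cmp$tests[[label]]$conf.int
df_of <- function(cmp, label) cmp$tests[[label]]$df
rejected <- function(cmp, label) cmp$tests[[label]]$rejected
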