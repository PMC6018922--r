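#' Minor-variant frequencies in genome and transcriptome
#'
#' For each biallelic site, the minor variant is the base receiving fewer
#' transcriptome reads (ties broken towards the lexicographically smaller
#' base, so the choice is deterministic).  Its frequency is computed as a
#' proportion of the total site depth separately in the transcriptome and
#' in the genome.  Because the minor base is defined on the transcriptome,
#' `f_transcriptome <= 0.5` always, while the genomic frequency of that
#' same base may exceed 0.5.  Sites with zero total depth in either data
#' set are dropped; the number dropped is reported as the `n_dropped`
#' attribute.
#'
#' @param snp SNP depth `data.frame` as returned by [read_snp_table()].
#' @return A `data.frame` with `gene_id`, `position`, `minor_base`,
#'   `f_genome`, `f_transcriptome`, `total_depth_genome`,
#'   `total_depth_transcriptome`.
#' @export
minor_frequencies <- function(snp) {
  tg <- snp$g_depth_a + snp$g_depth_b
  tt <- snp$t_depth_a + snp$t_depth_b
  keep <- tg > 0 & tt > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " site(s) dropped for zero total depth")
  }
  d <- snp[keep, , drop = FALSE]
  tg <- tg[keep]; tt <- tt[keep]
  minor_is_a <- d$t_depth_a < d$t_depth_b |
    (d$t_depth_a == d$t_depth_b & d$base_a < d$base_b)
  out <- data.frame(
    gene_id = d$gene_id, position = d$position,
    minor_base = ifelse(minor_is_a, d$base_a, d$base_b),
    f_genome = ifelse(minor_is_a, d$g_depth_a, d$g_depth_b) / tg,
    f_transcriptome = ifelse(minor_is_a, d$t_depth_a, d$t_depth_b) / tt,
    total_depth_genome = tg, total_depth_transcriptome = tt,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Correlate minor-variant frequencies between transcriptome and genome
#'
#' Ordinary least squares of the transcriptome frequency on the genome
#' frequency across sites.  Under equal per-copy expression the two
#' frequencies share the same expectation at every site, so the regression
#' slope tends to 1 with growing depth; silenced or down-regulated copies
#' pull the transcriptome frequency away from the allele-dosage
#' expectation and weaken the correlation.
#'
#' @param pairs Frequency pairs from [minor_frequencies()].
#' @return An `ase_result`: list with `n_sites`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided t test on the slope).
#' @export
ase_correlation <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 sites")
  x <- pairs$f_genome
  y <- pairs$f_transcriptome
  if (stats::var(x) == 0) stop("uninformative sites: no variance in genome frequencies")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(n_sites = nrow(pairs),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4]),
            class = "ase_result")
}

#' @export
print.ase_result <- function(x, ...) {
  cat(sprintf(
    "ase_result: %d sites; slope = %.3f, R^2 = %.3f, p = %.3g\n",
    x$n_sites, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
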