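#' Filter qPCR measurements by amplification efficiency
#'
#' Retains measurements with efficiency in `[min_efficiency,
#' max_efficiency]` (bounds inclusive; the exclusion rule is strictly
#' below/above the bounds).  Efficiency is on the fold-change scale, where
#' 2 means perfect per-cycle doubling; values above 2.2 trip a unit hint
#' because they usually mean the input is on the percentage scale (e.g. 95
#' for 95%).  Amplicons losing all their measurements are dropped with a
#' warning.
#'
#' @param measures Measurement `data.frame` (`sample_id`, `gene_id`,
#'   `amplicon_id`, `replicate_index`, `ct`, `efficiency`).
#' @param min_efficiency,max_efficiency Retention bounds.
#' @return The retained rows; rejected rows attached as the `rejected`
#'   attribute.
#' @export
filter_efficiency <- function(measures, min_efficiency = 1.85,
                              max_efficiency = 2.1) {
  if (any(measures$efficiency > 2.2)) {
    stop("efficiency above 2.2 looks like a percentage-scale value; ",
         "supply fold amplification per cycle (2 = doubling)")
  }
  if (any(measures$efficiency <= 1)) stop("efficiency must exceed 1")
  keep <- measures$efficiency >= min_efficiency &
    measures$efficiency <= max_efficiency
  lost <- setdiff(unique(measures$amplicon_id),
                  unique(measures$amplicon_id[keep]))
  if (length(lost) > 0) {
    warning("amplicon(s) dropped entirely by the efficiency filter: ",
            paste(lost, collapse = ", "))
  }
  out <- measures[keep, , drop = FALSE]
  attr(out, "rejected") <- measures[!keep, , drop = FALSE]
  out
}

# per-amplicon mean Ct, its sampling variance, and the efficiency
aggregate_replicates <- function(measures) {
  sp <- split(measures, measures$amplicon_id)
  do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(amplicon_id = d$amplicon_id[1], gene_id = d$gene_id[1],
               efficiency = d$efficiency[1], mean_ct = mean(d$ct),
               var_mean_ct = if (n > 1) stats::var(d$ct) / n else 0,
               n_replicates = n, stringsAsFactors = FALSE)
  }))
}

#' Efficiency-corrected relative quantity (Pfaffl method)
#'
#' Per-amplicon template quantity is `Q = E^(-mean Ct)`; the target's
#' relative copy number is `Q_target` over the mean of the reference
#' amplicons' quantities.  With all efficiencies equal to 2 this reduces to
#' the classical `2^(Ct_ref - Ct_target)`.  Standard errors are propagated
#' from the replicate Ct spread by the first-order delta method
#' (`Var(Q)/Q^2 = ln(E)^2 Var(mean Ct)`).
#'
#' @param target Filtered measurements of one target amplicon (one
#'   sample).
#' @param reference Filtered measurements of the reference amplicon(s)
#'   (same sample), e.g. the two primer pairs of the reference gene.
#' @return A `data.frame` with `amplicon_id`, `gene_id`, `relative_copy`,
#'   `se`.
#' @export
pfaffl_relative_copy <- function(target, reference) {
  if (nrow(reference) == 0L) stop("missing reference measurements")
  if (nrow(target) == 0L) stop("missing target measurements")
  tg <- aggregate_replicates(target)
  if (nrow(tg) != 1L) stop("target must be a single amplicon")
  rf <- aggregate_replicates(reference)
  q_t <- tg$efficiency^(-tg$mean_ct)
  q_r <- rf$efficiency^(-rf$mean_ct)
  q_ref <- mean(q_r)
  rel <- q_t / q_ref
  # delta method: Var(Q) = (ln E)^2 Q^2 Var(mean Ct)
  var_qt <- (log(tg$efficiency) * q_t)^2 * tg$var_mean_ct
  var_qref <- sum((log(rf$efficiency) * q_r)^2 * rf$var_mean_ct) /
    nrow(rf)^2
  se <- rel * sqrt(var_qt / q_t^2 + var_qref / q_ref^2)
  data.frame(amplicon_id = tg$amplicon_id, gene_id = tg$gene_id,
             relative_copy = rel, se = se, stringsAsFactors = FALSE)
}

#' Relative copy numbers of all genes against a reference gene
#'
#' Applies [filter_efficiency()] then [pfaffl_relative_copy()] per
#' amplicon and sample, normalizing against the mean quantity of the
#' reference gene's primer pairs.  Per gene, amplicon estimates are
#' averaged and an SE across amplicons/replicates reported.  With
#' `renormalize = TRUE` (default) each sample's values are divided by the
#' reference gene's own aggregated estimate so the reference is exactly 1.
#'
#' @param measures Measurement `data.frame` (possibly several samples).
#' @param reference_gene Gene identifier of the reference.
#' @param renormalize Force the reference gene's relative copy to 1.
#' @param filter Apply the efficiency filter first.
#' @return A `data.frame` with `sample_id`, `gene_id`, `relative_copy`,
#'   `se`, `n_amplicons`.
#' @export
qpcr_relative_copies <- function(measures, reference_gene,
                                 renormalize = TRUE, filter = TRUE) {
  if (filter) measures <- filter_efficiency(measures)
  out <- do.call(rbind, lapply(split(measures, measures$sample_id),
                               function(d) {
    ref <- d[d$gene_id == reference_gene, , drop = FALSE]
    if (nrow(ref) == 0L) {
      stop("missing reference: no measurements of ", reference_gene,
           " in sample ", d$sample_id[1])
    }
    per_amp <- do.call(rbind, lapply(split(d, d$amplicon_id), function(a) {
      pfaffl_relative_copy(a, ref)
    }))
    per_gene <- do.call(rbind, lapply(split(per_amp, per_amp$gene_id),
                                      function(g) {
      data.frame(sample_id = d$sample_id[1], gene_id = g$gene_id[1],
                 relative_copy = mean(g$relative_copy),
                 se = if (nrow(g) > 1) {
                   stats::sd(g$relative_copy) / sqrt(nrow(g))
                 } else g$se,
                 n_amplicons = nrow(g), stringsAsFactors = FALSE)
    }))
    if (renormalize) {
      ref_val <- per_gene$relative_copy[per_gene$gene_id == reference_gene]
      per_gene$relative_copy <- per_gene$relative_copy / ref_val
      per_gene$se <- per_gene$se / ref_val
    }
    per_gene
  }))
  rownames(out) <- NULL
  out
}

#' Read and write qPCR measurement tables
#'
#' `qpcr.tsv` columns: `sample_id`, `gene_id`, `amplicon_id`,
#' `replicate_index`, `ct`, `efficiency`.
#'
#' @param path File path.
#' @return `read_qpcr_table()` returns the measurement `data.frame`.
#' @export
read_qpcr_table <- function(path) {
  df <- read_tsv_strict(path,
                        c("sample_id", "gene_id", "amplicon_id",
                          "replicate_index", "ct", "efficiency"),
                        numeric_cols = c("replicate_index", "ct",
                                         "efficiency"))
  if (any(df$ct <= 0)) stop("non-positive Ct in ", basename(path))
  if (any(df$efficiency > 2.2)) {
    stop("efficiency above 2.2 in ", basename(path),
         " looks like a percentage-scale value; supply fold amplification",
         " per cycle (2 = doubling)")
  }
  df
}

#' @param measures Measurement `data.frame`.
#' @rdname read_qpcr_table
#' @export
write_qpcr_table <- function(measures, path) {
  utils::write.table(measures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
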