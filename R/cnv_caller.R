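#' Expected read counts under the GC-corrected binomial model
#'
#' For each gene, the single-copy success probability is
#' `P_i = L_i * (a + b * x_i) / N` and the expected count is
#' `E(c_i) = N * P_i = L_i * (a + b * x_i)`.  Substituting `b = 0`,
#' `a = N / G` recovers the uncorrected uniform-sampling model
#' `P_i = L_i / G`; the GC-corrected probabilities are independent of the
#' genome size, so they can be estimated for samples without a genome-size
#' measurement.  Genes whose modelled rate is non-positive are flagged
#' unusable rather than dropped, so the caller can report them.
#'
#' @param genes Reference table (`gene_id`, `length_bp`, `gc_fraction`).
#' @param fit A `gc_fit` (or anything with elements `a` and `b`).
#' @param N Library size (binomial trials).
#' @return A `data.frame` with `gene_id`, `P` (success probability), `E`
#'   (expected count), `usable` (logical).
#' @export
expected_count <- function(genes, fit, N) {
  stopifnot(N >= 1)
  rate <- fit$a + fit$b * genes$gc_fraction
  E <- genes$length_bp * rate
  P <- E / N
  if (any(P >= 1)) {
    stop("success probability >= 1 for gene(s): ",
         paste(genes$gene_id[P >= 1], collapse = ", "),
         " (model violated; check N and the GC fit)")
  }
  data.frame(gene_id = genes$gene_id, P = P, E = E, usable = P > 0,
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected binomial confidence interval for single-copy counts
#'
#' Two-sided interval on the observed count of a single-copy gene:
#' per-gene level `alpha = (1 - family_confidence) / M`, split equally per
#' tail, with bounds from the standard binomial quantile convention
#' (smallest integer q with `CDF(q) >= alpha/2`, resp. `>= 1 - alpha/2`).
#' The interval is inclusive on both ends.  `qbinom` evaluates the CDF in a
#' numerically stable way for the extreme N, small P regime typical of
#' genome-wide libraries.
#'
#' @param N Number of binomial trials (library size).
#' @param P Success probability (vectorized).
#' @param M Number of tests for the Bonferroni correction (genes with a
#'   usable probability).
#' @param family_confidence Family-wise confidence level.
#' @return A `data.frame` with integer `ci_lower`, `ci_upper`.
#' @export
binomial_ci <- function(N, P, M, family_confidence = 0.99) {
  stopifnot(M >= 1, family_confidence > 0, family_confidence < 1,
            all(P > 0 & P < 1))
  alpha <- (1 - family_confidence) / M
  data.frame(ci_lower = stats::qbinom(alpha / 2, N, P),
             ci_upper = stats::qbinom(1 - alpha / 2, N, P))
}

#' Classify a gene from its count and confidence interval
#'
#' Rule table: an interval reaching zero cannot distinguish absence from
#' sampling noise, so the gene is excluded (`excluded_ci_spans_zero`);
#' otherwise a zero count is `absent`; a positive count below the lower
#' limit is removed (`below_ci_removed`, copy number not estimable); counts
#' within the limits (inclusive) are `single`; counts above the upper limit
#' are `duplicated`.
#'
#' @param c_i Observed counts (vectorized).
#' @param ci_lower,ci_upper Interval bounds from [binomial_ci()].
#' @return Character vector of labels.
#' @export
classify_gene <- function(c_i, ci_lower, ci_upper) {
  stopifnot(all(ci_lower <= ci_upper))
  ifelse(ci_lower == 0, "excluded_ci_spans_zero",
  ifelse(c_i == 0, "absent",
  ifelse(c_i < ci_lower, "below_ci_removed",
  ifelse(c_i <= ci_upper, "single", "duplicated"))))
}

#' Estimate copy number from observed and expected counts
#'
#' `k = c_i / E(c_i)`, the observed count relative to the single-copy
#' expectation.  The integer estimate for duplicated genes either rounds up
#' (`"ceiling"`, acknowledging that partial duplications inflate counts by
#' a fraction of a copy) or to the nearest integer (`"nearest"`); single
#' genes report 1, absent genes 0, removed/excluded genes `NA`.
#'
#' @param c_i Observed counts.
#' @param E Expected single-copy counts (> 0).
#' @param label Labels from [classify_gene()].
#' @param rounding `"ceiling"` (default) or `"nearest"`.
#' @return A `data.frame` with `k_estimate`, `k_rounded`.
#' @export
estimate_k <- function(c_i, E, label, rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  if (any(E <= 0)) stop("expected count must be positive")
  k <- c_i / E
  kr <- ifelse(label == "duplicated",
               if (rounding == "ceiling") ceiling(k) else round(k),
        ifelse(label == "single", 1,
        ifelse(label == "absent", 0, NA_real_)))
  data.frame(k_estimate = k, k_rounded = as.integer(kr))
}

# majority label with deterministic tie-break by a fixed preference order
consensus_label <- function(labels) {
  order_pref <- c("single", "duplicated", "absent", "below_ci_removed",
                  "excluded_ci_spans_zero")
  tab <- table(factor(labels, levels = order_pref))
  names(tab)[which.max(tab)]
}

#' Call copy numbers for one sample across a GC-fit ensemble
#'
#' Runs the full classification once per ensemble member (each member's
#' coefficients give their own expected counts, Bonferroni count `M`, and
#' confidence intervals), then reduces to per-gene consensus calls
#' (majority label, median `k_estimate`, rounding applied to the median)
#' and to a per-sample summary of the single/duplicated/absent proportions
#' (min, median, max across members, in percent of the analysed genes,
#' i.e. excluding removed and excluded categories).
#'
#' @param genes Reference table.
#' @param counts A `count_table`.
#' @param ensemble A `gc_fit_ensemble` (or single `gc_fit`, treated as an
#'   ensemble of one).
#' @param family_confidence Family-wise confidence level for the intervals.
#' @param rounding Integer rounding rule, see [estimate_k()].
#' @return A `cnv_calls` object: list with `calls` (long `data.frame`, one
#'   row per gene per ensemble member: `gene_id`, `ensemble_member`, `c`,
#'   `E`, `P`, `ci_lower`, `ci_upper`, `k`, `label`), `consensus`
#'   (`data.frame`: `gene_id`, `c`, `label`, `k_estimate`, `k_rounded`,
#'   `n_members`), and `summary` (a `call_summary`).
#' @export
call_sample <- function(genes, counts, ensemble, family_confidence = 0.99,
                        rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(counts, "count_table"))
  if (inherits(ensemble, "gc_fit")) {
    ensemble <- structure(list(fits = data.frame(
      repeat_index = 1L, a = ensemble$a, b = ensemble$b,
      n_genes_used = ensemble$n_genes_used)), class = "gc_fit_ensemble")
  }
  fits <- ensemble$fits
  if (nrow(fits) == 0L) stop("empty GC-fit ensemble")
  cnt <- counts$counts[genes$gene_id]
  if (anyNA(cnt)) stop("count table is missing gene(s) present in reference")
  N <- counts$total_reads
  member_calls <- vector("list", nrow(fits))
  for (r in seq_len(nrow(fits))) {
    exp_r <- expected_count(genes, list(a = fits$a[r], b = fits$b[r]), N)
    M <- sum(exp_r$usable)
    call_r <- data.frame(gene_id = genes$gene_id,
                         ensemble_member = fits$repeat_index[r],
                         c = unname(cnt), E = exp_r$E, P = exp_r$P,
                         ci_lower = NA_integer_, ci_upper = NA_integer_,
                         k = NA_real_, label = "unusable_rate",
                         stringsAsFactors = FALSE)
    u <- exp_r$usable
    if (any(u)) {
      ci <- binomial_ci(N, exp_r$P[u], M, family_confidence)
      call_r$ci_lower[u] <- ci$ci_lower
      call_r$ci_upper[u] <- ci$ci_upper
      call_r$label[u] <- classify_gene(call_r$c[u], ci$ci_lower, ci$ci_upper)
      ke <- estimate_k(call_r$c[u], call_r$E[u], call_r$label[u], rounding)
      call_r$k[u] <- ke$k_estimate
    }
    member_calls[[r]] <- call_r
  }
  calls <- do.call(rbind, member_calls)
  by_gene <- split(calls, calls$gene_id)
  cons <- do.call(rbind, lapply(by_gene, function(d) {
    lab <- consensus_label(d$label[d$label != "unusable_rate"])
    if (length(lab) == 0L) lab <- "unusable_rate"
    data.frame(gene_id = d$gene_id[1], c = d$c[1], label = lab,
               k_estimate = stats::median(d$k, na.rm = TRUE),
               n_members = nrow(d), stringsAsFactors = FALSE)
  }))
  cons <- cons[match(genes$gene_id, cons$gene_id), , drop = FALSE]
  rownames(cons) <- NULL
  cons$k_rounded <- estimate_k(cons$k_estimate, rep(1, nrow(cons)),
                               cons$label, rounding)$k_rounded
  summary <- summarize_calls(calls, counts$sample_id)
  structure(list(calls = calls, consensus = cons, summary = summary,
                 sample_id = counts$sample_id),
            class = "cnv_calls")
}

# Table-2-style per-sample summary: proportions over the analysed
# denominator (single + duplicated + absent), min/median/max across members
summarize_calls <- function(calls, sample_id) {
  per_member <- lapply(split(calls, calls$ensemble_member), function(d) {
    n_s <- sum(d$label == "single")
    n_d <- sum(d$label == "duplicated")
    n_a <- sum(d$label == "absent")
    denom <- n_s + n_d + n_a
    c(single = 100 * n_s / denom, duplicated = 100 * n_d / denom,
      absent = 100 * n_a / denom, analysed = denom)
  })
  m <- do.call(rbind, per_member)
  tri <- function(col) c(min = min(m[, col]), median = stats::median(m[, col]),
                         max = max(m[, col]))
  structure(list(sample_id = sample_id,
                 n_genes_analysed = stats::median(m[, "analysed"]),
                 prop_single = tri("single"),
                 prop_duplicated = tri("duplicated"),
                 prop_absent = tri("absent")),
            class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  fmt <- function(tr) sprintf("%.1f (%.1f-%.1f)", tr["median"], tr["min"],
                              tr["max"])
  cat("call_summary:", x$sample_id, "-", x$n_genes_analysed,
      "genes analysed\n",
      " single:    ", fmt(x$prop_single), "%\n",
      " duplicated:", fmt(x$prop_duplicated), "%\n",
      " absent:    ", fmt(x$prop_absent), "%\n")
  invisible(x)
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat("cnv_calls:", x$sample_id, "-",
      length(unique(x$calls$ensemble_member)), "ensemble member(s),",
      nrow(x$consensus), "genes\n")
  print(x$summary)
  invisible(x)
}

#' Theoretical sequencing coverage from read counts and genome size
#'
#' `coverage = (read_pairs * 2 * read_length_bp) / (2 * genome_size_2cx_gb
#' * 1e9)`: total sequenced bases over the 2C nuclear genome size, reported
#' to two decimals.  When the genome size is unknown a default of 2.2 Gb is
#' applied (with a message), the largest value observed for a diploid in
#' the study system.
#'
#' @param read_pairs Number of read pairs (vectorized).
#' @param read_length_bp Read length in bp.
#' @param genome_size_2cx_gb Genome size in Gb per 2Cx; `NA` uses
#'   `default_size_gb`.
#' @param default_size_gb Fallback genome size in Gb.
#' @return Numeric coverage, rounded to two decimals.
#' @examples
#' theoretical_coverage(18899157, 100, 1.88)  # 1.01
#' @export
theoretical_coverage <- function(read_pairs, read_length_bp,
                                 genome_size_2cx_gb = NA,
                                 default_size_gb = 2.2) {
  stopifnot(all(read_pairs > 0), all(read_length_bp > 0),
            all(genome_size_2cx_gb > 0, na.rm = TRUE))
  n <- max(length(read_pairs), length(read_length_bp),
           length(genome_size_2cx_gb))
  g <- rep_len(genome_size_2cx_gb, n)
  if (anyNA(g)) {
    message(sum(is.na(g)), " sample(s) without genome size; using default ",
            default_size_gb, " Gb")
    g[is.na(g)] <- default_size_gb
  }
  round(rep_len(read_pairs, n) * 2 * rep_len(read_length_bp, n) /
          (2 * g * 1e9), 2)
}

#' Write per-gene calls and consensus to TSV
#'
#' @param calls A `cnv_calls` object.
#' @param calls_path Path for the long per-member table (optional).
#' @param consensus_path Path for the consensus table (optional).
#' @return Invisibly, the `cnv_calls` object.
#' @export
write_calls <- function(calls, calls_path = NULL, consensus_path = NULL) {
  stopifnot(inherits(calls, "cnv_calls"))
  if (!is.null(calls_path)) {
    utils::write.table(calls$calls, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(consensus_path)) {
    utils::write.table(calls$consensus, consensus_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(calls)
}
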