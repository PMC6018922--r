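#' Enrich a count table for putative single-copy genes
#'
#' Applies the filters used before fitting the GC-rate model: only genes
#' longer than `min_length` bp (long genes receive more reads and give more
#' accurate rates), with at least one read, and whose length-normalized
#' count does not exceed `max_fold` times the median length-normalized
#' count (median over genes with any reads).  The upper cut discards most
#' duplicated genes so the remaining pool approximates the single-copy
#' background.
#'
#' @param genes Reference table (`gene_id`, `length_bp`, `gc_fraction`).
#' @param counts A `count_table` for one sample.
#' @param min_length Minimum gene length in bp (exclusive bound).
#' @param max_fold Multiple of the median normalized count above which a
#'   gene is discarded (inclusive bound: exactly `max_fold` x median is
#'   kept).
#' @param min_genes Minimum surviving pool size before erroring out.
#' @return A `data.frame` with `gene_id`, `length_bp`, `gc_fraction`,
#'   `count`, `norm_count` (reads per base).
#' @export
filter_candidate_single_copy <- function(genes, counts, min_length = 700,
                                         max_fold = 1.5, min_genes = 200) {
  stopifnot(inherits(counts, "count_table"))
  cnt <- counts$counts[genes$gene_id]
  if (anyNA(cnt)) stop("count table is missing gene(s) present in reference")
  norm <- unname(cnt) / genes$length_bp
  med <- stats::median(norm[cnt > 0])
  keep <- genes$length_bp > min_length & cnt > 0 & norm <= max_fold * med
  out <- data.frame(gene_id = genes$gene_id[keep],
                    length_bp = genes$length_bp[keep],
                    gc_fraction = genes$gc_fraction[keep],
                    count = unname(cnt[keep]), norm_count = norm[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) < min_genes) {
    stop("insufficient single-copy pool: ", nrow(out), " genes survive (",
         min_genes, " required)")
  }
  out
}

#' Fit the linear GC-rate model
#'
#' Ordinary least squares of length-normalized count (reads per base) on GC
#' fraction: `c_i / L_i = a + b * x_i`.
#'
#' @param subset A filtered pool as returned by
#'   [filter_candidate_single_copy()] (needs `norm_count`, `gc_fraction`).
#' @return A `gc_fit`: list with intercept `a` (expected reads per base at
#'   GC = 0), slope `b` (reads per base per unit GC fraction) and
#'   `n_genes_used`.
#' @export
fit_gc_linear <- function(subset) {
  x <- subset$gc_fraction
  y <- subset$norm_count
  if (length(unique(x)) < 2L) {
    stop("singular design: need at least 2 distinct GC values")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(a = unname(fit$coefficients[1]),
                 b = unname(fit$coefficients[2]),
                 n_genes_used = length(y)),
            class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf("gc_fit: a = %.4g, b = %.4g (%d genes)\n",
              x$a, x$b, x$n_genes_used))
  invisible(x)
}

# nine equally spaced class boundaries on the GC fraction scale;
# classes are [lo, hi) except the last, which is closed
gc_class_bounds <- function(class_range, n_classes) {
  br <- seq(class_range[1], class_range[2], length.out = n_classes + 1L)
  data.frame(lo = br[-length(br)], hi = br[-1])
}

gc_class_index <- function(gc, bounds) {
  idx <- findInterval(gc, c(bounds$lo, bounds$hi[nrow(bounds)]),
                      rightmost.closed = TRUE)
  idx[gc < bounds$lo[1] | gc > bounds$hi[nrow(bounds)]] <- NA_integer_
  idx
}

#' Estimate the GC-rate coefficients by class-balanced resampling
#'
#' Repeats, `n_repeats` times: draw `genes_per_class` genes without
#' replacement from each of `n_classes` equally spaced GC classes spanning
#' `class_range`, pool them, and fit [fit_gc_linear()].  Balancing the
#' classes stops the (typically unimodal) GC distribution from letting
#' mid-GC genes dominate the fit; the spread of the resampled coefficient
#' pairs is a non-parametric estimate of their sampling variation.  Genes
#' outside `class_range` are never sampled.  A class with fewer genes than
#' requested contributes all of them (sampling stays without replacement);
#' an empty class is skipped.  Both conditions emit a warning once.
#'
#' @param genes Reference table.
#' @param counts A `count_table` for one sample.
#' @param n_repeats Number of resampling repeats.
#' @param genes_per_class Genes drawn per GC class.
#' @param class_range GC fraction range partitioned into classes.
#' @param n_classes Number of equal-width classes.
#' @param seed Integer seed.
#' @param ... Passed to [filter_candidate_single_copy()].
#' @return A `gc_fit_ensemble`: list with `fits` (`data.frame`:
#'   `repeat_index`, `a`, `b`, `n_genes_used`), `seed`, `class_bounds`.
#' @export
fit_gc_ensemble <- function(genes, counts, n_repeats = 100L,
                            genes_per_class = 60L,
                            class_range = c(0.38, 0.78), n_classes = 9L,
                            seed = 1L, ...) {
  pool <- filter_candidate_single_copy(genes, counts, ...)
  bounds <- gc_class_bounds(class_range, n_classes)
  cls <- gc_class_index(pool$gc_fraction, bounds)
  pool <- pool[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  sizes <- tabulate(cls, nbins = n_classes)
  if (any(sizes == 0L)) {
    warning("GC class(es) with no genes skipped: ",
            paste(which(sizes == 0L), collapse = ", "))
  }
  if (any(sizes > 0L & sizes < genes_per_class)) {
    warning("GC class(es) with fewer than ", genes_per_class,
            " genes; using all their genes: ",
            paste(which(sizes > 0L & sizes < genes_per_class), collapse = ", "))
  }
  by_class <- split(seq_len(nrow(pool)), factor(cls, levels = seq_len(n_classes)))
  set.seed(seed)
  fits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    take <- unlist(lapply(by_class, function(idx) {
      if (length(idx) == 0L) return(integer())
      if (length(idx) <= genes_per_class) return(idx)
      idx[sample.int(length(idx), genes_per_class)]
    }), use.names = FALSE)
    f <- fit_gc_linear(pool[take, , drop = FALSE])
    fits[[r]] <- data.frame(repeat_index = r, a = f$a, b = f$b,
                            n_genes_used = f$n_genes_used)
  }
  structure(list(fits = do.call(rbind, fits), seed = as.integer(seed),
                 class_bounds = bounds),
            class = "gc_fit_ensemble")
}

#' @export
print.gc_fit_ensemble <- function(x, ...) {
  cat(sprintf(paste0("gc_fit_ensemble: %d fits; median a = %.4g ",
                     "[%.4g, %.4g], median b = %.4g [%.4g, %.4g]\n"),
              nrow(x$fits),
              stats::median(x$fits$a), min(x$fits$a), max(x$fits$a),
              stats::median(x$fits$b), min(x$fits$b), max(x$fits$b)))
  invisible(x)
}

#' Read and write GC-fit ensembles
#'
#' `gcfit.tsv` columns: `repeat_index`, `a`, `b`, `n_genes_used`.
#'
#' @param path File path.
#' @return `read_gc_ensemble()` returns a `gc_fit_ensemble` (with
#'   `class_bounds`/`seed` unset, as only the fits are serialized).
#' @export
read_gc_ensemble <- function(path) {
  df <- read_tsv_strict(path, c("repeat_index", "a", "b", "n_genes_used"),
                        numeric_cols = c("repeat_index", "a", "b",
                                         "n_genes_used"))
  structure(list(fits = df, seed = NA_integer_, class_bounds = NULL),
            class = "gc_fit_ensemble")
}

#' @param ensemble A `gc_fit_ensemble`.
#' @rdname read_gc_ensemble
#' @export
write_gc_ensemble <- function(ensemble, path) {
  utils::write.table(ensemble$fits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
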