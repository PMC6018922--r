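#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator.  Defaults describe a
#' low-coverage genome-skimming experiment over a CDS reference: a couple of
#' million mapped reads, a mildly positive linear GC-rate relationship, and
#' a copy-number spectrum dominated by single-copy genes with a duplicated
#' tail and a small absent fraction, as observed in background genome scans
#' of wild grass accessions.
#'
#' @param n_genes Number of reference genes to simulate.
#' @param seed Integer seed; every generator is reproducible under it.
#' @param library_size Total mapped reads N (binomial trials).
#' @param gc_coefficients Numeric `c(a, b)`: expected reads per base at
#'   GC = 0 and its change per unit GC fraction.  `a + b * x` must stay
#'   strictly positive over the GC support.
#' @param copy_spectrum Named numeric vector of probabilities over integer
#'   copy numbers (names "0".."8"); must sum to 1.
#' @param length_meanlog,length_sdlog Log-scale location/spread of gene
#'   lengths (bp); lengths are floored at 150 bp.
#' @param gc_range Support of the GC distribution (fraction scale).
#' @param gc_shape1,gc_shape2 Beta shape parameters for GC, rescaled to
#'   `gc_range`.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 5000L,
                              seed = 1L,
                              library_size = 2e6,
                              gc_coefficients = c(a = 0.008, b = 0.005),
                              copy_spectrum = c("0" = 0.007, "1" = 0.860,
                                                "2" = 0.090, "3" = 0.025,
                                                "4" = 0.010, "5" = 0.004,
                                                "6" = 0.002, "7" = 0.001,
                                                "8" = 0.001),
                              length_meanlog = log(1500), length_sdlog = 0.45,
                              gc_range = c(0.30, 0.85),
                              gc_shape1 = 5, gc_shape2 = 5) {
  stopifnot(n_genes >= 1, library_size >= 1, length(gc_coefficients) == 2,
            length(gc_range) == 2, gc_range[1] < gc_range[2],
            gc_shape1 > 0, gc_shape2 > 0, length_sdlog >= 0)
  if (abs(sum(copy_spectrum) - 1) > 1e-8) {
    stop("copy_spectrum probabilities must sum to 1")
  }
  if (any(copy_spectrum < 0) || all(copy_spectrum == 0)) {
    stop("degenerate copy_spectrum")
  }
  a <- gc_coefficients[[1]]; b <- gc_coefficients[[2]]
  if (min(a + b * gc_range[1], a + b * gc_range[2]) <= 0) {
    stop("a + b * x must be strictly positive over the GC support")
  }
  structure(list(n_genes = as.integer(n_genes), seed = as.integer(seed),
                 library_size = library_size,
                 a = a, b = b,
                 copy_spectrum = copy_spectrum,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 gc_range = gc_range, gc_shape1 = gc_shape1,
                 gc_shape2 = gc_shape2),
            class = "sim_config")
}

#' Simulate a CDS reference with known copy numbers
#'
#' Draws gene lengths (log-normal, floored at 150 bp), GC fractions
#' (rescaled Beta) and true integer copy numbers from the configured
#' spectrum.  Copy number 0 means the gene is missing from the simulated
#' genome.
#'
#' @param config A [simulation_config()].
#' @return List with `genes` (reference `data.frame`) and `truth`
#'   (list with `true_copy`, a named integer vector).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  len <- pmax(150L, as.integer(round(stats::rlnorm(n, config$length_meanlog,
                                                   config$length_sdlog))))
  gc <- config$gc_range[1] + diff(config$gc_range) *
    stats::rbeta(n, config$gc_shape1, config$gc_shape2)
  copies <- as.integer(names(config$copy_spectrum))[
    sample.int(length(config$copy_spectrum), n, replace = TRUE,
               prob = config$copy_spectrum)]
  genes <- data.frame(gene_id = ids, family_id = ids, length_bp = len,
                      gc_fraction = gc, stringsAsFactors = FALSE)
  list(genes = genes,
       truth = list(true_copy = stats::setNames(copies, ids)))
}

#' Simulate binomially sampled read counts with linear GC bias
#'
#' Each gene's count is drawn `Binomial(N, k_i * P_i)` with
#' `P_i = L_i * (a + b * x_i) / N`: the chance that any one of the N reads
#' starts inside gene i, scaled by its true copy number.  Genes with
#' `k_i = 0` receive zero counts.
#'
#' @param genes Reference table (`gene_id`, `length_bp`, `gc_fraction`).
#' @param truth Ground truth from [simulate_reference()] (or a named
#'   integer vector of true copies).
#' @param N Library size (binomial trials).
#' @param a,b GC-rate coefficients.
#' @param seed Integer seed.
#' @param sample_id Sample identifier for the returned table.
#' @return A `count_table`.
#' @export
simulate_counts <- function(genes, truth, N, a, b, seed,
                            sample_id = "sim") {
  true_copy <- if (is.list(truth)) truth$true_copy else truth
  k <- unname(true_copy[genes$gene_id])
  stopifnot(!anyNA(k))
  p1 <- genes$length_bp * (a + b * genes$gc_fraction) / N
  if (any(p1 <= 0)) {
    stop("non-positive success probability for gene(s): ",
         paste(genes$gene_id[p1 <= 0], collapse = ", "))
  }
  p <- k * p1
  if (any(p >= 1)) {
    stop("success probability >= 1 for gene(s): ",
         paste(genes$gene_id[p >= 1], collapse = ", "))
  }
  set.seed(seed)
  counts <- stats::rbinom(length(p), size = N, prob = p)
  count_table(sample_id, stats::setNames(counts, genes$gene_id), N)
}

#' Simulate biallelic SNP read depths under allele dosage
#'
#' Emulates the genome/transcriptome SNP comparison for a gene present in
#' `k_copies` copies in a diploid (2 * k alleles).  Each site carries its
#' variant base on `m` alleles, `m` drawn uniformly on `1..k_copies` (the
#' minor variant by construction, frequency at most 1/2).  Genome depths for
#' the variant are binomial with success probability `m / (2 k)`;
#' transcriptome depths are binomial with success probability equal to the
#' summed expression weight of the variant-bearing alleles over the total
#' weight, so unequal per-copy expression decouples the two frequencies.
#'
#' @param k_copies Gene copy number (>= 1).
#' @param n_sites Number of polymorphic sites.
#' @param genome_total_depth,transcriptome_total_depth Total read depth per
#'   site in each data set.
#' @param expression_weights Non-negative weights, one per allele
#'   (length `2 * k_copies`); default equal expression.
#' @param seed Integer seed.
#' @return List with `snp` (depth `data.frame` as in [read_snp_table()]),
#'   and `truth` (`data.frame` with per-site variant multiplicity `m`).
#' @export
simulate_snp_sites <- function(k_copies, n_sites, genome_total_depth,
                               transcriptome_total_depth,
                               expression_weights = rep(1, 2 * k_copies),
                               seed = 1L) {
  stopifnot(k_copies >= 1, n_sites >= 1, genome_total_depth >= 1,
            transcriptome_total_depth >= 1,
            length(expression_weights) == 2 * k_copies,
            all(expression_weights >= 0))
  if (sum(expression_weights) <= 0) stop("zero total expression weight")
  set.seed(seed)
  n_alleles <- 2L * as.integer(k_copies)
  m <- sample.int(k_copies, n_sites, replace = TRUE)
  w_tot <- sum(expression_weights)
  p_t <- vapply(m, function(mi) {
    idx <- sample.int(n_alleles, mi)
    sum(expression_weights[idx]) / w_tot
  }, numeric(1))
  p_g <- m / n_alleles
  g_a <- stats::rbinom(n_sites, genome_total_depth, p_g)
  t_a <- stats::rbinom(n_sites, transcriptome_total_depth, p_t)
  bases <- t(vapply(seq_len(n_sites),
                    function(i) sample(c("A", "C", "G", "T"), 2),
                    character(2)))
  snp <- data.frame(gene_id = "simgene", position = seq_len(n_sites),
                    base_a = bases[, 1], base_b = bases[, 2],
                    g_depth_a = g_a, g_depth_b = genome_total_depth - g_a,
                    t_depth_a = t_a,
                    t_depth_b = transcriptome_total_depth - t_a,
                    stringsAsFactors = FALSE)
  list(snp = snp,
       truth = data.frame(position = seq_len(n_sites), m = m,
                          p_genome = p_g, p_transcriptome = p_t))
}

# lower-triangular factor of sigma2 * C for Brownian tip simulation
bm_deviates <- function(C, sigma2) {
  if (sigma2 == 0) return(rep(0, nrow(C)))
  L <- t(chol(sigma2 * C + diag(1e-12, nrow(C))))
  as.numeric(L %*% stats::rnorm(nrow(C)))
}

#' Simulate a gene-family tree with copy-number and abundance traits
#'
#' Grows a pure-birth tree, assigns integer copy numbers 1..5 by
#' thresholding a unit-rate Brownian trait, and sets
#' `log_abundance = beta * copy_number + e` where `e` is Brownian with rate
#' `sigma2` on the same tree.  With `sigma2 = 0` the abundance is exactly
#' linear in copy number, so a generalized least squares fit recovers
#' `beta` without error.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param beta True copy-number effect on log10 abundance.
#' @param sigma2 Brownian rate of the abundance deviations.
#' @param seed Integer seed.
#' @return List with `tree` (`phylo`), `traits` (`data.frame`: `tip_id`,
#'   `copy_number`, `log_abundance`) and `truth` (`true_slope_beta`).
#' @export
simulate_tree_and_traits <- function(n_tips, birth_rate = 1, beta = 0.3,
                                     sigma2 = 0.05, seed = 1L) {
  stopifnot(n_tips >= 3, birth_rate > 0, sigma2 >= 0)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  C <- brownian_covariance(tree)$C
  z <- bm_deviates(C, 1)
  s <- sqrt(mean(diag(C)))
  cuts <- stats::qnorm(c(0.45, 0.75, 0.88, 0.96), sd = s)
  copy <- 1L + findInterval(z, cuts)
  y <- beta * copy + bm_deviates(C, sigma2)
  list(tree = tree,
       traits = data.frame(tip_id = tree$tip.label, copy_number = copy,
                           log_abundance = y, stringsAsFactors = FALSE),
       truth = list(true_slope_beta = beta))
}

#' Simulate qPCR Ct measurements
#'
#' Ct is the cycle at which the amplified quantity `q * E^Ct` crosses a
#' fluorescence threshold common to all amplicons, so
#' `Ct = (base_ct * log 2 - log(quantity)) / log(E)` with `base_ct` the Ct
#' of a unit quantity at perfect doubling.  One extra template doubling at
#' efficiency 2 lowers Ct by exactly one cycle, and efficiency-corrected
#' back-calculation (`E^-Ct`, the Pfaffl quantity) recovers the true
#' relative quantities exactly in the noise-free limit.  Gaussian cycle
#' noise is added per technical replicate.
#'
#' @param true_relative_copy Named positive vector of relative template
#'   quantities per amplicon.
#' @param efficiencies Named vector of fold amplification per cycle per
#'   amplicon (2 = perfect doubling); must exceed 1.
#' @param gene_of Optional named character vector mapping amplicon to gene;
#'   defaults to the amplicon name itself.
#' @param base_ct Ct of a unit quantity.
#' @param noise_sd Gaussian SD of replicate Ct values, in cycles.
#' @param n_replicates Technical replicates per amplicon.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return A `data.frame` of measurements: `sample_id`, `gene_id`,
#'   `amplicon_id`, `replicate_index`, `ct`, `efficiency`.
#' @export
simulate_qpcr <- function(true_relative_copy, efficiencies,
                          gene_of = NULL, base_ct = 25, noise_sd = 0,
                          n_replicates = 3L, seed = 1L, sample_id = "S1") {
  stopifnot(length(true_relative_copy) == length(efficiencies),
            !is.null(names(true_relative_copy)),
            all(names(true_relative_copy) %in% names(efficiencies)))
  if (any(true_relative_copy <= 0)) {
    stop("non-positive relative copy for amplicon(s): ",
         paste(names(true_relative_copy)[true_relative_copy <= 0],
               collapse = ", "))
  }
  if (any(efficiencies <= 1)) stop("amplification efficiencies must exceed 1")
  if (is.null(gene_of)) {
    gene_of <- stats::setNames(names(true_relative_copy),
                               names(true_relative_copy))
  }
  set.seed(seed)
  amp <- names(true_relative_copy)
  out <- do.call(rbind, lapply(amp, function(a) {
    e <- efficiencies[[a]]
    ct0 <- (base_ct * log(2) - log(true_relative_copy[[a]])) / log(e)
    data.frame(sample_id = sample_id, gene_id = unname(gene_of[[a]]),
               amplicon_id = a, replicate_index = seq_len(n_replicates),
               ct = ct0 + stats::rnorm(n_replicates, 0, noise_sd),
               efficiency = e, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a full synthetic study to a directory
#'
#' Emits `genes.tsv`, `counts.tsv`, `samples.tsv`, `snp.tsv`, `expr.tsv`,
#' `tree.nwk` and `truth.tsv`, all consumable by the package's readers.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  ct <- simulate_counts(ref$genes, ref$truth, config$library_size,
                        config$a, config$b, seed = config$seed + 1L)
  snp <- simulate_snp_sites(4L, 200L, 500L, 500L, seed = config$seed + 2L)
  tt <- simulate_tree_and_traits(12L, seed = config$seed + 3L)
  expr <- data.frame(accession_id = tt$traits$tip_id,
                     gene_id = "famA",
                     rpkm = pmax(0, 10^tt$traits$log_abundance - 1),
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ct$sample_id,
                        total_reads = ct$total_reads,
                        read_pairs = ceiling(ct$total_reads / 2),
                        read_length_bp = 100L, genome_size_2cx_gb = NA,
                        ploidy = 2L, stringsAsFactors = FALSE)
  write_gene_table(ref$genes, file.path(outdir, "genes.tsv"))
  write_count_table(ct, file.path(outdir, "counts.tsv"))
  write_sample_table(samples, file.path(outdir, "samples.tsv"))
  write_snp_table(snp$snp, file.path(outdir, "snp.tsv"))
  write_expression_table(expr, file.path(outdir, "expr.tsv"))
  ape::write.tree(tt$tree, file.path(outdir, "tree.nwk"))
  utils::write.table(
    data.frame(gene_id = names(ref$truth$true_copy),
               true_copy = unname(ref$truth$true_copy)),
    file.path(outdir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(list(reference = ref, counts = ct, snp = snp, tree_traits = tt))
}
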