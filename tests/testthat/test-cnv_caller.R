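test_that("expected counts follow the length-GC rate and recover the uniform model", {
  genes <- data.frame(gene_id = c("gA", "gB"), family_id = "f",
                      length_bp = c(1000L, 700L),
                      gc_fraction = c(0.5, 0.5))
  # flat GC model: E independent of N
  ec <- expected_count(genes, list(a = 0.01, b = 0), N = 1e6)
  expect_equal(ec$E[1], 10)
  expect_equal(ec$P[1], 10 / 1e6)
  # L = 700, a = 0.008, b = 0.005, x = 0.5 -> E = 700 x 0.0105
  ec2 <- expected_count(genes, list(a = 0.008, b = 0.005), N = 1e6)
  expect_equal(ec2$E[2], 7.35)
  # b = 0, a = N/G reduces to the uniform-sampling probability L/G
  N <- 2e6; G <- 2e9
  ec3 <- expected_count(genes, list(a = N / G, b = 0), N = N)
  expect_equal(ec3$P, genes$length_bp / G)
  expect_error(expected_count(genes, list(a = 2000, b = 0), N = 100),
               "model violated")
})

test_that("binomial CI bounds equal exhaustive CDF enumeration", {
  N <- 1e6; P <- 1e-5; conf <- 0.99
  ci <- binomial_ci(N, P, M = 1, family_confidence = conf)
  # brute-force oracle: scan the CDF upward from zero
  cdf <- cumsum(dbinom(0:200, N, P))
  alpha <- (1 - conf)
  expect_equal(ci$ci_lower, which(cdf >= alpha / 2)[1] - 1L)
  expect_equal(ci$ci_upper, which(cdf >= 1 - alpha / 2)[1] - 1L)
})

test_that("Bonferroni correction only ever widens the interval", {
  N <- 2e6; P <- 5e-5
  prev <- binomial_ci(N, P, M = 1)
  for (M in c(10, 100, 1000, 10000)) {
    cur <- binomial_ci(N, P, M = M)
    expect_lte(cur$ci_lower, prev$ci_lower)
    expect_gte(cur$ci_upper, prev$ci_upper)
    prev <- cur
  }
})

test_that("classification follows the rule table with inclusive limits", {
  # interval spanning zero wins over everything else
  expect_equal(classify_gene(c(0L, 50L), c(0L, 0L), c(9L, 9L)),
               rep("excluded_ci_spans_zero", 2))
  expect_equal(classify_gene(0L, 3L, 9L), "absent")
  expect_equal(classify_gene(2L, 3L, 9L), "below_ci_removed")
  expect_equal(classify_gene(3L, 3L, 9L), "single")   # lower limit inclusive
  expect_equal(classify_gene(9L, 3L, 9L), "single")   # upper limit inclusive
  expect_equal(classify_gene(10L, 3L, 9L), "duplicated")
})

test_that("increasing the count only moves labels towards duplicated", {
  order_rank <- c(absent = 1, below_ci_removed = 1, single = 2,
                  duplicated = 3)
  lab <- classify_gene(0:20, rep(4L, 21), rep(12L, 21))
  ranks <- order_rank[lab]
  expect_true(all(diff(ranks) >= 0))
})

test_that("copy-number estimates divide by the expectation and round by label", {
  k <- estimate_k(c(10, 20, 25), rep(10, 3),
                  c("single", "duplicated", "duplicated"))
  expect_equal(k$k_estimate, c(1, 2, 2.5))
  expect_equal(k$k_rounded, c(1L, 2L, 3L))  # ceiling for duplicated
  k2 <- estimate_k(25, 10, "duplicated", rounding = "nearest")
  expect_equal(k2$k_rounded, 2L)
  expect_equal(estimate_k(0, 10, "absent")$k_rounded, 0L)
  expect_error(estimate_k(5, 0, "single"), "positive")
})

test_that("an ensemble of one fit yields that member's calls as consensus", {
  genes <- make_genes(50, seed = 90L)
  truth <- setNames(c(rep(1L, 45), 2L, 2L, 3L, 0L, 0L), genes$gene_id)
  genes$length_bp <- pmax(genes$length_bp, 2000L)
  ct <- simulate_counts(genes, truth, 2e6, 0.1, 0.05, seed = 91L)
  fit <- structure(list(a = 0.1, b = 0.05, n_genes_used = 45L),
                   class = "gc_fit")
  res <- call_sample(genes, ct, fit)
  expect_equal(nrow(res$calls), 50L)
  m <- res$calls
  expect_equal(res$consensus$label, m$label)
  expect_equal(res$consensus$k_estimate, m$k)
})

test_that("per-member proportions account for every analysed gene", {
  sim <- simulate_reference(simulation_config(n_genes = 1500L, seed = 95L,
                                              library_size = 5e6))
  ct <- simulate_counts(sim$genes, sim$truth, 5e6, 0.05, 0.02, seed = 96L)
  ens <- suppressWarnings(  # tail GC classes of a 1,500-gene pool run short
    fit_gc_ensemble(sim$genes, ct, n_repeats = 5L, seed = 97L))
  res <- call_sample(sim$genes, ct, ens)
  for (d in split(res$calls, res$calls$ensemble_member)) {
    tab <- table(d$label)
    denom <- sum(tab[c("single", "duplicated", "absent")], na.rm = TRUE)
    props <- 100 * tab[c("single", "duplicated", "absent")] / denom
    expect_equal(sum(props, na.rm = TRUE), 100)
  }
  expect_true(all(res$summary$prop_single[["median"]] >=
                    res$summary$prop_single[["min"]]))
  expect_true(all(res$summary$prop_single[["median"]] <=
                    res$summary$prop_single[["max"]]))
})

test_that("duplicated genes recover their true copy number at high coverage", {
  # single-copy expectation around 200-400 counts; nearest-integer rounding
  set.seed(100)
  n <- 2500L
  genes <- make_genes(n, lengths = sample(1800:3000, n, TRUE), seed = 100L)
  copies <- rep(1L, n)
  dup_idx <- 101:800
  copies[dup_idx] <- rep(2:8, each = 100)
  truth <- setNames(copies, genes$gene_id)
  N <- 2e6; a <- 0.1; b <- 0.05
  ct <- simulate_counts(genes, truth, N, a, b, seed = 101L)
  ens <- fit_gc_ensemble(genes, ct, n_repeats = 25L, seed = 102L)
  res <- call_sample(genes, ct, ens, rounding = "nearest")
  cons <- res$consensus[dup_idx, ]
  ok <- cons$k_rounded == copies[dup_idx]
  expect_gte(mean(ok), 0.95)
})

test_that("replicate samples from one genome agree on most consensus labels", {
  sim <- simulate_reference(simulation_config(n_genes = 2000L, seed = 110L))
  a <- 0.05; b <- 0.02; N <- 4e6
  call_rep <- function(seed) {
    ct <- simulate_counts(sim$genes, sim$truth, N, a, b, seed = seed)
    ens <- suppressWarnings(  # tail GC classes run short of 60 genes
      fit_gc_ensemble(sim$genes, ct, n_repeats = 10L, seed = seed + 1L))
    call_sample(sim$genes, ct, ens)$consensus$label
  }
  l1 <- call_rep(111L)
  l2 <- call_rep(222L)
  expect_gte(mean(l1 == l2), 0.82)
})

test_that("theoretical coverage reproduces published accession values", {
  expect_equal(theoretical_coverage(18899157, 100, 1.88), 1.01)
  expect_equal(theoretical_coverage(13824190, 100, 5.22), 0.26)
  expect_message(cov_default <- theoretical_coverage(33933832, 150, NA),
                 "2.2")
  expect_equal(cov_default, 2.31)
  # more 100/150 bp rows with stated or default sizes
  expect_equal(theoretical_coverage(20898025, 100, NA), 0.95)   # default size
  expect_equal(theoretical_coverage(18665954, 100, 1.95), 0.96)
  expect_equal(theoretical_coverage(12524356, 100, 1.80), 0.70)
  expect_equal(theoretical_coverage(14749392, 150, NA), 1.01)
  expect_equal(theoretical_coverage(11600487, 100, 2.20), 0.53)
})
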