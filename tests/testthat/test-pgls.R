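test_that("Brownian covariance equals shared root-to-MRCA path lengths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  v <- brownian_covariance(tree)
  expect_equal(v$C["A", "B"], 1)
  expect_equal(v$C["A", "A"], 2)
  expect_equal(v$C["A", "C"], 0)
  # star tree: independence
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  vs <- brownian_covariance(star)
  expect_equal(unname(vs$C), diag(3, 4))
})

test_that("covariance matches both ape and a path-enumeration oracle", {
  set.seed(150)
  tree <- ape::rtree(10)
  v <- brownian_covariance(tree)
  expect_equal(v$C, ape::vcv.phylo(tree)[v$tips, v$tips], tolerance = 1e-12)
  # brute force: intersect root-to-tip edge paths per tip pair
  edges <- tree$edge
  path_to_root <- function(node) {
    p <- integer()
    while (TRUE) {
      row <- which(edges[, 2] == node)
      if (length(row) == 0) break
      p <- c(p, row)
      node <- edges[row, 1]
    }
    p
  }
  for (i in 1:10) for (j in 1:10) {
    shared <- intersect(path_to_root(i), path_to_root(j))
    expect_equal(v$C[tree$tip.label[i], tree$tip.label[j]],
                 sum(tree$edge.length[shared]))
  }
})

test_that("degenerate trees are rejected", {
  unrooted <- ape::unroot(
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_error(brownian_covariance(unrooted), "unrooted|3 tips")
  nolen <- ape::read.tree(text = "((A,B),C);")
  expect_error(brownian_covariance(nolen), "branch lengths")
})

test_that("log abundance transform anchors zero and matches arithmetic", {
  expect_equal(log_transform_abundance(0), 0)
  expect_equal(log_transform_abundance(999), 3)
  expect_equal(log_transform_abundance(10), log10(11))
  expect_error(log_transform_abundance(-1), "negative")
})

test_that("GLS with identity covariance reduces exactly to OLS", {
  set.seed(160)
  n <- 12
  x <- rnorm(n); y <- 2 + 0.5 * x + rnorm(n)
  C <- diag(n)
  dimnames(C) <- list(paste0("t", 1:n), paste0("t", 1:n))
  fit <- pgls_fit(x, y, C)
  ols <- summary(lm(y ~ x))
  expect_equal(fit$slope, unname(coef(ols)[2, 1]), tolerance = 1e-12)
  expect_equal(fit$slope_se, unname(coef(ols)[2, 2]), tolerance = 1e-12)
  expect_equal(fit$p_value, unname(coef(ols)[2, 4]), tolerance = 1e-12)
})

test_that("a five-tip fit equals explicit matrix-algebra evaluation", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,(C:0.5,D:0.5):1.5):1,E:3);")
  v <- brownian_covariance(tree)
  x <- c(A = 1, B = 2, C = 2, D = 3, E = 1)
  y <- c(A = 0.2, B = 0.9, C = 1.1, D = 1.6, E = 0.3)
  fit <- pgls_fit(x, y, v)
  # independent oracle: direct inverse, textbook GLS formulas
  Ci <- solve(v$C)
  X <- cbind(1, x[v$tips]); yy <- y[v$tips]
  beta <- solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% yy
  r <- yy - X %*% beta
  s2 <- as.numeric(t(r) %*% Ci %*% r) / 3
  se <- sqrt(diag(s2 * solve(t(X) %*% Ci %*% X)))
  expect_equal(fit$slope, beta[2, 1], tolerance = 1e-10)
  expect_equal(fit$intercept, beta[1, 1], tolerance = 1e-10)
  expect_equal(fit$slope_se, unname(se[2]), tolerance = 1e-10)
  expect_equal(fit$p_value, 2 * pt(-abs(beta[2, 1] / se[2]), 3),
               tolerance = 1e-10)
})

test_that("fit agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(165)
  sim <- simulate_tree_and_traits(20L, beta = 0.4, sigma2 = 0.1, seed = 166L)
  v <- brownian_covariance(sim$tree)
  fit <- pgls_fit(sim$traits$copy_number, sim$traits$log_abundance, v)
  d <- data.frame(x = sim$traits$copy_number, y = sim$traits$log_abundance,
                  tip = sim$traits$tip_id)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, sim$tree, form = ~tip))
  ct <- summary(g)$tTable
  expect_equal(fit$slope, unname(ct["x", "Value"]), tolerance = 1e-6)
  expect_equal(fit$slope_se, unname(ct["x", "Std.Error"]), tolerance = 1e-6)
  expect_equal(fit$p_value, unname(ct["x", "p-value"]), tolerance = 1e-6)
})

test_that("slope is invariant to rescaling the covariance", {
  sim <- simulate_tree_and_traits(10L, beta = 0.2, sigma2 = 0.2, seed = 170L)
  v <- brownian_covariance(sim$tree)
  f1 <- pgls_fit(sim$traits$copy_number, sim$traits$log_abundance, v$C)
  f2 <- pgls_fit(sim$traits$copy_number, sim$traits$log_abundance, 17 * v$C)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
})

test_that("perfectly linear traits drive the p-value to zero", {
  sim <- simulate_tree_and_traits(12L, beta = 0.5, sigma2 = 0, seed = 171L)
  fit <- pgls_fit(sim$traits$copy_number, sim$traits$log_abundance,
                  brownian_covariance(sim$tree))
  expect_lt(fit$p_value, 1e-12)
})

test_that("constant copy numbers are untestable", {
  sim <- simulate_tree_and_traits(8L, seed = 172L)
  expect_error(pgls_fit(rep(2, 8), sim$traits$log_abundance,
                        brownian_covariance(sim$tree)), "untestable")
})

test_that("slope estimates recover the generating effect and its null", {
  # replicates where thresholding leaves no copy-number variation are
  # untestable by construction and sit out, as in a real family scan
  fit_slope <- function(sim) {
    tryCatch(pgls_fit(sim$traits$copy_number, sim$traits$log_abundance,
                      brownian_covariance(sim$tree))$slope,
             error = function(e) NA_real_)
  }
  slopes_null <- vapply(1:200, function(i) {
    fit_slope(simulate_tree_and_traits(15L, beta = 0, sigma2 = 0.3,
                                       seed = 500L + i))
  }, numeric(1))
  slopes_null <- slopes_null[!is.na(slopes_null)]
  n0 <- length(slopes_null)
  expect_gt(n0, 150)
  expect_lt(abs(mean(slopes_null)), 3 * sd(slopes_null) / sqrt(n0))

  slopes <- vapply(1:200, function(i) {
    fit_slope(simulate_tree_and_traits(30L, beta = 0.3, sigma2 = 0.1,
                                       seed = 800L + i))
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  n1 <- length(slopes)
  expect_gt(n1, 150)
  expect_lt(abs(mean(slopes) - 0.3), 3 * sd(slopes) / sqrt(n1))
})

test_that("family scan reports Bonferroni p-values and untestable families", {
  sim1 <- simulate_tree_and_traits(10L, beta = 0.5, sigma2 = 0.05,
                                   seed = 180L)
  sim2 <- simulate_tree_and_traits(10L, beta = 0, sigma2 = 0.3, seed = 181L)
  fams <- list(
    famA = list(tree = sim1$tree, x = sim1$traits$copy_number,
                y = sim1$traits$log_abundance),
    famB = list(tree = sim2$tree, x = sim2$traits$copy_number,
                y = sim2$traits$log_abundance),
    famC = list(tree = sim2$tree, x = rep(1, 10),
                y = sim2$traits$log_abundance))
  res <- run_family_scan(fams)
  expect_equal(nrow(res), 3L)
  expect_true(is.na(res$p_value[res$family_id == "famC"]))
  expect_match(res$status[res$family_id == "famC"], "untestable")
  m <- 2  # testable families
  ok <- !is.na(res$p_value)
  expect_equal(res$p_bonferroni[ok], pmin(1, res$p_value[ok] * m))
  # single testable family: no correction
  r1 <- run_family_scan(fams["famA"])
  expect_equal(r1$p_bonferroni, r1$p_value)
})

test_that("the scan controls family-wise error and ranks a true effect first", {
  # Bonferroni validity: 10 null families, alpha 0.05
  n_rep <- 200L
  fp <- vapply(seq_len(n_rep), function(r) {
    fams <- lapply(1:10, function(j) {
      s <- simulate_tree_and_traits(8L, beta = 0, sigma2 = 0.3,
                                    seed = 2000L + 17L * r + j)
      list(tree = s$tree, x = s$traits$copy_number,
           y = s$traits$log_abundance)
    })
    names(fams) <- paste0("f", 1:10)
    res <- run_family_scan(fams)
    any(res$p_bonferroni <= 0.05, na.rm = TRUE)
  }, logical(1))
  rate <- mean(fp)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))

  # power: one true-effect family among nine nulls attains the smallest p
  hits <- vapply(1:200, function(r) {
    fams <- lapply(1:9, function(j) {
      s <- simulate_tree_and_traits(20L, beta = 0, sigma2 = 0.3,
                                    seed = 60000L + 19L * r + j)
      list(tree = s$tree, x = s$traits$copy_number,
           y = s$traits$log_abundance)
    })
    s <- simulate_tree_and_traits(20L, beta = 0.5, sigma2 = 0.05,
                                  seed = 90000L + r)
    fams <- c(fams, list(list(tree = s$tree, x = s$traits$copy_number,
                              y = s$traits$log_abundance)))
    names(fams) <- paste0("f", 1:10)
    res <- run_family_scan(fams)
    which.min(res$p_value) == 10L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("multiple trees per family yield a per-tree p-value distribution", {
  sim <- simulate_tree_and_traits(10L, beta = 0.4, sigma2 = 0.1, seed = 190L)
  trees <- c(sim$tree, sim$tree, sim$tree)
  res <- run_family_scan(list(fam = list(tree = trees,
                                         x = sim$traits$copy_number,
                                         y = sim$traits$log_abundance)))
  rb <- attr(res, "tree_robustness")
  expect_equal(nrow(rb), 3L)
  expect_true(all(rb$p_value == rb$p_value[1]))
})
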