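#' Brownian-motion tip covariance of a rooted tree
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' shared path length from the root to their most recent common ancestor,
#' and each tip's variance is its root-to-tip distance.  Built here from
#' node depths and the MRCA matrix; ultrametricity is not required.
#'
#' @param tree A rooted `phylo` with branch lengths on every edge.
#' @return A `phylo_vcv`: list with `tips` (labels, fixing the row order)
#'   and `C` (symmetric positive semi-definite matrix).
#' @export
brownian_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree lacks branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  n <- length(tree$tip.label)
  if (n < 3L) stop("need at least 3 tips")
  # a pure star (every edge from the root) is usable despite ape's
  # basal-polytomy rootedness convention; its covariance is diagonal
  is_star <- all(tree$edge[, 1] == n + 1L)
  if (!ape::is.rooted(tree) && !is_star) {
    stop("tree is unrooted; root it upstream (midpoint or outgroup)")
  }
  depth <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  anc <- ape::mrca(tree, full = FALSE)       # tip-by-tip MRCA node numbers
  C <- matrix(depth[anc], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(C) <- depth[seq_len(n)]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("covariance matrix is not positive semi-definite")
  }
  structure(list(tips = tree$tip.label, C = C), class = "phylo_vcv")
}

#' Phylogenetic generalized least squares under Brownian covariance
#'
#' Fits `y = intercept + slope * x + e`, `e ~ N(0, sigma2 * C)`, by
#' generalized least squares: `beta = (X' C^-1 X)^-1 X' C^-1 y` with
#' `X = [1, x]`, `sigma2 = r' C^-1 r / (n - 2)`, standard errors from
#' `sigma2 * (X' C^-1 X)^-1`, and a two-sided t test with `n - 2` degrees
#' of freedom on the slope.  Computed via the Cholesky whitening transform
#' (equivalent algebra, numerically stabler than forming `C^-1`); a
#' singular `C` falls back to a pseudo-inverse with a warning.  With
#' `C = I` the fit reduces exactly to ordinary least squares, and the
#' slope estimate is invariant to rescaling `C` by any positive scalar.
#'
#' @param x Predictor per tip (e.g. integer copy number).
#' @param y Response per tip (e.g. log10 transcript abundance).
#' @param C A `phylo_vcv`, or a covariance matrix with tip dimnames.
#'   Vectors `x`/`y` may be named, in which case they are aligned to the
#'   tip order; unnamed vectors are assumed already aligned.
#' @param family_id Optional identifier carried into the result.
#' @return A `pgls_result`: list with `family_id`, `n_tips`, `slope`,
#'   `intercept`, `slope_se`, `t_stat`, `df`, `p_value`.
#' @export
pgls_fit <- function(x, y, C, family_id = NA_character_) {
  if (inherits(C, "phylo_vcv")) C <- C$C
  n <- nrow(C)
  if (n < 3L) stop("need at least 3 tips")
  tips <- rownames(C)
  if (!is.null(names(x))) {
    stopifnot(setequal(names(x), tips))
    x <- x[tips]
  }
  if (!is.null(names(y))) {
    stopifnot(setequal(names(y), tips))
    y <- y[tips]
  }
  stopifnot(length(x) == n, length(y) == n)
  if (stats::var(x) == 0) {
    stop("untestable: predictor shows no variation across tips")
  }
  X <- cbind(intercept = 1, slope = as.numeric(x))
  W <- tryCatch(solve(t(chol(C))), error = function(e) NULL)
  if (is.null(W)) {
    warning("covariance matrix is singular; using pseudo-inverse")
    if (!requireNamespace("MASS", quietly = TRUE)) {
      stop("MASS needed for the pseudo-inverse fallback")
    }
    e <- eigen(MASS::ginv(C), symmetric = TRUE)
    W <- diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  }
  Xw <- W %*% X
  yw <- as.numeric(W %*% y)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  r <- yw - Xw %*% beta
  df <- n - 2L
  sigma2 <- sum(r^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  t_stat <- unname(beta["slope", 1] / se["slope"])
  structure(list(family_id = family_id, n_tips = n,
                 slope = unname(beta["slope", 1]),
                 intercept = unname(beta["intercept", 1]),
                 slope_se = unname(se["slope"]), t_stat = unname(t_stat),
                 df = df, sigma2 = sigma2,
                 p_value = 2 * stats::pt(-abs(t_stat), df)),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "pgls_result%s: n = %d, slope = %.4f (SE %.4f), t = %.3f, df = %d, p = %.3g\n",
    if (is.na(x$family_id)) "" else paste0(" [", x$family_id, "]"),
    x$n_tips, x$slope, x$slope_se, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Log-transform transcript abundances
#'
#' `log10(rpkm + 1)`: the unit offset anchors zero abundance at zero and
#' keeps genes recorded with 0 RPKM in the analysis.
#'
#' @param rpkm Non-negative abundances.
#' @return `log10(rpkm + 1)`.
#' @export
log_transform_abundance <- function(rpkm) {
  if (any(rpkm < 0)) stop("negative abundance")
  log10(rpkm + 1)
}

#' Scan gene families for copy-number/abundance association
#'
#' Runs [pgls_fit()] for every family and Bonferroni-adjusts the p-values
#' over the number of testable families.  Families whose copy numbers do
#' not vary across tips are untestable and reported with a reason instead
#' of a p-value.  A family may supply several trees (`multiPhylo`), e.g.
#' posterior samples: the first tree is the primary analysis and the full
#' per-tree p-value distribution is attached as the `tree_robustness`
#' attribute, without combining.
#'
#' @param families Named list; each element a list with `tree` (a `phylo`
#'   or `multiPhylo`), `x` (copy numbers, named by tip or aligned), and
#'   `y` (log abundances).
#' @return A `data.frame` with one row per family: `family_id`, `n_tips`,
#'   `slope`, `slope_se`, `t_stat`, `df`, `p_value`, `p_bonferroni`,
#'   `status`.
#' @export
run_family_scan <- function(families) {
  stopifnot(length(families) >= 1, !is.null(names(families)))
  robustness <- list()
  rows <- lapply(names(families), function(fid) {
    fam <- families[[fid]]
    trees <- fam$tree
    if (inherits(trees, "phylo")) trees <- list(trees)
    fit <- tryCatch({
      C <- brownian_covariance(trees[[1]])
      pgls_fit(fam$x, fam$y, C, family_id = fid)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(family_id = fid, n_tips = NA_integer_,
                        slope = NA_real_, slope_se = NA_real_,
                        t_stat = NA_real_, df = NA_integer_,
                        p_value = NA_real_,
                        status = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    }
    if (length(trees) > 1L) {
      robustness[[fid]] <<- data.frame(
        family_id = fid, tree_index = seq_along(trees),
        p_value = vapply(trees, function(tr) {
          pgls_fit(fam$x, fam$y, brownian_covariance(tr))$p_value
        }, numeric(1)))
    }
    data.frame(family_id = fid, n_tips = fit$n_tips, slope = fit$slope,
               slope_se = fit$slope_se, t_stat = fit$t_stat, df = fit$df,
               p_value = fit$p_value, status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p_value))
  out$p_bonferroni <- pmin(1, out$p_value * max(m, 1L))
  out <- out[, c("family_id", "n_tips", "slope", "slope_se", "t_stat", "df",
                 "p_value", "p_bonferroni", "status")]
  if (length(robustness) > 0) {
    attr(out, "tree_robustness") <- do.call(rbind, robustness)
  }
  out
}
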