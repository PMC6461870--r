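#' Pagel's lambda branch-length transform
#'
#' Rescales a rooted tree so that every off-diagonal entry of the implied
#' Brownian-motion tip covariance is multiplied by `lambda` while tip-to-root
#' distances (the diagonal) are preserved. Internally all edges are scaled by
#' `lambda` and each terminal edge is stretched back to the tip's original
#' depth. `lambda = 1` leaves the tree unchanged; `lambda = 0` is equivalent
#' to a star phylogeny (no phylogenetic covariance).
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param lambda Value in `[0, lambda_max]`, where `lambda_max =
#'   min(tip depth / parent-node depth)` keeps all terminal branches
#'   non-negative (>= 1; Inf on a star tree).
#' @return The transformed `phylo` object.
#' @examples
#' tr <- ape::rtree(5)
#' lambda_transform(tr, 0.5)
#' @export
lambda_transform <- function(tree, lambda) {
  check_phylo(tree)
  lmax <- lambda_max(tree)
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0 || lambda > lmax) {
    stop(sprintf("lambda must lie in [0, %.4g] for this tree", lmax), call. = FALSE)
  }
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  child <- tree$edge[, 2]
  el <- tree$edge.length * lambda
  tip_edge <- child <= n
  el[tip_edge] <- el[tip_edge] + (1 - lambda) * depth[child[tip_edge]]
  tree$edge.length <- el
  tree
}

#' Maximum admissible lambda for a tree
#'
#' Largest `lambda` for which the lambda transform keeps every terminal
#' branch non-negative: `min_i(tip depth_i / parent depth_i)`.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return A number `>= 1` (Inf for a star tree).
#' @export
lambda_max <- function(tree) {
  check_phylo(tree)
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  child <- tree$edge[, 2]
  parent <- tree$edge[, 1]
  tip_edge <- child <= n
  parent_depth <- depth[parent[tip_edge]]
  tip_depth <- depth[child[tip_edge]]
  pos <- parent_depth > 0
  if (!any(pos)) return(Inf)
  min(tip_depth[pos] / parent_depth[pos])
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Estimates the strength of phylogenetic signal in a continuous trait under
#' the lambda model: tip values are multivariate normal with covariance
#' `sigma2 * C(lambda)`, where `C(lambda)` is the Brownian-motion covariance
#' with off-diagonals multiplied by `lambda`. For each candidate `lambda` the
#' rate `sigma2` and root state are solved in closed form by generalized least
#' squares; `lambda` itself is profiled over `[0, lambda_max]` with a coarse
#' grid scan followed by bounded optimization (so local optima on rugged
#' profiles are avoided). Significance of signal comes from a likelihood-ratio
#' test of `lambda_hat` against `lambda = 0`; because 0 is a boundary of the
#' parameter space, the default reference distribution is the 50:50 mixture of
#' a point mass at 0 and chi-squared with 1 df (`p_method = "mixture"`); plain
#' chi-squared 1 df is available as `"chisq1"`.
#'
#' Traits are typically analyzed on a log10 scale; the lambda estimate is
#' invariant to affine transformations of the trait (and hence to the log
#' base).
#'
#' @param tree A rooted `phylo` object with branch lengths; tips not named in
#'   the trait are pruned.
#' @param trait A named numeric vector, or a data frame whose first column is
#'   the species id and second column the trait value (columns named
#'   `species_id`/`value` are used when present).
#' @param p_method Reference distribution for the LRT p value.
#' @param grid_n Number of points in the pre-scan grid over
#'   `[0, lambda_max]`.
#' @return An object of class `lambda_fit`: `lambda` (the ML estimate),
#'   `sigma2`, `root_state`, `logLik`, `logLik0` (at lambda = 0), `lrt`,
#'   `p_value`, `lambda_max`, `n`, `p_method`.
#' @examples
#' cfg <- simulation_config(seed = 7, n_species = 50)
#' tr <- simulate_tree(cfg)
#' x <- simulate_bm_trait(tr, cfg)
#' fit_pagel_lambda(tr, x)
#' @export
fit_pagel_lambda <- function(tree, trait, p_method = c("mixture", "chisq1"),
                             grid_n = 21) {
  p_method <- match.arg(p_method)
  x <- as_trait_vector(trait)
  check_phylo(tree)
  missing_tips <- setdiff(names(x), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("trait species not in the tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 tips with trait values", call. = FALSE)
  if (any(!is.finite(x))) stop("trait values must be finite", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in trait", call. = FALSE)
  if (length(x) < ape::Ntip(tree)) {
    tree <- ape::keep.tip(tree, names(x))
  }
  C <- ape::vcv(tree)[names(x), names(x)]
  lmax <- min(lambda_max(tree), 10)  # cap profiling range on pathological trees
  n <- length(x)

  nll <- function(lam) -pagel_profile_loglik(C, x, lam)$logLik

  grid <- seq(0, lmax, length.out = max(5, grid_n))
  gvals <- vapply(grid, nll, numeric(1))
  i <- which.min(gvals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-8)
  cand <- rbind(c(opt$minimum, opt$objective),
                c(grid[i], gvals[i]),
                c(0, gvals[1]),
                c(lmax, gvals[length(gvals)]))
  best <- cand[which.min(cand[, 2]), ]
  lam_hat <- best[1]
  fit <- pagel_profile_loglik(C, x, lam_hat)
  logL0 <- pagel_profile_loglik(C, x, 0)$logLik
  lrt <- max(0, 2 * (fit$logLik - logL0))
  p <- if (p_method == "mixture") {
    if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  structure(list(
    lambda = lam_hat, sigma2 = fit$sigma2, root_state = fit$root_state,
    logLik = fit$logLik, logLik0 = logL0, lrt = lrt, p_value = p,
    lambda_max = lmax, n = n, p_method = p_method
  ), class = "lambda_fit")
}

# Profile log-likelihood of the lambda model at a fixed lambda:
# sigma2 and root state solved by GLS through a Cholesky factorization.
pagel_profile_loglik <- function(C, x, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(list(logLik = -Inf, sigma2 = NA_real_, root_state = NA_real_))
  n <- length(x)
  L <- t(U)
  w <- forwardsolve(L, cbind(rep(1, n), x))
  one_v_one <- sum(w[, 1]^2)
  one_v_x <- sum(w[, 1] * w[, 2])
  root <- one_v_x / one_v_one
  wr <- w[, 2] - root * w[, 1]
  q <- sum(wr^2)
  sigma2 <- q / n
  logdet <- 2 * sum(log(diag(U)))
  logLik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(logLik = logLik, sigma2 = sigma2, root_state = root)
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda ML fit (n = %d tips)\n", x$n))
  cat(sprintf("  lambda = %.4f (search bound %.3g), sigma2 = %.4g, root = %.4g\n",
              x$lambda, x$lambda_max, x$sigma2, x$root_state))
  cat(sprintf("  logL = %.4f, logL(lambda=0) = %.4f\n", x$logLik, x$logLik0))
  cat(sprintf("  LRT = %.4f, p = %.3g (%s)\n", x$lrt, x$p_value, x$p_method))
  invisible(x)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts by the standard pruning recursion: at each internal
#' node of a fully bifurcating tree, the contrast is
#' `(x1 - x2) / sqrt(v1 + v2)` where `v` are the (extended) child branch
#' lengths; the ancestral value is the precision-weighted mean and the parent
#' branch is extended by `v1 v2 / (v1 + v2)`. Polytomies are resolved to
#' zero-length bifurcations first (with a message giving the count). A tree
#' with `n` tips yields `n - 1` contrasts.
#'
#' @param tree A rooted `phylo` object with non-negative branch lengths.
#' @param trait Named numeric vector or two-column data frame (see
#'   [fit_pagel_lambda()]).
#' @return A tibble of class `contrast_set` with columns `node` (ape internal
#'   node id), `contrast` (standardized) and `variance` (expected variance
#'   `v1 + v2`).
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' pic_contrasts(tr, c(A = 3, B = 1)) # contrast 2/sqrt(2)
#' @export
pic_contrasts <- function(tree, trait) {
  x <- as_trait_vector(trait)
  check_phylo(tree)
  missing_tips <- setdiff(names(x), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("trait species not in the tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  if (length(x) < ape::Ntip(tree)) tree <- ape::keep.tip(tree, names(x))
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (!ape::is.binary(tree)) {
    n_poly <- ape::Nnode(tree)
    tree <- ape::multi2di(tree, random = FALSE)
    message("resolved ", ape::Nnode(tree) - n_poly,
            " polytomy node(s) to zero-length bifurcations")
  }
  n <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "postorder")
  nnode <- tr$Nnode
  val <- c(x[tr$tip.label], rep(NA_real_, nnode))
  vlen <- c(rep(0, n + nnode))
  edge_len <- tr$edge.length
  parent <- tr$edge[, 1]
  child <- tr$edge[, 2]

  contrast <- numeric(nnode)
  variance <- numeric(nnode)
  node_id <- integer(nnode)
  k <- 0
  # postorder edge list visits both child edges of a node consecutively
  for (e in seq(1, length(parent), by = 2)) {
    nd <- parent[e]
    c1 <- child[e]; c2 <- child[e + 1]
    v1 <- edge_len[e] + vlen[c1]
    v2 <- edge_len[e + 1] + vlen[c2]
    if (v1 + v2 <= 0) {
      stop("zero expected variance at an internal node (two zero-length ",
           "sister branches); add branch lengths", call. = FALSE)
    }
    k <- k + 1
    contrast[k] <- (val[c1] - val[c2]) / sqrt(v1 + v2)
    variance[k] <- v1 + v2
    node_id[k] <- nd
    val[nd] <- (val[c1] / v1 + val[c2] / v2) / (1 / v1 + 1 / v2)
    vlen[nd] <- v1 * v2 / (v1 + v2)
  }
  out <- tibble::tibble(node = node_id, contrast = contrast, variance = variance)
  class(out) <- c("contrast_set", class(out))
  attr(out, "n_tips") <- n
  out
}

#' Correlation of two traits through independent contrasts
#'
#' Computes contrasts for both traits on the shared tree and correlates them
#' through the origin (the sign of each contrast is arbitrary, so the
#' regression must have no intercept). The test statistic is
#' `t = r * sqrt(df / (1 - r^2))` with `df = n_contrasts - 1`.
#'
#' @param tree A rooted `phylo` object.
#' @param x,y Named numeric vectors or two-column data frames of trait values.
#' @return A one-row tibble: `estimate` (through-origin correlation), `slope`
#'   (through-origin regression slope of y-contrasts on x-contrasts),
#'   `statistic`, `df`, `p_value`, `n_contrasts`.
#' @export
pic_correlation <- function(tree, x, y) {
  xv <- as_trait_vector(x)
  yv <- as_trait_vector(y)
  common <- intersect(names(xv), names(yv))
  common <- intersect(common, tree$tip.label)
  if (length(common) < 3) stop("need at least 3 species shared by tree and both traits",
                               call. = FALSE)
  tree <- ape::keep.tip(tree, common)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  cx <- pic_contrasts(tree, xv[common])$contrast
  cy <- pic_contrasts(tree, yv[common])$contrast
  sxx <- sum(cx^2); syy <- sum(cy^2); sxy <- sum(cx * cy)
  if (sxx == 0 || syy == 0) stop("zero contrast variance", call. = FALSE)
  r <- sxy / sqrt(sxx * syy)
  df <- length(cx) - 1
  if (abs(r) >= 1) {
    tstat <- Inf * sign(r); p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  tibble::tibble(estimate = r, slope = sxy / sxx, statistic = tstat, df = df,
                 p_value = p, n_contrasts = length(cx))
}

# ---- internal helpers -------------------------------------------------------

check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label) > 0) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(tree)
}

as_trait_vector <- function(trait) {
  if (is.data.frame(trait)) {
    cols <- names(trait)
    sp_col <- if ("species_id" %in% cols) "species_id" else cols[1]
    val_col <- if ("value" %in% cols) "value" else setdiff(cols, sp_col)[1]
    out <- stats::setNames(as.numeric(trait[[val_col]]), as.character(trait[[sp_col]]))
  } else if (is.numeric(trait) && !is.null(names(trait))) {
    out <- trait
  } else {
    stop("trait must be a named numeric vector or a species/value data frame",
         call. = FALSE)
  }
  if (anyDuplicated(names(out)) > 0) {
    stop("duplicate species in trait: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  }
  out
}
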