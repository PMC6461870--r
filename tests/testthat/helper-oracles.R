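# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# SMA loss: sum of right-triangle areas between points and the line
# y = a + b x, with the intercept profiled out (a = mean(y) - b mean(x)).
sma_triangle_loss <- function(b, x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum((yc - b * xc)^2) / (2 * abs(b))
}

# Brute-force SMA slope: numeric minimization of the triangle-area loss over
# both sign branches on a log scale.
brute_force_sma_slope <- function(x, y) {
  best <- NULL
  for (s in c(-1, 1)) {
    opt <- stats::optimize(function(t) sma_triangle_loss(s * exp(t), x, y),
                           interval = c(-15, 15), tol = 1e-12)
    if (is.null(best) || opt$objective < best$objective) {
      best <- list(slope = s * exp(opt$minimum), objective = opt$objective)
    }
  }
  best$slope
}

# Dense-matrix GLS log-likelihood of the lambda model, written directly from
# the multivariate-normal density with solve() and determinant().
dense_lambda_loglik <- function(tree, x, lambda) {
  C <- ape::vcv(tree)[names(x), names(x)]
  V <- lambda * C
  diag(V) <- diag(C)
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  root <- as.numeric((t(one) %*% Vi %*% x) / (t(one) %*% Vi %*% one))
  q <- as.numeric(t(x - root) %*% Vi %*% (x - root))
  s2 <- q / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus + n))
}

# Bivariate sample whose population SMA slope is `slope` and population
# correlation is sign(slope) * r (0 < r < 1 controls the noise level).
simulate_sma_pairs <- function(n, slope, r) {
  x <- stats::rnorm(n)
  y <- slope * r * x + sqrt(1 - r^2) * abs(slope) * stats::rnorm(n)
  data.frame(x = x, y = y)
}
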