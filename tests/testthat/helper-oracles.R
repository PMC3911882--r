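# Shared fixture builders and independent oracles used across test files.

# n x m design with mean-zero columns and (1/n) X'X = I: QR of a
# column-centered Gaussian matrix keeps columns orthogonal to the 1-vector.
orthonormal_design <- function(n, m, seed) {
  withr::with_seed(seed, {
    A <- scale(matrix(rnorm(n * m), n, m), center = TRUE, scale = FALSE)
    sqrt(n) * qr.Q(qr(A))
  })
}

# Independent Lasso oracle: minimize (1/2n)||y - Xb||^2 + lambda*||b||_1 by
# box-constrained L-BFGS-B on the smooth reformulation b = u - v, u, v >= 0.
lasso_optim_oracle <- function(X, y, lambda) {
  n <- nrow(X); m <- ncol(X)
  obj <- function(uv) {
    b <- uv[1:m] - uv[(m + 1):(2 * m)]
    sum((y - X %*% b)^2) / (2 * n) + lambda * sum(uv)
  }
  grd <- function(uv) {
    b <- uv[1:m] - uv[(m + 1):(2 * m)]
    g <- -as.numeric(crossprod(X, y - X %*% b)) / n
    c(g + lambda, -g + lambda)
  }
  opt <- stats::optim(rep(0, 2 * m), obj, grd, method = "L-BFGS-B",
                      lower = 0, control = list(factr = 10, maxit = 10000))
  opt$par[1:m] - opt$par[(m + 1):(2 * m)]
}

# Mann-Whitney AUC oracle: fraction of (member, non-member) pairs where the
# member outranks (smaller rank than) the non-member, ties counted half.
mann_whitney_auc <- function(rank, member) {
  rm <- rank[member]; rn <- rank[!member]
  wins <- 0
  for (a in rm) wins <- wins + sum(a < rn) + 0.5 * sum(a == rn)
  wins / (length(rm) * length(rn))
}

# Every (rank, printed percentile) pair from the single-gene results tables
# (exposure-time series and concentration series), display convention included.
published_percentile_pairs <- function() {
  data.frame(
    rank = c(2080, 4686, 588, 859,
             1752, 4078, 20, 426,
             1716, 1461, 483, 291,
             1835, 852, 39, 56,
             5714, 4068, 1543, 1133,
             1812, 1047, 498, 160,
             2081, 1489, 73, 149,
             1835, 852, 39, 56,
             2302, 1119, 93, 105,
             1934, 775, 40, 66,
             2007, 721, 74, 116),
    display = c("69", "30", "91", "87",
                "74", "39", "99.7", "94",
                "74", "78", "93", "96",
                "73", "87", "99", "99",
                "14", "39", "77", "83",
                "73", "84", "93", "98",
                "69", "78", "99", "98",
                "73", "87", "99", "99",
                "66", "83", "99", "98",
                "71", "88", "99", "99",
                "70", "89", "99", "98"),
    stringsAsFactors = FALSE)
}

# Small random compendium of independent noise genes.
noise_compendium <- function(p, n, seed, sd = 1) {
  withr::with_seed(seed, {
    Y <- matrix(rnorm(p * n, sd = sd), p, n,
                dimnames = list(sprintf("g%03d", seq_len(p)),
                                sprintf("s%d", seq_len(n))))
    expression_compendium(Y)
  })
}
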