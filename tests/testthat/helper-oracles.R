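# Shared fixtures and independent brute-force oracles used across test files.

# random regression data frame with outcome column "y"
make_data <- function(n, p, beta = NULL, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  if (is.null(beta)) beta <- rep(0, p)
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- as.numeric(X %*% beta) + rnorm(n, sd = sd)
  d
}

# design with X'X/n = I and mean-zero columns (via QR of a centered matrix)
make_orthonormal_data <- function(n, p, seed = 1) {
  set.seed(seed)
  A <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(A))
  X <- sqrt(n) * Q
  colnames(X) <- paste0("x", seq_len(p))
  X
}

# brute-force grid minimizer of 0.5*(z - b)^2 + penalty(|b|)
grid_threshold <- function(z, spec, weight = 1, step = 5e-5) {
  lo <- min(0, z) - 0.5
  hi <- max(0, z) + 0.5
  b <- seq(lo, hi, by = step)
  obj <- 0.5 * (z - b)^2 + penalty_value(abs(b), spec, weight)
  b[which.min(obj)]
}

# penalized least-squares objective on the standardized scale
pls_objective <- function(Xs, yc, beta, spec) {
  n <- nrow(Xs)
  sum((yc - Xs %*% beta)^2) / (2 * n) +
    sum(penalty_value(abs(beta), spec))
}

# nested-grid brute-force minimizer of the p = 2 lasso objective
grid_lasso_p2 <- function(Xs, yc, lambda, levels = 4, pts = 21) {
  spec <- penalty_spec("lasso", lambda = lambda)
  ctr <- c(0, 0)
  half <- max(abs(crossprod(Xs, yc)) / nrow(Xs)) + 0.5
  for (l in seq_len(levels)) {
    g1 <- seq(ctr[1] - half, ctr[1] + half, length.out = pts)
    g2 <- seq(ctr[2] - half, ctr[2] + half, length.out = pts)
    grid <- expand.grid(b1 = g1, b2 = g2)
    obj <- apply(grid, 1L, function(b) pls_objective(Xs, yc, b, spec))
    ctr <- as.numeric(grid[which.min(obj), ])
    half <- half * 2 / (pts - 1)  # next level spans two old grid cells
  }
  ctr
}

# standardization identical to the solver's internal one
std_xy <- function(d, outcome = "y") {
  X <- as.matrix(d[setdiff(names(d), outcome)])
  y <- d[[outcome]]
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  xsd <- sqrt(colMeans(Xc^2))
  list(Xs = sweep(Xc, 2, xsd, "/"), yc = y - mean(y), xbar = xbar,
       xsd = xsd, ybar = mean(y))
}
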