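# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the libraries standing behind them) so that
# implementation and check stay separate routes.

# Flood-fill connected-component count (8- or 4-connectivity), queue based.
flood_fill_count <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    moves <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    moves <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- matrix(c(i, j), ncol = 2)
    seen[i, j] <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(moves))) {
        r <- p[1] + moves[k, 1]; c <- p[2] + moves[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  count
}

# All-pairs nearest-neighbour distances, O(n^2) scan.
brute_force_nn <- function(centroids) {
  n <- nrow(centroids)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Step-up BH adjustment written out directly.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# OLS (normal equations) with a t test on a chosen coefficient.
ols_oracle <- function(y, X, coef_index) {
  xtx <- solve(t(X) %*% X)
  beta <- xtx %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtx))
  tval <- beta[coef_index] / se[coef_index]
  list(beta = as.numeric(beta), se = unname(se),
       p = unname(2 * pt(-abs(tval), df = df)))
}

# One-way balanced ANOVA method-of-moments variance components.
anova_varcomp_oracle <- function(values, line) {
  line <- factor(line)
  r <- as.numeric(table(line)[1])
  stopifnot(all(table(line) == r))
  means <- tapply(values, line, mean)
  grand <- mean(values)
  k <- nlevels(line)
  msb <- r * sum((means - grand)^2) / (k - 1)
  msw <- sum((values - means[line])^2) / (k * (r - 1))
  list(var_line = (msb - msw) / r, var_residual = msw)
}

# Threshold a generated synthetic image at mid-contrast (ground-truth mask).
truth_bright_mask <- function(eye) {
  lat <- eye$truth$lattice
  eye$image > (lat$background_level + lat$dot_level) / 2
}

# Expected blob count from the ground-truth fusion graph (union-find).
expected_component_count <- function(truth) {
  n <- truth$true_count
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(truth$fused_pairs) > 0) {
    for (k in seq_len(nrow(truth$fused_pairs))) {
      a <- find(truth$fused_pairs[k, 1]); b <- find(truth$fused_pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
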