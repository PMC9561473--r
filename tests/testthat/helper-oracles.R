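# Independent oracle implementations and fixture builders. These are kept
# deliberately naive (explicit loops, full matrices, textbook formulas) so
# they stay independent of the vectorized code paths they check.

random_embedding <- function(n, d, seed) {
  withr::with_seed(seed, matrix(rnorm(n * d), nrow = n, ncol = d))
}

# OLS slope via the generic linear-model solver.
oracle_slope <- function(x, y) {
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# Dissimilarity selection replayed with a full distance matrix and explicit
# set bookkeeping.
oracle_select <- function(embedding, n, gamma, k, start, seed) {
  N <- nrow(embedding)
  D2 <- as.matrix(stats::dist(embedding))^2
  S <- exp(-gamma * D2)
  diag(S) <- 1
  selected <- start
  excluded <- c(start)
  remaining <- setdiff(seq_len(N), excluded)
  withr::with_seed(seed, {
    while (length(selected) < n) {
      if (length(remaining) == 0 || length(remaining) < k) break
      anchor <- selected[length(selected)]
      sims <- S[anchor, ]
      ties <- remaining[sims[remaining] == min(sims[remaining])]
      pick <- if (length(ties) == 1) ties else ties[sample.int(length(ties), 1)]
      selected <- c(selected, pick)
      excluded <- c(excluded, pick)
      remaining <- setdiff(remaining, pick)
      if (k > 0 && length(remaining) > 0) {
        nn <- remaining[order(sims[remaining], decreasing = TRUE)]
        nn <- nn[seq_len(min(k, length(nn)))]
        excluded <- c(excluded, nn)
        remaining <- setdiff(remaining, nn)
      }
    }
  })
  list(selected = selected, excluded = excluded)
}

# Benjamini-Hochberg step-up from the textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sample KS statistic as the exhaustive supremum of ECDF gaps.
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# AUROC by pair counting, ties worth 1/2.
oracle_auroc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# 2000 cells in 10 well-separated isotropic Gaussian components on a circle.
mixture_embedding <- function(seed) {
  withr::with_seed(seed, {
    ang <- seq(0, 2 * pi, length.out = 11)[1:10]
    means <- cbind(20 * cos(ang), 20 * sin(ang))
    comp <- rep(1:10, each = 200)
    emb <- means[comp, ] + matrix(rnorm(4000), ncol = 2)
    list(embedding = emb, component = comp)
  })
}

# Spot lattice with one marker confined to a corner block: the fixture used
# for inverse-mode annotation checks. Expression is log1p scale, as scored
# in practice; the marker is crisply confined to the block.
block_marker_fixture <- function(n_side = 20, block = 3, n_genes = 100,
                                 seed = 303) {
  withr::with_seed(seed, {
    coords <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
    n <- nrow(coords)
    in_block <- coords[, 1] <= block & coords[, 2] <= block
    X <- matrix(rpois(n * n_genes, lambda = 3), nrow = n,
                dimnames = list(paste0("spot_", seq_len(n)),
                                paste0("g", seq_len(n_genes))))
    X[, 1] <- ifelse(in_block, 20, 0)
    list(coords = coords, X = log1p(X), in_block = in_block,
         marker = "g1", gamma = 1)
  })
}
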