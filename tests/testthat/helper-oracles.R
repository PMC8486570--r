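# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# diagonal-covariance Gaussian discriminant: class posterior from explicit
# density evaluation (oracle for NSC at delta = 0)
oracle_gaussian_posterior <- function(x, centroids, sds, priors) {
  logd <- vapply(seq_len(nrow(centroids)), function(k) {
    sum(stats::dnorm(x, mean = centroids[k, ], sd = sds, log = TRUE)) +
      log(priors[k])
  }, numeric(1))
  e <- exp(logd - max(logd))
  e / sum(e)
}

# naive agglomerative complete-linkage clustering; returns the sorted merge
# heights and the set partition after every merge
oracle_complete_linkage <- function(x, dist_fun = function(a, b) sum(abs(a - b))) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- dist_fun(x[i, ], x[j, ])
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) { best_h <- h; best <- c(a, b) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, function(cl) sort(cl))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a set partition (for comparing clusterings)
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, min, 0L))]
}

# partition of 1..n induced by cutree at k groups
hclust_partition <- function(hc, k) {
  ct <- stats::cutree(hc, k = k)
  canon_partition(unname(split(seq_along(ct), ct)))
}

# two-sample log-rank chi-squared computed from first principles
oracle_logrank_chisq <- function(time, event, g) {
  g <- as.logical(g)
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n1 <- sum(at & g); n0 <- sum(at & !g); nn <- n1 + n0
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / nn
    if (nn > 1) V <- V + d * (n1 / nn) * (n0 / nn) * (nn - d) / (nn - 1)
  }
  (O - E)^2 / V
}

# exhaustive scan for the orientation-free Youden-type cutoff
oracle_best_cutoff <- function(expr, status) {
  u <- sort(unique(expr))
  cand <- (u[-1] + u[-length(u)]) / 2
  ne <- sum(status == 1); nc <- sum(status == 0)
  best <- -Inf; best_c <- NA
  for (c in cand) {
    sens <- sum(expr > c & status == 1) / ne
    spec <- sum(expr <= c & status == 0) / nc
    sc <- max(sens + spec, 2 - sens - spec)
    if (sc > best + 1e-12) { best <- sc; best_c <- c }
  }
  best_c
}

# binomial (two-class) lasso by uniform-bound MM coordinate descent:
# oracle for the K = 2 multinomial reduction. Z must be standardized the
# same way as fit_multinomial_lasso standardizes (population SD).
oracle_binomial_lasso <- function(Z, yy, lambda, tol = 1e-9, max_iter = 20000) {
  n <- nrow(Z); J <- ncol(Z)
  b <- rep(0, J); b0 <- 0
  w <- 0.25
  for (it in seq_len(max_iter)) {
    eta <- drop(b0 + Z %*% b)
    p <- 1 / (1 + exp(-eta))
    rr <- (yy - p) / w
    ch <- 0
    upd <- mean(rr); b0 <- b0 + upd; rr <- rr - upd; ch <- max(ch, abs(upd))
    for (j in seq_len(J)) {
      g <- mean(Z[, j] * rr) + b[j]
      bn <- sign(g) * max(abs(g) - lambda / w, 0)
      dj <- bn - b[j]
      if (dj != 0) { rr <- rr - Z[, j] * dj; b[j] <- bn; ch <- max(ch, abs(dj)) }
    }
    if (ch < tol) break
  }
  list(b = b, b0 = b0)
}

# standardize columns to mean 0 / population SD 1 (mirrors the lasso's
# internal convention, recomputed independently)
standardize_pop <- function(x) {
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  scl[scl == 0] <- 1
  sweep(sweep(x, 2, ctr), 2, scl, "/")
}
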