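# Independent oracles used across the suite. Each re-derives a quantity by
# brute force or from first principles, on a code path disjoint from the
# package implementation.

# Tricube local-linear scatterplot smoother, coded from the textbook
# definition: per evaluation point, take the ns nearest neighbours (sliding
# window over sorted x), tricube weights scaled by the window half-width,
# weighted local-linear fit (falling back to a weighted mean when the
# weighted x-spread is negligible relative to the data range).
oracle_tricube_smooth <- function(x, y, f = 2/3) {
  o <- order(x); xs <- x[o]; ys <- y[o]; n <- length(x)
  ns <- max(2L, min(n, as.integer(f * n + 1e-7)))
  rng <- xs[n] - xs[1]
  fit <- numeric(n)
  nleft <- 1L; nright <- ns
  for (i in seq_len(n)) {
    while (nright < n) {
      d1 <- xs[i] - xs[nleft]; d2 <- xs[nright + 1L] - xs[i]
      if (d1 <= d2) break
      nleft <- nleft + 1L; nright <- nright + 1L
    }
    h <- max(xs[i] - xs[nleft], xs[nright] - xs[i])
    h9 <- 0.999 * h; h1 <- 0.001 * h
    j <- nleft:n
    r <- abs(xs[j] - xs[i])
    past <- which(r > h9 & xs[j] > xs[i])   # scan stops at first far right point
    if (length(past)) { j <- j[seq_len(past[1] - 1L)]; r <- r[seq_len(past[1] - 1L)] }
    w <- numeric(length(j))
    inw <- r <= h9
    w[inw] <- (1 - (r[inw] / h)^3)^3
    w[r <= h1] <- 1
    a <- sum(w)
    if (a <= 0) { fit[i] <- ys[i]; next }
    w <- w / a
    if (h > 0) {
      xb <- sum(w * xs[j])
      cc <- sum(w * (xs[j] - xb)^2)
      if (sqrt(cc) > 0.001 * rng) {
        b <- (xs[i] - xb) / cc
        w <- w * (b * (xs[j] - xb) + 1)
      }
    }
    fit[i] <- sum(w * ys[j])
  }
  out <- numeric(n); out[o] <- fit
  out
}

# Brute-force local outlier factor: double loop over the full distance matrix.
oracle_lof <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  kdist <- numeric(n); nb <- vector("list", n)
  for (i in 1:n) {
    kdist[i] <- sort(D[i, ])[k]
    nb[[i]] <- which(D[i, ] <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    reach <- vapply(nb[[i]], function(j) max(kdist[j], D[i, j]), numeric(1))
    lrd[i] <- 1 / mean(reach)
  }
  vapply(1:n, function(i) mean(lrd[nb[[i]]]) / lrd[i], numeric(1))
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(which(p[o] >= p[o][i]), function(j) min(1, m * p[o][j] / j),
                   numeric(1))
    q[o[i]] <- min(cand)
  }
  q
}

# Exhaustive O(n^2) concordance under left truncation; same comparability
# convention as the implementation, enumerated pair by pair.
oracle_harrell_c <- function(entry, exit, event, score) {
  n <- length(exit)
  conc <- 0; tot <- 0
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (entry[j] < exit[i] && exit[j] > exit[i]) {
        tot <- tot + 1
        if (score[i] > score[j]) conc <- conc + 1
        else if (score[i] == score[j]) conc <- conc + 0.5
      }
    }
  }
  if (tot == 0) return(NA_real_)
  conc / tot
}

# Written-out Breslow partial log-likelihood for a single covariate, one
# stratum, no ties; maximized by stats::optimize.
oracle_cox1_loglik <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (i in which(event)) {
    at_risk <- entry < exit[i] & exit >= exit[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Shared small simulated survival fixture: exposure with known log hazard.
make_surv_fixture <- function(n, beta = 0.4, seed = 1, base_rate = 0.05,
                              max_fu = 25) {
  set.seed(seed)
  d <- data.frame(subject_id = sprintf("P%04d", 1:n),
                  entry_age = runif(n, 40, 60),
                  x = rnorm(n), stringsAsFactors = FALSE)
  d$sex <- sample(c("f", "m"), n, TRUE)
  d$center <- sample(c("A", "B"), n, TRUE)
  t_ev <- d$entry_age + rexp(n, base_rate * exp(beta * d$x))
  cens <- d$entry_age + runif(n, 1, max_fu)
  d$exit_age <- pmin(t_ev, cens)
  d$event <- t_ev <= cens
  d$endpoint <- "sim"
  d$stratum <- paste(d$sex, d$center, sep = "|")
  d
}
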