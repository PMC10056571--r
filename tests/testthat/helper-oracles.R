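# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# AUC by enumerating every positive-negative pair (half credit for ties)
oracle_auc <- function(markers, labels) {
  pos <- markers[labels == 1]
  neg <- markers[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden by exhaustive scan over every midpoint threshold (lowest wins ties)
oracle_youden <- function(markers, labels) {
  u <- sort(unique(markers))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    sens <- mean(markers[labels == 1] >= t)
    spec <- mean(markers[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$J + 1e-12)
      best <- list(threshold = t, J = j, sens = sens, spec = spec)
  }
  best
}

# exact two-sided McNemar p by direct binomial tail enumeration
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  tail <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * tail)
}

# ICC(A,1) point estimate via aov() mean squares
oracle_icc_a1 <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  d <- data.frame(y = as.vector(ratings),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# simple stratified bootstrap of a paired AUC difference
oracle_bootstrap_se_delta <- function(ma, mb, labels, reps = 10000) {
  ip <- which(labels == 1); ineg <- which(labels == 0)
  deltas <- vapply(seq_len(reps), function(r) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    oracle_auc(ma[idx], labels[idx]) - oracle_auc(mb[idx], labels[idx])
  }, 0)
  sd(deltas)
}
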