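# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: naive loops, explicit enumeration.

# Base-by-base mean mappability over [start, end); uncovered bases score 0.
oracle_mean_mappability <- function(chrom, start, end, track) {
  tr <- track[track$chrom == chrom, ]
  scores <- numeric(end - start)
  for (k in seq_len(end - start)) {
    base <- start + k - 1L  # 0-based position
    hit <- which(tr$start <= base & tr$end > base)
    if (length(hit) == 1L) scores[k] <- tr$score[hit]
  }
  mean(scores)
}

# Exhaustive maximisation over all 3^T state paths of the HMM joint
# log-likelihood. em: T x 3 emission log-lik matrix (cols CN1, CN2, CN3).
oracle_viterbi <- function(em, transition_prob = 1e-4, expected_cnv_targets = 5) {
  t <- transition_prob
  E <- expected_cnv_targets
  s <- 1 - 1 / E
  A <- log(rbind(c(s, 1 / E - t, t),
                 c(t, 1 - 2 * t, t),
                 c(t, 1 / E - t, s)))
  init <- log(c(t, 1 - 2 * t, t))
  Tn <- nrow(em)
  paths <- as.matrix(expand.grid(rep(list(1:3), Tn)))
  score <- apply(paths, 1, function(p) {
    v <- init[p[1]] + em[1, p[1]]
    if (Tn > 1) for (k in 2:Tn) v <- v + A[p[k - 1], p[k]] + em[k, p[k]]
    v
  })
  list(score = max(score), path = paths[which.max(score), ])
}

# Exhaustive best subset of controls under the aggregate-correlation
# objective.
oracle_best_subset <- function(test, pool) {
  n <- ncol(pool)
  best <- -Inf
  best_set <- NULL
  for (m in seq_len(2^n - 1)) {
    ss <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    r <- suppressWarnings(cor(test, rowSums(pool[, ss, drop = FALSE])))
    if (!is.na(r) && r > best) {
      best <- r
      best_set <- ss
    }
  }
  list(set = best_set, r = best)
}

# A 6-control pool with graded control quality: shared log-normal target
# profile, controls carrying increasing independent log-normal noise.
make_graded_pool <- function(seed, n_targets = 300) {
  set.seed(seed)
  mu <- rlnorm(n_targets, log(200), 1)
  test <- rnbinom(n_targets, size = 100, mu = mu)
  noise_sd <- seq(0.05, 0.8, length.out = 6)
  pool <- sapply(noise_sd, function(s) {
    rnbinom(n_targets, size = 100, mu = mu * exp(rnorm(n_targets, 0, s)))
  })
  colnames(pool) <- paste0("c", 1:6)
  list(test = test, pool = pool)
}
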