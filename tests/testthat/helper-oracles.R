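# Independent brute-force oracles used to check the fast implementations.
# These deliberately use the slow, obvious algorithm.

# Mann-Whitney AUC by exhaustive pairwise comparison, O(n^2).
oracle_mw_auc <- function(values, labels, direction = "above") {
  s <- if (direction == "below") -values else values
  pos <- s[labels]
  neg <- s[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Youden search by exhaustive enumeration of every candidate cutoff.
oracle_youden_j <- function(values, labels, direction = "above") {
  s <- if (direction == "below") -values else values
  u <- sort(unique(s))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- -Inf
  for (t in cand) {
    pos <- s >= t
    j <- sum(pos & labels) / sum(labels) + sum(!pos & !labels) / sum(!labels) - 1
    if (j > best) best <- j
  }
  best
}

# ROC vertices by classifying at every distinct threshold, O(n^2).
oracle_roc_vertices <- function(values, labels, direction = "above") {
  s <- if (direction == "below") -values else values
  ts <- sort(unique(s), decreasing = TRUE)
  fpr <- tpr <- numeric(length(ts))
  for (i in seq_along(ts)) {
    pos <- s >= ts[i]
    tpr[i] <- sum(pos & labels) / sum(labels)
    fpr[i] <- sum(pos & !labels) / sum(!labels)
  }
  rbind(c(0, 0), cbind(fpr, tpr))
}

# Density crossing of a 2-component weighted Gaussian mixture located on
# a fine grid between the means.
oracle_density_crossing <- function(w, m, s, step = 1e-6) {
  xs <- seq(m[1], m[2], by = step)
  d <- w[1] * dnorm(xs, m[1], s[1]) - w[2] * dnorm(xs, m[2], s[2])
  xs[which.min(abs(d))]
}

# Small random marker/label instance generator for property tests.
random_instance <- function(n = 40, ties = TRUE) {
  values <- if (ties) sample(1:8, n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)
  else rnorm(n)
  labels <- rbinom(n, 1, 0.4) == 1
  if (!any(labels)) labels[1] <- TRUE
  if (all(labels)) labels[1] <- FALSE
  list(values = values, labels = labels)
}

# A fitted csf_gmm-shaped object built directly from known parameters,
# bypassing EM (for cutoff-rule unit tests).
gmm_from_pars <- function(w, m, s) {
  structure(list(weights = w, means = m, sds = s,
                 log_likelihood = NA_real_, n_iter = 0L, converged = TRUE,
                 loglik_trace = numeric(0), n = 0L, k = length(w),
                 data = numeric(0)),
            class = "csf_gmm")
}
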