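# Independent brute-force oracles, deliberately written in a naive style
# (loops, explicit formulas) so they share no code path with the package.

# naive percentile: linear interpolation between closest order statistics
naive_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

# naive recomputation of the 19 histogram features from the raw value list
naive_features <- function(v, bin_width = 25) {
  n <- length(v)
  mu <- sum(v) / n
  dev <- v - mu
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  p10 <- naive_percentile(v, 0.10); p90 <- naive_percentile(v, 0.90)
  inr <- v[v >= p10 & v <= p90]
  # histogram with min-anchored fixed-width bins
  b <- floor((v - min(v)) / bin_width)
  cnt <- sapply(sort(unique(b)), function(k) sum(b == k))
  pr <- cnt / n
  c(energy = sum(v * v),
    entropy = -sum(pr * log(pr, base = 2)),
    minimum = min(v),
    percentile_2_5 = naive_percentile(v, 0.025),
    percentile_10 = p10,
    median = naive_percentile(v, 0.5),
    mean = mu,
    percentile_90 = p90,
    percentile_97_5 = naive_percentile(v, 0.975),
    maximum = max(v),
    interquartile_range = naive_percentile(v, 0.75) -
      naive_percentile(v, 0.25),
    range = max(v) - min(v),
    mean_absolute_deviation = sum(abs(dev)) / n,
    robust_mean_absolute_deviation =
      sum(abs(inr - sum(inr) / length(inr))) / length(inr),
    root_mean_square = sqrt(sum(v * v) / n),
    standard_deviation = sqrt(m2),
    variance = m2,
    skewness = if (m2 > 0 && n >= 2) m3 / (sqrt(m2)^3) else NaN,
    kurtosis = if (m2 > 0 && n >= 2) m4 / (m2 * m2) else NaN,
    uniformity = sum(pr * pr))
}

# direct three-clause HPDv re-evaluation (rule-engine oracle)
oracle_hpdv <- function(v, d, ttf_days) {
  if (any(is.na(v))) return("NOT_EVALUABLE")
  pre <- (v[2] - v[1]) / (d[2] - d[1])
  post <- (v[3] - v[2]) / (d[3] - d[2])
  ok <- ttf_days < 2 * 30.44 &&
    pre > 0 && post / pre >= 2 &&
    (v[3] - v[2]) / v[2] >= 0.5
  if (ok) "HPDV" else "NON_HPDV"
}

oracle_nelson <- function(vb, vf) {
  chg <- 100 * (vf - vb) / vb
  if (chg >= 25) "PROGRESSION"
  else if (chg <= -25) "PARTIAL_RESPONSE"
  else "STABLE"
}

# naive Kaplan-Meier: product-limit over distinct event times
naive_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# naive two-group log-rank chi-square via risk-set tabulation
naive_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    n1 <- sum(time >= t & group == g1)
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# random masked patch for property tests (not via generate_patch)
random_patch <- function(seed) {
  set.seed(seed)
  d <- c(sample(2:5, 1), sample(4:9, 1), sample(4:9, 1))
  intens <- array(rnorm(prod(d), mean = runif(1, -100, 100),
                        sd = runif(1, 1, 80)), dim = d)
  mask <- array(runif(prod(d)) < 0.6, dim = d)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  voxel_patch(intens, mask, spacing = runif(3, 0.5, 3))
}

# clustered binary outcomes with EXACT marginal logistic model via a
# Gaussian-copula shared cluster factor (latent random intercept)
sim_clustered_logistic <- function(n_clusters, size = 3, beta0 = -0.5,
                                   beta1 = 1, rho = 0.4) {
  g <- rep(seq_len(n_clusters), each = size)
  x <- rnorm(n_clusters * size)
  p <- plogis(beta0 + beta1 * x)
  w <- sqrt(rho) * rnorm(n_clusters)[g] +
    sqrt(1 - rho) * rnorm(n_clusters * size)
  list(y = as.integer(pnorm(w) < p), x = x, cluster = g)
}

fixture_classified <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_cohort()
      cls <- classify_lesions(fx$lesions, fx$patients)
      cache <<- list(fx = fx, cls = cls,
                     dr = classify_patients_dr(cls))
    }
    cache
  }
})
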