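#' Logistic generalized estimating equations with exchangeable correlation
#'
#' Marginal logistic regression for clustered binary outcomes (lesions
#' nested in patients) solved by iteratively reweighted estimating
#' equations.  The working correlation is exchangeable: every pair of
#' observations in a cluster shares one correlation parameter `alpha`,
#' re-estimated at each iteration by the usual moment estimator on Pearson
#' residuals.  Standard errors come from the Liang-Zeger robust sandwich
#' covariance, so inference is valid even when the working correlation is
#' misspecified.  With all cluster sizes equal to 1 the solution coincides
#' with the ordinary logistic-regression MLE.
#'
#' Non-convergence (including quasi-complete separation, detected as
#' diverging coefficients) is reported through `converged = FALSE` and a
#' `message`, never as an error, so screening loops can continue.
#'
#' @param y binary 0/1 outcome vector.
#' @param X design matrix (an intercept column is prepended unless the first
#'   column is constant 1).
#' @param cluster cluster identifier per row of `X` (patient id).
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param scale `"estimate"` (moment estimate of the dispersion, default) or
#'   a fixed numeric value (e.g. 1).
#' @param maxit,tol iteration cap and relative coefficient tolerance.
#' @return Object of class `gee_fit`: `coefficients`, `robust_vcov`,
#'   `se_robust`, `z`, `p_value`, odds ratios with 95% CI (`or`, `or_lower`,
#'   `or_upper`), working `alpha`, dispersion `phi`, `n_clusters`, `n_obs`,
#'   `converged`, `linear_predictor`, `fitted`.
#' @examples
#' set.seed(1)
#' x <- rnorm(80); y <- rbinom(80, 1, plogis(x))
#' fit <- gee_logistic(y, cbind(1, x), cluster = seq_len(80))
#' fit$coefficients
#' @export
gee_logistic <- function(y, X, cluster, corstr = c("exchangeable",
                                                   "independence"),
                         scale = "estimate", maxit = 100, tol = 1e-6) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (nrow(X) != length(y) || length(cluster) != length(y))
    stop("`y`, `X` and `cluster` must have matching lengths")
  if (!all(abs(X[, 1] - 1) < 1e-12)) X <- cbind(`(Intercept)` = 1, X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  p <- ncol(X)
  nonconst <- apply(X[, -1, drop = FALSE], 2, function(c) stats::var(c) > 0)
  if (p > 1L && !all(nonconst))
    stop("constant non-intercept column in design matrix")
  g <- as.integer(factor(cluster))
  K <- max(g)
  if (K < 2L) stop("need at least 2 clusters")
  nsz <- tabulate(g)
  N <- length(y)

  # initialize at the independence (glm) solution
  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y,
      family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  if (anyNA(beta)) beta <- ifelse(is.na(beta), 0, beta)

  alpha <- 0; phi <- 1
  converged <- FALSE; msg <- NULL
  pairs_n <- sum(nsz * (nsz - 1)) / 2

  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    if (any(v < 1e-12)) v <- pmax(v, 1e-12)
    e <- (y - mu) / sqrt(v)                     # Pearson residuals
    phi_hat <- sum(e^2) / (N - p)
    phi <- if (identical(scale, "estimate")) phi_hat else as.numeric(scale)
    if (corstr == "exchangeable" && pairs_n > p) {
      se_g <- rowsum(e, g)
      s2_g <- rowsum(e^2, g)
      cross <- sum(se_g^2 - s2_g) / 2
      alpha <- cross / ((pairs_n - p) * phi)
      nmax <- max(nsz)
      alpha <- min(max(alpha, -1 / max(nmax - 1, 1) + 1e-8), 1 - 1e-8)
    } else alpha <- 0
    # R^{-1} for compound symmetry: c1 * I - c2_i * J (c2 depends on n_i)
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / ((1 - alpha) * (1 + (nsz - 1) * alpha))
    Xt <- X * sqrt(v)                           # A^{1/2} X
    Ug <- rowsum(Xt, g)                         # per-cluster column sums
    seg <- drop(rowsum(e, g))
    # per-cluster score contributions S_g = Xt_g' R^{-1} e_g / phi
    f <- c1 * e - c2[g] * seg[g]
    Smat <- rowsum(Xt * f, g) / phi
    score <- colSums(Smat)
    B <- (c1 * crossprod(Xt) - t(Ug) %*% (Ug * c2)) / phi
    step <- tryCatch(solve(B, score), error = function(e) NULL)
    if (is.null(step)) { msg <- "singular working information"; break }
    beta_new <- beta + step
    if (any(!is.finite(beta_new)) || max(abs(beta_new)) > 50) {
      beta <- beta_new; msg <- "diverging coefficients (separation?)"; break
    }
    delta <- max(abs(step) / pmax(abs(beta_new), 1e-4))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && is.null(msg)) msg <- "iteration limit reached"

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  v <- pmax(mu * (1 - mu), 1e-12)
  e <- (y - mu) / sqrt(v)
  c1 <- 1 / (1 - alpha)
  c2 <- alpha / ((1 - alpha) * (1 + (nsz - 1) * alpha))
  Xt <- X * sqrt(v)
  Ug <- rowsum(Xt, g)
  seg <- drop(rowsum(e, g))
  f <- c1 * e - c2[g] * seg[g]
  Smat <- rowsum(Xt * f, g) / phi
  B <- (c1 * crossprod(Xt) - t(Ug) %*% (Ug * c2)) / phi
  Binv <- tryCatch(solve(B), error = function(e) matrix(NA_real_, p, p))
  M <- crossprod(Smat)
  V <- Binv %*% M %*% Binv
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    robust_vcov = V, se_robust = stats::setNames(se, colnames(X)),
    z = z, p_value = stats::setNames(pv, colnames(X)),
    or = exp(beta), or_lower = exp(beta - 1.96 * se),
    or_upper = exp(beta + 1.96 * se),
    alpha = alpha, phi = phi, n_clusters = K, n_obs = N,
    converged = converged, message = msg,
    linear_predictor = eta, fitted = mu), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Logistic GEE (exchangeable), ", x$n_obs, " obs in ", x$n_clusters,
      " clusters; alpha = ", signif(x$alpha, 3),
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, robust_se = x$se_robust,
                    OR = x$or, OR_low = x$or_lower, OR_high = x$or_upper,
                    p = x$p_value)
  print(signif(as.matrix(tab), 4))
  invisible(x)
}
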