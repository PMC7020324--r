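## Independent brute-force oracles shared by the unit and acceptance suites.

## Literal max-min Kennard-Stone with explicit loops, kept deliberately
## naive and separate from the package implementation.
ks_oracle <- function(x, fraction) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  n_train <- floor(fraction * n)
  pair <- c(NA, NA); best <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > best) { best <- d[i, j]; pair <- c(i, j) }
  }
  sel <- pair
  while (length(sel) < n_train) {
    cand <- setdiff(1:n, sel)
    mind <- sapply(cand, function(k) min(d[k, sel]))
    sel <- c(sel, cand[which.max(mind)])
  }
  as.integer(sel)
}

## Dual objective of a fitted binary C-SVC: sum(alpha) - 0.5 a'Qa with
## Q = (y y') * K, reconstructed from the libsvm coefficients.
svc_dual_objective_value <- function(model, x, g) {
  K <- exp(-g * as.matrix(dist(x))^2)
  alpha_y <- rep(0, nrow(x))
  alpha_y[model$fit$index] <- model$fit$coefs
  sum(abs(alpha_y)) - 0.5 * drop(t(alpha_y) %*% K %*% alpha_y)
}

## Dual objective of a fitted SVR: -0.5 b'Kb - eps * sum|b| + y'b with
## b = alpha - alpha*.
svr_dual_objective_value <- function(model, x, y, g, eps) {
  K <- exp(-g * as.matrix(dist(x))^2)
  beta <- rep(0, nrow(x))
  beta[model$fit$index] <- model$fit$coefs
  -0.5 * drop(t(beta) %*% K %*% beta) - eps * sum(abs(beta)) + sum(y * beta)
}
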