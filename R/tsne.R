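## Exact (non-Barnes-Hut) t-SNE for small sample sets, with per-point
## Gaussian bandwidths solved by bisection to match a target perplexity,
## plus 95% confidence ellipses for group display.

#' Conditional t-SNE affinities
#'
#' Solves, for every point, the Gaussian bandwidth whose conditional
#' distribution over the other points has Shannon entropy log2(perplexity),
#' by bisection on the precision to an entropy tolerance.
#'
#' @param x Numeric data matrix (samples x features).
#' @param perplexity Target perplexity, `< (n - 1) / 3`.
#' @param tol Entropy tolerance in bits (default 1e-5).
#' @return The `n x n` conditional probability matrix P(j | i) with zero
#'   diagonal; each row sums to 1.
#' @export
tsne_affinities <- function(x, perplexity, tol = 1e-5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5L) stop("t-SNE needs at least 5 samples", call. = FALSE)
  if (perplexity >= (n - 1) / 3) {
    stop("perplexity must be below (n - 1) / 3", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  target <- log2(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:200) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { hi <- beta; beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log2(p[p > 0]))
      if (abs(h - target) < tol) break
      if (h > target) {            # too flat: increase precision
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

.tsne_kl <- function(P_joint, Y) {
  n <- nrow(Y)
  d2 <- as.matrix(stats::dist(Y))^2
  qnum <- 1 / (1 + d2); diag(qnum) <- 0
  Q <- qnum / sum(qnum)
  mask <- P_joint > 0
  sum(P_joint[mask] * log(P_joint[mask] / pmax(Q[mask], 1e-12)))
}

#' Exact t-SNE embedding
#'
#' Symmetrised joint affinities from [tsne_affinities()], Student-t
#' low-dimensional kernel, gradient descent with momentum 0.5 switching to
#' 0.8 and early exaggeration (factor 12) for the first quarter of the
#' iterations (250 of the default 1,000). Deterministic given the seed.
#'
#' @param x Data matrix (samples x features).
#' @param perplexity Target perplexity (default 10, suited to n near 100).
#' @param iterations Gradient steps (default 1,000).
#' @param seed Integer seed for the random initialisation.
#' @param learning_rate Gradient step size (default 200).
#' @param exaggeration Early-exaggeration factor (default 12).
#' @return Object of class `tsne_embedding`: `coords` (n x 2), `final_kl`,
#'   `kl_after_exaggeration`, `perplexity`, `seed`.
#' @export
tsne <- function(x, perplexity = 10, iterations = 1000L, seed = 1L,
                 learning_rate = 200, exaggeration = 12) {
  x <- as.matrix(x)
  n <- nrow(x)
  Pc <- tsne_affinities(x, perplexity)
  P <- (Pc + t(Pc)) / (2 * n)               # symmetrised joint P
  P <- pmax(P, .Machine$double.eps)
  diag(P) <- 0
  P <- P / sum(P)

  exag_iter <- max(1L, min(250L, iterations %/% 4L))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  kl_after_exag <- NA_real_
  for (it in seq_len(iterations)) {
    Pe <- if (it <= exag_iter) P * exaggeration else P
    d2 <- as.matrix(stats::dist(Y))^2
    qnum <- 1 / (1 + d2); diag(qnum) <- 0
    Q <- pmax(qnum / sum(qnum), .Machine$double.eps)
    L <- (Pe - Q) * qnum
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it <= exag_iter) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), `-`)
    if (it == exag_iter) kl_after_exag <- .tsne_kl(P, Y)
  }
  structure(list(coords = Y, final_kl = .tsne_kl(P, Y),
                 kl_after_exaggeration = kl_after_exag,
                 perplexity = perplexity, seed = seed,
                 iterations = iterations),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat("t-SNE embedding: ", nrow(x$coords), " points, perplexity ",
      x$perplexity, ", final KL = ", format(x$final_kl, digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Confidence ellipse of a 2-D point cloud
#'
#' Ellipse of the sample mean and covariance scaled by
#' `sqrt(qchisq(level, 2))` (sqrt(5.991) at the 95% level), the usual
#' display convention for per-group confidence regions in an embedding.
#'
#' @param points `n x 2` matrix, `n >= 3`.
#' @param level Coverage level (default 0.95).
#' @return List of class `confidence_ellipse`: `center`, `axes` (semi-axis
#'   lengths, major first), `angle` (radians, major axis vs x), `level`.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 2L) {
    stop("need an n x 2 matrix with n >= 3", call. = FALSE)
  }
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values) || max(e$values) <= 0) {
    stop("singular covariance: points are (nearly) collinear",
         call. = FALSE)
  }
  r <- sqrt(stats::qchisq(level, df = 2))
  structure(list(center = colMeans(points),
                 axes = r * sqrt(e$values),
                 angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                 level = level),
            class = "confidence_ellipse")
}

#' Polygon outline of a confidence ellipse
#'
#' @param ellipse A [confidence_ellipse()].
#' @param n_points Number of outline points.
#' @return `n_points x 2` matrix tracing the ellipse.
#' @export
ellipse_outline <- function(ellipse, n_points = 100L) {
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(ellipse$axes[1L] * cos(th), ellipse$axes[2L] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2L, 2L)
  sweep(circ %*% t(rot), 2L, ellipse$center, `+`)
}

#' Plot a t-SNE embedding with per-group confidence ellipses
#'
#' @param x A `tsne_embedding`.
#' @param labels Optional group labels (one per point); groups with at
#'   least 3 points get a dashed 95% ellipse.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tsne_embedding <- function(x, labels = NULL, ...) {
  coords <- x$coords
  if (is.null(labels)) {
    graphics::plot(coords, xlab = "t-SNE 1", ylab = "t-SNE 2", pch = 19, ...)
    return(invisible(x))
  }
  labels <- as.factor(labels)
  cols <- seq_len(nlevels(labels))
  graphics::plot(coords, col = cols[as.integer(labels)], pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  for (g in seq_len(nlevels(labels))) {
    pts <- coords[as.integer(labels) == g, , drop = FALSE]
    if (nrow(pts) >= 3L) {
      ell <- try(confidence_ellipse(pts), silent = TRUE)
      if (!inherits(ell, "try-error")) {
        graphics::lines(ellipse_outline(ell), lty = 2, col = cols[g])
      }
    }
  }
  graphics::legend("topright", legend = levels(labels), col = cols,
                   pch = 19, bty = "n")
  invisible(x)
}
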