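## NIPALS PLS2 discriminant analysis: dummy-coded Y, mean-centred (optionally
## unit-variance) X, per-component deflation, venetian-blind cross-validation
## for Q2(cum)/RMSECV, VIP scores, and Table-style confusion reporting.

#' One-hot class encoding
#'
#' @param labels Character or factor class labels, at least two classes.
#' @param levels Class order for the dummy columns; defaults to the factor
#'   levels or the sorted unique labels.
#' @return An `n x k` 0/1 matrix with one column per class; each row sums
#'   to 1.
#' @export
encode_classes <- function(labels, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (is.factor(labels)) base::levels(labels)
              else sort(unique(as.character(labels)))
  }
  labels <- as.character(labels)
  if (length(levels) < 2L) {
    stop("need at least two classes to encode", call. = FALSE)
  }
  if (!all(labels %in% levels)) {
    stop("labels outside the provided levels", call. = FALSE)
  }
  y <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  y[cbind(seq_along(labels), match(labels, levels))] <- 1
  y
}

## Core NIPALS PLS2 on centred/scaled matrices. Returns weights W, loadings
## P, Y-loadings C, scores T, and per-component explained Y variance.
.nipals_pls2 <- function(Xc, Yc, A, tol = 1e-12, max_iter = 1000L) {
  n <- nrow(Xc); p <- ncol(Xc); k <- ncol(Yc)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  C <- matrix(0, k, A); Tt <- matrix(0, n, A)
  ssy <- numeric(A)
  E <- Xc; F_ <- Yc
  a <- 0L
  while (a < A) {
    u <- F_[, which.max(colSums(F_^2))]
    if (sum(u^2) < 1e-14 || sum(E^2) < 1e-14) break
    t_old <- rep(Inf, n)
    t <- NULL; w <- NULL; cvec <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)[, 1L]
      w_norm <- sqrt(sum(w^2))
      if (w_norm < 1e-14) break
      w <- w / w_norm
      t <- E %*% w
      tt <- sum(t^2)
      if (tt < 1e-14) break
      cvec <- crossprod(F_, t)[, 1L] / tt
      if (sum(cvec^2) < 1e-14) break
      u <- F_ %*% cvec / sum(cvec^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    if (is.null(t) || sum(t^2) < 1e-14) break
    a <- a + 1L
    tt <- sum(t^2)
    pvec <- crossprod(E, t)[, 1L] / tt
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; Tt[, a] <- t
    ssy[a] <- tt * sum(cvec^2)       # squared norm of rank-1 Y piece t c'
    E <- E - t %*% t(pvec)
    F_ <- F_ - t %*% t(cvec)
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       C = C[, seq_len(a), drop = FALSE], T = Tt[, seq_len(a), drop = FALSE],
       ssy = ssy[seq_len(a)], ncomp = a)
}

#' Fit a PLS2 discriminant-analysis model
#'
#' Dummy-codes the class labels, centres (optionally unit-variance scales)
#' X, and extracts `ncomp` NIPALS components with per-component deflation.
#' `R2Y(cum)` after each component is `1 - ||Y - Yhat_A||^2 / ||Y - Ybar||^2`.
#'
#' @param x Numeric matrix of predictors (samples x features).
#' @param labels Class labels (length `nrow(x)`), or an already dummy-coded
#'   0/1 matrix.
#' @param ncomp Number of latent variables A (capped at the effective rank,
#'   with a warning).
#' @param scale `"center"` (default) or `"uv"` for unit-variance scaling.
#' @param class_levels Optional class order.
#' @return An object of class `plsda` with weights `W`, loadings `P`,
#'   Y-loadings `C`, scores `T`, projection matrix `R` (so scores of new
#'   data are `Xc %*% R`), coefficients, and the `r2y_cum` diagnostic
#'   vector.
#' @export
plsda <- function(x, labels, ncomp = 2L, scale = c("center", "uv"),
                  class_levels = NULL) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (is.matrix(labels)) {
    y <- labels
    class_levels <- colnames(y)
  } else {
    y <- encode_classes(labels, class_levels)
    class_levels <- colnames(y)
  }
  n <- nrow(x); p <- ncol(x)
  a_req <- as.integer(ncomp)
  a_cap <- min(n - 1L, p)
  if (a_req > a_cap) {
    warning("ncomp reduced from ", a_req, " to rank cap ", a_cap,
            call. = FALSE)
    a_req <- a_cap
  }
  x_mean <- colMeans(x)
  x_scale <- if (scale == "uv") {
    s <- apply(x, 2L, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    s
  } else rep(1, p)
  y_mean <- colMeans(y)
  Xc <- sweep(sweep(x, 2L, x_mean, `-`), 2L, x_scale, `/`)
  Yc <- sweep(y, 2L, y_mean, `-`)
  fit <- .nipals_pls2(Xc, Yc, a_req)
  if (fit$ncomp < a_req) {
    warning("NIPALS stopped after ", fit$ncomp,
            " components (X residual exhausted)", call. = FALSE)
  }
  ## R = W (P'W)^-1 : scores of any centred data are Xc %*% R
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  ssy_tot <- sum(Yc^2)
  yhat_c <- fit$T %*% t(fit$C)
  r2y_cum <- cumsum(fit$ssy) / ssy_tot
  resid <- Yc - yhat_c
  structure(list(W = fit$W, P = fit$P, C = fit$C, T = fit$T, R = R,
                 ncomp = fit$ncomp, x_mean = x_mean, x_scale = x_scale,
                 y_mean = y_mean, class_levels = class_levels,
                 r2y_cum = r2y_cum, ssy_comp = fit$ssy,
                 residuals = resid, scale = scale,
                 n = n, p = p),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model: ", x$ncomp, " latent variable(s), ", x$p,
      " predictors, ", length(x$class_levels), " classes\n", sep = "")
  cat("  R2Y(cum): ", paste(sprintf("%.3f", x$r2y_cum), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) {
  b <- object$R %*% t(object$C)
  sweep(b, 1L, object$x_scale, `/`)
}

#' Predict classes or dummy responses from a PLS-DA model
#'
#' @param object A fitted [plsda()] model.
#' @param newdata Numeric matrix with the training number of columns.
#' @param type `"class"` for labels (argmax of predicted dummies, ties to
#'   the lowest class index) or `"response"` for the predicted dummy matrix.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Ignored.
#' @return Character vector of labels or an `n x k` numeric matrix.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response"),
                          ncomp = object$ncomp, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$p, call. = FALSE)
  }
  Xc <- sweep(sweep(newdata, 2L, object$x_mean, `-`), 2L,
              object$x_scale, `/`)
  a <- min(ncomp, object$ncomp)
  scores <- Xc %*% object$R[, seq_len(a), drop = FALSE]
  yhat <- scores %*% t(object$C[, seq_len(a), drop = FALSE])
  yhat <- sweep(yhat, 2L, object$y_mean, `+`)
  colnames(yhat) <- object$class_levels
  if (type == "response") return(yhat)
  object$class_levels[apply(yhat, 1L, which.max)]
}

#' Project data onto the PLS score space
#'
#' @param object A fitted [plsda()] model.
#' @param newdata Numeric matrix (training columns).
#' @return Matrix of X-scores (`n x ncomp`).
#' @export
plsda_scores <- function(object, newdata) {
  stopifnot(inherits(object, "plsda"))
  newdata <- as.matrix(newdata)
  Xc <- sweep(sweep(newdata, 2L, object$x_mean, `-`), 2L,
              object$x_scale, `/`)
  Xc %*% object$R
}

#' Venetian-blind cross-validation of a PLS-DA model
#'
#' Assigns folds by row order (venetian blinds), fits the model on each
#' held-in part and accumulates out-of-fold squared Y-residuals per
#' component count. `Q2cum(A) = 1 - PRESS(A)/SS` with
#' `SS = ||Y - Ybar||^2`; `RMSECV(A)` is `sqrt(PRESS_col(A)/n)` averaged
#' over the dummy-Y columns. If a fold's held-in part would miss a class,
#' the fold assignment is rotated deterministically until every class is
#' represented (with a warning if impossible).
#'
#' @param x Predictor matrix.
#' @param labels Class labels or dummy matrix.
#' @param ncomp_max Largest component count to evaluate.
#' @param folds Number of folds (default 7).
#' @param scale As in [plsda()].
#' @param class_levels Optional class order.
#' @return List with `q2_cum` and `rmsecv` (length `ncomp_max` each) and
#'   `press`.
#' @export
plsda_cv <- function(x, labels, ncomp_max, folds = 7L,
                     scale = c("center", "uv"), class_levels = NULL) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  y <- if (is.matrix(labels)) labels else encode_classes(labels, class_levels)
  n <- nrow(x)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  folds <- min(folds, n)
  a_max <- min(as.integer(ncomp_max), n - ceiling(n / folds) - 1L, ncol(x))
  labs_chr <- colnames(y)[apply(y, 1L, which.max)]
  fold_id <- NULL
  for (off in 0:(folds - 1L)) {
    cand <- ((seq_len(n) - 1L + off) %% folds) + 1L
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(labs_chr[cand != f])) == length(unique(labs_chr))
    }, logical(1)))
    if (ok) { fold_id <- cand; break }
  }
  if (is.null(fold_id)) {
    warning("some CV folds lack a class; proceeding with plain venetian ",
            "blinds", call. = FALSE)
    fold_id <- ((seq_len(n) - 1L) %% folds) + 1L
  }
  press <- matrix(0, a_max, ncol(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    xm <- colMeans(x[tr, , drop = FALSE])
    xs <- if (scale == "uv") {
      s <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
      s[s == 0 | !is.finite(s)] <- 1
      s
    } else rep(1, ncol(x))
    ym <- colMeans(y[tr, , drop = FALSE])
    Xc <- sweep(sweep(x[tr, , drop = FALSE], 2L, xm, `-`), 2L, xs, `/`)
    Yc <- sweep(y[tr, , drop = FALSE], 2L, ym, `-`)
    fit <- .nipals_pls2(Xc, Yc, a_max)
    Xte <- sweep(sweep(x[te, , drop = FALSE], 2L, xm, `-`), 2L, xs, `/`)
    if (fit$ncomp > 0L) {
      R <- fit$W %*% solve(crossprod(fit$P, fit$W))
      scores <- Xte %*% R
    }
    for (a in seq_len(a_max)) {
      a_eff <- min(a, fit$ncomp)
      yhat <- if (a_eff > 0L) {
        sweep(scores[, seq_len(a_eff), drop = FALSE] %*%
                t(fit$C[, seq_len(a_eff), drop = FALSE]), 2L, ym, `+`)
      } else {
        matrix(ym, sum(te), ncol(y), byrow = TRUE)
      }
      press[a, ] <- press[a, ] + colSums((y[te, , drop = FALSE] - yhat)^2)
    }
  }
  ss <- sum(sweep(y, 2L, colMeans(y), `-`)^2)
  q2_cum <- 1 - rowSums(press) / ss
  rmsecv <- rowMeans(sqrt(press / n))
  list(q2_cum = q2_cum, rmsecv = rmsecv, press = press, folds = folds)
}

#' VIP scores
#'
#' Variable importance in the projection:
#' `VIP_j = sqrt( p * sum_a[ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a )`
#' where `SSY_a` is the Y-variance explained by component a. The
#' mean-square of the VIPs equals 1 by construction, so VIP > 1 flags
#' above-average importance.
#'
#' @param model A fitted [plsda()] model.
#' @return Numeric vector of length p.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  W <- model$W
  ssy <- model$ssy_comp
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), `/`)
  p <- nrow(W)
  sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
}

#' In-sample root-mean-square error of estimation
#'
#' `sqrt(sum(residual^2) / n)` per dummy-Y column, averaged over columns
#' (the "(avg)" convention of multi-class reporting).
#'
#' @param model A fitted [plsda()] model.
#' @return Scalar RMSEE.
#' @export
rmsee <- function(model) {
  stopifnot(inherits(model, "plsda"))
  mean(sqrt(colSums(model$residuals^2) / model$n))
}

#' Confusion matrix with per-class and total accuracy
#'
#' Rows are genuine classes, columns predicted classes; per-class accuracy
#' is the diagonal fraction of each row and total accuracy is
#' `100 * trace / n`.
#'
#' @param truth,predicted Class label vectors of equal length.
#' @param levels Class order (default: union of both, sorted).
#' @return An object of class `confusion_matrix` with `counts`,
#'   `per_class_accuracy` (%), and `total_accuracy` (%).
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (is.null(levels)) levels <- sort(unique(c(truth, predicted)))
  counts <- table(factor(truth, levels), factor(predicted, levels))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  per_class <- 100 * diag(counts) / pmax(1L, rowSums(counts))
  structure(list(counts = counts,
                 per_class_accuracy = per_class,
                 total_accuracy = 100 * sum(diag(counts)) / length(truth),
                 n = length(truth)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- cbind(x$counts, `Accuracy (%)` = round(x$per_class_accuracy, 2))
  print(m)
  cat("Total: ", x$n, " samples, accuracy ",
      sprintf("%.2f", x$total_accuracy), "%\n", sep = "")
  invisible(x)
}
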