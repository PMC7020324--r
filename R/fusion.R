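## Multi-block fusion: low-level splicing of cap and stipe matrices, and
## mid-level splicing of per-block features selected by eigenvalue > 1
## (PCA), maximum Q2(cum) (PLS latent variables) or VIP > 1.

.feature_matrix <- function(values, feature_names, fusion_tag) {
  values <- as.matrix(values)
  colnames(values) <- feature_names
  attr(values, "fusion_tag") <- fusion_tag
  values
}

.block_matrix <- function(block, prefix) {
  .feature_matrix(block$absorbance,
                  paste0(prefix, ":wn",
                         format(block$wavenumbers, trim = TRUE,
                                scientific = FALSE)),
                  paste0("single_", prefix))
}

.check_paired <- function(caps, stipes) {
  if (!identical(caps$meta$fruiting_body_id, stipes$meta$fruiting_body_id)) {
    stop("blocks are not paired; run pair_blocks() first", call. = FALSE)
  }
}

#' Low-level data fusion
#'
#' Directly splices the paired cap and stipe absorbance matrices row-wise:
#' the fused matrix has `p_cap + p_stipe` columns with `cap:`/`stipe:`
#' provenance prefixes on the feature names.
#'
#' @param caps,stipes Paired [spectra_block()]s (same fruiting-body order).
#' @return Numeric feature matrix with `attr(, "fusion_tag") == "low"`.
#' @export
fuse_low_level <- function(caps, stipes) {
  .check_paired(caps, stipes)
  .feature_matrix(cbind(caps$absorbance, stipes$absorbance),
                  c(colnames(.block_matrix(caps, "cap")),
                    colnames(.block_matrix(stipes, "stipe"))),
                  "low")
}

## ---- feature selectors (fit on train, project anywhere) -------------------

#' Principal-component selector with the eigenvalue > 1 rule
#'
#' Standardises the training columns (correlation-matrix convention -- the
#' Kaiser eigenvalue > 1 rule is only meaningful on standardised data),
#' performs PCA and retains every component with eigenvalue > 1.
#' Zero-variance columns are dropped with a warning before the PCA.
#'
#' @param x Training matrix (samples x features).
#' @return A `pc_selector` with the centering/scaling vectors, retained
#'   rotation, and eigenvalues.
#' @export
fit_pc_selector <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  s <- apply(x, 2L, stats::sd)
  keep_cols <- which(is.finite(s) & s > 0)
  if (length(keep_cols) < ncol(x)) {
    warning(ncol(x) - length(keep_cols),
            " zero-variance column(s) dropped before PCA", call. = FALSE)
  }
  xs <- x[, keep_cols, drop = FALSE]
  pc <- stats::prcomp(xs, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  n_keep <- max(1L, sum(ev > 1))
  structure(list(cols = keep_cols,
                 center = pc$center, scale = pc$scale,
                 rotation = pc$rotation[, seq_len(n_keep), drop = FALSE],
                 eigenvalues = ev, n_components = n_keep),
            class = "pc_selector")
}

#' @export
predict.pc_selector <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$cols, drop = FALSE]
  xs <- sweep(sweep(newdata, 2L, object$center, `-`), 2L, object$scale, `/`)
  scores <- xs %*% object$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Latent-variable selector by maximum Q2(cum)
#'
#' Fits PLS-DA cross-validation for A = 1..`a_max` components and retains
#' the X-scores of the model with the largest `Q2(cum)` (first maximum on
#' ties). The fitted weights project test rows into the same score space.
#'
#' @param x Training matrix.
#' @param labels Training class labels.
#' @param a_max Largest component count tried (capped at the rank).
#' @param folds CV folds (default 7, venetian blinds).
#' @return An `lv_selector` holding the fitted [plsda()] model and the
#'   chosen component count.
#' @export
fit_lv_selector <- function(x, labels, a_max = 15L, folds = 7L) {
  cv <- plsda_cv(x, labels, ncomp_max = a_max, folds = folds)
  a_star <- which.max(cv$q2_cum)          # first maximum on ties
  model <- plsda(x, labels, ncomp = a_star)
  structure(list(model = model, n_components = model$ncomp,
                 q2_cum = cv$q2_cum),
            class = "lv_selector")
}

#' @export
predict.lv_selector <- function(object, newdata, ...) {
  scores <- plsda_scores(object$model, newdata)
  colnames(scores) <- paste0("LV", seq_len(ncol(scores)))
  scores
}

#' VIP > 1 variable selector
#'
#' Fits PLS-DA at its Q2-optimal component count, computes VIP scores, and
#' retains the original columns with VIP > 1 (the values themselves are
#' untouched -- this selector is a column mask).
#'
#' @inheritParams fit_lv_selector
#' @return A `vip_selector` with the retained column mask and VIP vector.
#' @export
fit_vip_selector <- function(x, labels, a_max = 15L, folds = 7L) {
  cv <- plsda_cv(x, labels, ncomp_max = a_max, folds = folds)
  a_star <- which.max(cv$q2_cum)
  model <- plsda(x, labels, ncomp = a_star)
  v <- vip(model)
  keep <- which(v > 1)
  if (!length(keep)) {
    stop("no variable reached VIP > 1; review the selection threshold",
         call. = FALSE)
  }
  structure(list(keep = keep, vip = v, n_components = model$ncomp),
            class = "vip_selector")
}

#' @export
predict.vip_selector <- function(object, newdata, ...) {
  as.matrix(newdata)[, object$keep, drop = FALSE]
}

#' Mid-level data fusion
#'
#' Applies the chosen feature selector (`"e"` eigenvalue > 1 PCA, `"q"`
#' maximum-Q2 latent variables, `"v"` VIP > 1 variables) to the cap and
#' stipe blocks independently -- fitted on the training rows only -- and
#' splices the selected features.
#'
#' @param caps,stipes Paired [spectra_block()]s.
#' @param labels Per-row class labels.
#' @param rule One of `"e"`, `"q"`, `"v"`.
#' @param train Integer indices of the training rows used to fit the
#'   selectors (default: all rows).
#' @param a_max,folds Passed to the PLS-based selectors.
#' @return Feature matrix for all rows with
#'   `attr(, "fusion_tag") == "mid_<rule>"` and the fitted per-block
#'   selectors in `attr(, "selectors")`.
#' @export
fuse_mid_level <- function(caps, stipes, labels, rule = c("e", "q", "v"),
                           train = NULL, a_max = 15L, folds = 7L) {
  rule <- match.arg(rule)
  .check_paired(caps, stipes)
  if (is.null(train)) train <- seq_len(nrow(caps$absorbance))
  fitted <- list()
  parts <- list()
  for (prefix in c("cap", "stipe")) {
    block <- if (prefix == "cap") caps else stipes
    xm <- .block_matrix(block, prefix)
    xtr <- xm[train, , drop = FALSE]
    sel <- switch(rule,
                  e = fit_pc_selector(xtr),
                  q = fit_lv_selector(xtr, labels[train], a_max, folds),
                  v = fit_vip_selector(xtr, labels[train], a_max, folds))
    feats <- predict(sel, xm)
    colnames(feats) <- if (rule == "v") {
      paste0(prefix, ":VIP:", sub("^[a-z]+:", "", colnames(feats)))
    } else {
      paste0(prefix, ":", colnames(feats))
    }
    fitted[[prefix]] <- sel
    parts[[prefix]] <- feats
  }
  out <- .feature_matrix(cbind(parts$cap, parts$stipe),
                         c(colnames(parts$cap), colnames(parts$stipe)),
                         paste0("mid_", rule))
  attr(out, "selectors") <- fitted
  out
}
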