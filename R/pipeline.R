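## End-to-end orchestration: the discrimination study (six fusion
## strategies x PLS-DA, plus grid- and PSO-tuned SVM on the single blocks
## and the low-level fusion) and the polyphenol prediction study
## (treatment sweep x GS-SVR per morphological part).

.minmax_block <- function(block, train) {
  ranges <- list(min = apply(block$absorbance[train, , drop = FALSE], 2L, min),
                 max = apply(block$absorbance[train, , drop = FALSE], 2L, max))
  spectra_block(minmax_1_2(block$absorbance, ranges),
                block$wavenumbers, block$meta)
}

.strategy_features <- function(caps, stipes, labels, strategy, fraction,
                               a_max, folds, normalize_scope) {
  base <- switch(strategy,
                 cap = .block_matrix(caps, "cap"),
                 stipe = .block_matrix(stipes, "stipe"),
                 fuse_low_level(caps, stipes))
  if (normalize_scope == "all") {
    base_n <- minmax_1_2(base)
    split <- kennard_stone(base_n, fraction)
  } else {
    split <- kennard_stone(base, fraction)
  }
  train <- split$train
  if (strategy %in% c("cap", "stipe", "low")) {
    x <- if (normalize_scope == "all") {
      minmax_1_2(base)
    } else {
      ranges <- list(min = apply(base[train, , drop = FALSE], 2L, min),
                     max = apply(base[train, , drop = FALSE], 2L, max))
      minmax_1_2(base, ranges)
    }
    attr(x, "fusion_tag") <- attr(base, "fusion_tag")
  } else {
    rule <- sub("^mid_", "", strategy)
    tr_for_norm <- if (normalize_scope == "all") {
      seq_len(nrow(caps$absorbance))
    } else train
    capn <- .minmax_block(caps, tr_for_norm)
    stipen <- .minmax_block(stipes, tr_for_norm)
    x <- fuse_mid_level(capn, stipen, labels, rule = rule, train = train,
                        a_max = a_max, folds = folds)
  }
  list(x = x, split = split)
}

#' Run the species-discrimination study
#'
#' For each fusion strategy, normalises to 1-2 (training statistics only,
#' unless `normalize_scope = "all"`), computes the Kennard-Stone split on
#' the matrix handed to the model, fits PLS-DA with the latent-variable
#' count chosen by maximum Q2(cum), and reports the test-set confusion.
#' For the single-block and low-level strategies it additionally tunes an
#' RBF-SVM by grid search and by PSO and reports training CV accuracy and
#' test accuracy.
#'
#' @param dataset A `synthetic_dataset` (or any list with paired `caps`,
#'   `stipes` [spectra_block()]s).
#' @param strategies Fusion strategies for PLS-DA.
#' @param svm_strategies Strategies for the SVM models.
#' @param fraction Kennard-Stone training fraction (default 2/3).
#' @param a_max Largest PLS component count tried.
#' @param folds CV folds for every cross-validated quantity.
#' @param c_grid,g_grid SVM grid-search candidates.
#' @param pso_swarm,pso_iterations PSO size.
#' @param normalize_scope `"train"` (default; 1-2 normalisation statistics
#'   from the training rows only) or `"all"` (statistics from all rows
#'   before splitting, as in replication of workflows that normalise before
#'   partitioning).
#' @param seed Seed for the PSO tuner.
#' @return A `discrimination_report`: data frames `plsda` and `svm`, plus
#'   per-strategy splits and confusion matrices.
#' @export
run_discrimination <- function(dataset,
                               strategies = c("cap", "stipe", "low",
                                              "mid_e", "mid_q", "mid_v"),
                               svm_strategies = c("cap", "stipe", "low"),
                               fraction = 2 / 3, a_max = 12L, folds = 7L,
                               c_grid = 2^seq(-5, 21, by = 2),
                               g_grid = 2^seq(-21, 7, by = 2),
                               pso_swarm = 10L, pso_iterations = 20L,
                               normalize_scope = c("train", "all"),
                               seed = 1L) {
  normalize_scope <- match.arg(normalize_scope)
  paired <- pair_blocks(dataset$caps, dataset$stipes)
  caps <- paired$caps; stipes <- paired$stipes
  labels <- caps$meta$species
  lev <- intersect(mirfuse_species(), unique(labels))

  plsda_rows <- list(); svm_rows <- list()
  splits <- list(); confusions <- list()
  for (strategy in unique(c(strategies, svm_strategies))) {
    sf <- .strategy_features(caps, stipes, labels, strategy, fraction,
                             a_max, folds, normalize_scope)
    x <- sf$x; split <- sf$split
    splits[[strategy]] <- split
    tr <- split$train; te <- split$test

    if (strategy %in% strategies) {
      cv <- plsda_cv(x[tr, , drop = FALSE], labels[tr], ncomp_max = a_max,
                     folds = folds, class_levels = lev)
      a_star <- which.max(cv$q2_cum)
      model <- plsda(x[tr, , drop = FALSE], labels[tr], ncomp = a_star,
                     class_levels = lev)
      pred <- predict(model, x[te, , drop = FALSE])
      cm <- confusion_matrix(labels[te], pred, levels = lev)
      confusions[[strategy]] <- cm
      plsda_rows[[strategy]] <- data.frame(
        strategy = strategy, n_lv = model$ncomp,
        r2y_cum = model$r2y_cum[model$ncomp],
        q2_cum = cv$q2_cum[a_star],
        rmsee = rmsee(model), rmsecv = cv$rmsecv[a_star],
        test_accuracy = cm$total_accuracy,
        stringsAsFactors = FALSE)
    }

    if (strategy %in% svm_strategies) {
      for (tuner in c("grid", "pso")) {
        tune <- if (tuner == "grid") {
          grid_search(x[tr, , drop = FALSE], labels[tr], task = "classify",
                      c_grid = c_grid, g_grid = g_grid, folds = folds)
        } else {
          pso_svm(x[tr, , drop = FALSE], labels[tr], task = "classify",
                  swarm = pso_swarm, iterations = pso_iterations,
                  seed = seed, folds = folds)
        }
        fit <- fit_svc(x[tr, , drop = FALSE], labels[tr],
                       tune$best_c, tune$best_g)
        pred <- predict(fit, x[te, , drop = FALSE])
        svm_rows[[paste(strategy, tuner)]] <- data.frame(
          strategy = strategy, tuner = tuner,
          best_c = tune$best_c, best_g = tune$best_g,
          train_cv_accuracy = tune$fitness,
          test_accuracy = 100 * mean(pred == labels[te]),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(plsda = do.call(rbind, plsda_rows[strategies[
                   strategies %in% names(plsda_rows)]]),
                 svm = do.call(rbind, svm_rows),
                 splits = splits, confusions = confusions,
                 normalize_scope = normalize_scope, seed = seed),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("== PLS-DA discrimination ==\n")
  df <- x$plsda
  df[sapply(df, is.numeric)] <- lapply(df[sapply(df, is.numeric)],
                                       round, digits = 3)
  print(df, row.names = FALSE)
  if (!is.null(x$svm)) {
    cat("\n== GS-SVM / PSO-SVM discrimination ==\n")
    s <- x$svm
    s$best_c <- signif(s$best_c, 4); s$best_g <- signif(s$best_g, 4)
    s$train_cv_accuracy <- round(s$train_cv_accuracy, 2)
    s$test_accuracy <- round(s$test_accuracy, 2)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

.cv_predictions_svr <- function(x, y, c, g, folds, epsilon) {
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- .venetian_folds(n, folds)
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    m <- fit_svr(x[tr, , drop = FALSE], y[tr], c, g, epsilon)
    pred[!tr] <- predict(m, x[!tr, , drop = FALSE])
  }
  pred
}

#' Run the total-polyphenol prediction study
#'
#' For each morphological part: one Kennard-Stone split on the raw spectra
#' (shared across treatment rows so every model is judged on the same test
#' samples); then, per treatment chain, the chain is fitted on the training
#' spectra, both sets are transformed and 1-2 normalised (training
#' statistics), a grid-searched RBF support-vector regression is tuned by
#' cross-validated RMSE, and the external test set yields R2, RMSEP, RPD
#' and its interpretation band.
#'
#' @param dataset A `synthetic_dataset` with a `contents` data frame.
#' @param treatments Character vector of treatment chains
#'   (see [treatment_chain()]).
#' @param parts Morphological parts to model.
#' @param fraction,folds,c_grid,g_grid,epsilon Tuning settings (see
#'   [grid_search()]).
#' @return A `prediction_report` data frame with one row per part x
#'   treatment.
#' @export
run_prediction <- function(dataset,
                           treatments = c("No", "SNV", "MSC", "FD", "SD",
                                          "SG(7)", "FD+SG(9)",
                                          "SNV+FD+SG(9)"),
                           parts = c("cap", "stipe"),
                           fraction = 2 / 3, folds = 7L,
                           c_grid = 2^seq(-5, 21, by = 2),
                           g_grid = 2^seq(-21, 7, by = 2),
                           epsilon = 0.1) {
  rows <- list()
  for (part in parts) {
    block <- if (part == "cap") dataset$caps else dataset$stipes
    cont <- dataset$contents
    y <- cont$content[match(block$meta$sample_id, cont$sample_id)]
    if (anyNA(y)) stop("contents missing for some samples", call. = FALSE)
    split <- kennard_stone(block$absorbance, fraction)
    tr <- split$train; te <- split$test
    for (treatment in treatments) {
      chain <- treatment_chain(treatment)
      fc <- fit_chain(chain, block[tr])
      x_tr <- transform_chain(fc, block[tr])$absorbance
      x_te <- transform_chain(fc, block[te])$absorbance
      ranges <- list(min = apply(x_tr, 2L, min), max = apply(x_tr, 2L, max))
      x_tr <- minmax_1_2(x_tr, ranges)
      x_te <- minmax_1_2(x_te, ranges)
      gs <- grid_search(x_tr, y[tr], task = "regress", c_grid = c_grid,
                        g_grid = g_grid, folds = folds, epsilon = epsilon)
      cv_pred <- .cv_predictions_svr(x_tr, y[tr], gs$best_c, gs$best_g,
                                     folds, epsilon)
      fit <- fit_svr(x_tr, y[tr], gs$best_c, gs$best_g, epsilon)
      te_pred <- predict(fit, x_te)
      rep_ <- regression_report(y[tr], cv_pred, y[te], te_pred)
      rows[[paste(part, treatment)]] <- data.frame(
        part = part, treatment = format(chain),
        best_c = gs$best_c, best_g = gs$best_g,
        r2_cv = rep_$r2_cv, rmsecv = rep_$rmsecv,
        r2_pred = rep_$r2_pred, rmsep = rep_$rmsep,
        rpd = rep_$rpd, rpd_band = rep_$rpd_band,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prediction_report", "data.frame")
  out
}

#' @export
print.prediction_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$best_c <- signif(df$best_c, 4); df$best_g <- signif(df$best_g, 4)
  for (col in c("r2_cv", "rmsecv", "r2_pred", "rmsep", "rpd")) {
    df[[col]] <- round(df[[col]], 2)
  }
  print(df, row.names = FALSE)
  invisible(x)
}
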