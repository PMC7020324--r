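## RBF-kernel support-vector classification and epsilon-regression with
## deterministic cross-validated fitness, exhaustive (c, g) grid search and
## canonical particle swarm optimisation in log2(c), log2(g) space.

#' Fit an RBF support-vector classifier
#'
#' One-vs-one C-SVC with kernel `K(x, z) = exp(-g * ||x - z||^2)`. Features
#' are used as given (no internal rescaling), so any normalisation is the
#' caller's explicit pipeline step.
#'
#' @param x Numeric matrix (samples x features).
#' @param labels Class labels (>= 2 classes).
#' @param c Penalty parameter, > 0.
#' @param g RBF kernel parameter, > 0.
#' @return An object of class `svm_model` (kind `"classifier"`).
#' @export
fit_svc <- function(x, labels, c, g) {
  if (!is.numeric(c) || c <= 0 || !is.numeric(g) || g <= 0) {
    stop("hyperparameters c and g must be positive", call. = FALSE)
  }
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need at least two classes", call. = FALSE)
  fit <- e1071::svm(as.matrix(x), factor(labels, levels = lev),
                    type = "C-classification", kernel = "radial",
                    cost = c, gamma = g, scale = FALSE)
  structure(list(kind = "classifier", c = c, g = g, fit = fit,
                 class_levels = lev),
            class = "svm_model")
}

#' Fit an RBF epsilon-regression SVM
#'
#' @inheritParams fit_svc
#' @param y Numeric response.
#' @param epsilon Width of the insensitive tube (default 0.1).
#' @return An object of class `svm_model` (kind `"regressor"`).
#' @export
fit_svr <- function(x, y, c, g, epsilon = 0.1) {
  if (!is.numeric(c) || c <= 0 || !is.numeric(g) || g <= 0) {
    stop("hyperparameters c and g must be positive", call. = FALSE)
  }
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  ## fitted = FALSE: a response constant within the tube yields an empty
  ## model (no support vectors) whose in-fit prediction would fail
  fit <- e1071::svm(as.matrix(x), as.numeric(y), type = "eps-regression",
                    kernel = "radial", cost = c, gamma = g,
                    epsilon = epsilon, scale = FALSE, fitted = FALSE)
  structure(list(kind = "regressor", c = c, g = g, epsilon = epsilon,
                 fit = fit, y_center = mean(as.numeric(y))),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "regressor" && object$fit$tot.nSV == 0L) {
    ## bias-only solution: response lies inside the insensitive tube
    return(rep(object$y_center, nrow(newdata)))
  }
  out <- predict(object$fit, newdata)
  if (object$kind == "classifier") as.character(out) else as.numeric(out)
}

#' @export
print.svm_model <- function(x, ...) {
  cat("RBF-SVM ", x$kind, ": c = ", format(x$c), ", g = ", format(x$g),
      if (x$kind == "regressor") paste0(", epsilon = ", format(x$epsilon)),
      ", ", x$fit$tot.nSV, " support vectors\n", sep = "")
  invisible(x)
}

.venetian_folds <- function(n, folds) ((seq_len(n) - 1L) %% folds) + 1L

#' Cross-validated tuning fitness
#'
#' Deterministic venetian-blind k-fold fitness used by both tuners:
#' classification fitness is the cross-validated accuracy in percent,
#' regression fitness is minus the RMSECV. No random number generator is
#' involved, so the same inputs always give the same fitness.
#'
#' @param x Feature matrix.
#' @param y Labels (classification) or numeric response (regression).
#' @param c,g RBF-SVM hyperparameters.
#' @param folds Number of folds (default 7).
#' @param task `"classify"` or `"regress"`.
#' @param epsilon SVR tube width (regression only).
#' @return Scalar fitness (% accuracy, or -RMSECV).
#' @export
cv_fitness <- function(x, y, c, g, folds = 7L,
                       task = c("classify", "regress"), epsilon = 0.1) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  folds <- min(folds, n)
  fold_id <- .venetian_folds(n, folds)
  pred <- if (task == "classify") character(n) else numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (task == "classify") {
      if (length(unique(y[tr])) < 2L) {
        pred[!tr] <- names(which.max(table(y[tr])))
        next
      }
      m <- fit_svc(x[tr, , drop = FALSE], y[tr], c, g)
    } else {
      m <- fit_svr(x[tr, , drop = FALSE], y[tr], c, g, epsilon)
    }
    pred[!tr] <- predict(m, x[!tr, , drop = FALSE])
  }
  if (task == "classify") {
    100 * mean(pred == as.character(y))
  } else {
    -sqrt(mean((pred - as.numeric(y))^2))
  }
}

#' Exhaustive (c, g) grid search
#'
#' Evaluates [cv_fitness()] on every pair of the two grids and returns the
#' maximiser; ties are broken towards smaller c, then smaller g (preferring
#' the more regularised model). The default grids cover log2(c) in [-5, 21]
#' and log2(g) in [-21, 7] at unit steps.
#'
#' @inheritParams cv_fitness
#' @param c_grid,g_grid Candidate values of c and g.
#' @return A `tuning_result`: `best_c`, `best_g`, `fitness` (at the
#'   optimum) and the full `trace` data frame of evaluated triples.
#' @export
grid_search <- function(x, y, task = c("classify", "regress"),
                        c_grid = 2^(-5:21), g_grid = 2^(-21:7),
                        folds = 7L, epsilon = 0.1) {
  task <- match.arg(task)
  if (!length(c_grid) || !length(g_grid)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  c_grid <- sort(c_grid); g_grid <- sort(g_grid)
  trace <- expand.grid(g = g_grid, c = c_grid)[, c("c", "g")]
  trace$fitness <- mapply(function(cc, gg) {
    cv_fitness(x, y, cc, gg, folds = folds, task = task, epsilon = epsilon)
  }, trace$c, trace$g)
  best <- which.max(trace$fitness)   # rows ordered by (c, g): first max wins
  structure(list(best_c = trace$c[best], best_g = trace$g[best],
                 fitness = trace$fitness[best], trace = trace,
                 tuner = "grid", task = task),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("SVM tuning (", x$tuner, ", ", x$task, "): best c = ",
      format(x$best_c, digits = 6), ", best g = ",
      format(x$best_g, digits = 6), ", fitness = ",
      format(x$fitness, digits = 6), " over ", nrow(x$trace),
      " evaluations\n", sep = "")
  invisible(x)
}

#' Canonical particle swarm maximisation
#'
#' Velocity update `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with
#' constriction-style defaults (w = 0.729, c1 = c2 = 1.49445), positions
#' clamped to the box. The global best is only ever replaced by a strictly
#' better particle, so its fitness sequence is monotone non-decreasing, and
#' the whole trajectory is reproducible from the seed.
#'
#' @param fn Objective to maximise, taking a numeric vector.
#' @param lower,upper Box bounds (equal length).
#' @param swarm Number of particles (>= 2).
#' @param iterations Number of update sweeps.
#' @param seed Integer RNG seed.
#' @param w,c1,c2 Inertia and acceleration constants.
#' @return List with `par`, `value`, `history` (gbest fitness per
#'   iteration) and `trace` (all evaluated points and fitnesses).
#' @export
pso_maximize <- function(fn, lower, upper, swarm = 20L, iterations = 100L,
                         seed = 1L, w = 0.729, c1 = 1.49445, c2 = 1.49445) {
  stopifnot(length(lower) == length(upper), all(upper > lower), swarm >= 2L)
  d <- length(lower)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  pos <- matrix(stats::runif(swarm * d, rep(lower, each = swarm),
                             rep(upper, each = swarm)), swarm, d)
  vel <- matrix(stats::runif(swarm * d, -1, 1), swarm, d) *
    matrix(rep(upper - lower, each = swarm), swarm, d) * 0.1
  fit <- apply(pos, 1L, fn)
  pbest <- pos; pbest_fit <- fit
  g_i <- which.max(fit)
  gbest <- pos[g_i, ]; gbest_fit <- fit[g_i]
  history <- numeric(iterations)
  trace <- cbind(pos, fitness = fit)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(swarm * d), swarm, d)
    r2 <- matrix(stats::runif(swarm * d), swarm, d)
    vel <- w * vel + c1 * r1 * (pbest - pos) +
      c2 * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - pos)
    pos <- pos + vel
    for (j in seq_len(d)) pos[, j] <- pmin(pmax(pos[, j], lower[j]), upper[j])
    fit <- apply(pos, 1L, fn)
    improved <- fit > pbest_fit
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    if (max(fit) > gbest_fit) {
      g_i <- which.max(fit)
      gbest <- pos[g_i, ]; gbest_fit <- fit[g_i]
    }
    history[it] <- gbest_fit
    trace <- rbind(trace, cbind(pos, fitness = fit))
  }
  list(par = gbest, value = gbest_fit, history = history, trace = trace)
}

#' PSO-tuned SVM hyperparameters
#'
#' Runs [pso_maximize()] over log2(c), log2(g) with [cv_fitness()] as the
#' objective, over the same default bounds as [grid_search()].
#'
#' @inheritParams cv_fitness
#' @param log2c_bounds,log2g_bounds Search box in log2 units.
#' @param swarm,iterations PSO size (defaults 20 particles, 100 sweeps).
#' @param seed Integer seed making the run reproducible.
#' @return A `tuning_result` (tuner `"pso"`) whose `trace` records every
#'   evaluated (c, g, fitness) triple and whose `history` is the monotone
#'   gbest fitness sequence.
#' @export
pso_svm <- function(x, y, task = c("classify", "regress"),
                    log2c_bounds = c(-5, 21), log2g_bounds = c(-21, 7),
                    swarm = 20L, iterations = 100L, seed = 1L,
                    folds = 7L, epsilon = 0.1) {
  task <- match.arg(task)
  fn <- function(par) {
    cv_fitness(x, y, 2^par[1L], 2^par[2L], folds = folds, task = task,
               epsilon = epsilon)
  }
  opt <- pso_maximize(fn, lower = c(log2c_bounds[1L], log2g_bounds[1L]),
                      upper = c(log2c_bounds[2L], log2g_bounds[2L]),
                      swarm = swarm, iterations = iterations, seed = seed)
  trace <- data.frame(c = 2^opt$trace[, 1L], g = 2^opt$trace[, 2L],
                      fitness = opt$trace[, 3L])
  structure(list(best_c = 2^opt$par[1L], best_g = 2^opt$par[2L],
                 fitness = opt$value, trace = trace,
                 history = opt$history, tuner = "pso", task = task),
            class = "tuning_result")
}
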