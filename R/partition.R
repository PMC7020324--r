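#' Kennard-Stone training/test split
#'
#' Classic deterministic Kennard-Stone selection: seed the training set with
#' the two samples at maximal pairwise Euclidean distance, then iteratively
#' add the sample whose minimum distance to the selected set is largest,
#' until the training set holds `floor(fraction * n)` samples. The remainder
#' is the test set. Ties are broken by the lowest row index, so the split is
#' fully reproducible and involves no random number generator.
#'
#' @param x Numeric matrix (samples x features) on which distances are
#'   measured -- conventionally the same matrix handed to the model.
#' @param fraction Training fraction in (0, 1); the default 2/3 gives a
#'   66/34 split for n = 100.
#' @return A list of class `split_index` with integer vectors `train` and
#'   `test` (row indices, selection order for `train`) and the `fraction`.
#' @export
kennard_stone <- function(x, fraction = 2 / 3) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("Kennard-Stone needs at least 3 samples", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- floor(fraction * n)
  n_train <- max(2L, as.integer(n_train))
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- NULL
  ## seed pair: maximal distance, ties -> lowest (i, j)
  best <- c(1L, 2L)
  best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    j_rel <- which.max(d[i, (i + 1L):n])        # first max = lowest j
    j <- i + j_rel
    if (d[i, j] > best_d) {
      best_d <- d[i, j]
      best <- c(i, j)
    }
  }
  selected <- best
  min_dist <- pmin(d[, best[1L]], d[, best[2L]])
  min_dist[selected] <- -Inf
  while (length(selected) < n_train) {
    nxt <- which.max(min_dist)                  # first max = lowest index
    selected <- c(selected, nxt)
    min_dist <- pmin(min_dist, d[, nxt])
    min_dist[nxt] <- -Inf
  }
  selected <- as.integer(unname(selected))
  structure(list(train = selected,
                 test = setdiff(seq_len(n), selected),
                 fraction = fraction),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat("Kennard-Stone split: ", length(x$train), " training / ",
      length(x$test), " test samples (fraction ",
      format(x$fraction, digits = 4), ")\n", sep = "")
  invisible(x)
}
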