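## Spectral pretreatments: Savitzky-Golay smoothing and derivatives, MSC,
## SNV, 1-2 min-max normalisation, and "+"-joined treatment chains such as
## "SNV+FD+SG(9)".

## Least-squares polynomial kernel: given point offsets (physical x units,
## 0 = the evaluation point), returns the weight vector whose dot product
## with the ordinates is the fitted value (deriv = 0) or the deriv-th
## derivative at 0.
.sg_weights <- function(offsets, polyorder, deriv = 0L) {
  A <- outer(offsets, 0:polyorder, `^`)
  coef_rows <- solve(crossprod(A), t(A))      # (polyorder+1) x m
  factorial(deriv) * coef_rows[deriv + 1L, ]
}

.sg_apply <- function(mat, grid, window, polyorder, deriv = 0L, gap = 1L) {
  p <- ncol(mat)
  h <- (window - 1L) %/% 2L
  out <- matrix(0, nrow(mat), p)
  ## interior kernel: window points at stride `gap`, symmetric about centre
  rel <- seq.int(-h, h) * gap
  interior <- which(seq_len(p) + min(rel) >= 1L & seq_len(p) + max(rel) <= p)
  if (length(interior)) {
    ## uniform grid assumed for the shared interior kernel
    step <- grid[1L] - grid[2L]
    w <- .sg_weights(-rel * step, polyorder, deriv)
    for (k in seq_along(rel)) {
      cols <- interior + rel[k]
      out[, interior] <- out[, interior] + w[k] * mat[, cols, drop = FALSE]
    }
  }
  ## edges: same window clipped to the valid index range (truncated window)
  edge_cols <- setdiff(seq_len(p), interior)
  for (j in edge_cols) {
    idx <- j + rel
    idx <- idx[idx >= 1L & idx <= p]
    if (length(idx) < polyorder + 1L) {
      idx <- seq.int(max(1L, j - h * gap), min(p, j + h * gap))
    }
    w <- .sg_weights(grid[idx] - grid[j], polyorder, deriv)
    out[, j] <- mat[, idx, drop = FALSE] %*% w
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Convolves each spectrum with the least-squares polynomial kernel of the
#' given window and order. Edge points are fitted on the window truncated at
#' the spectrum boundary, so output length equals input length.
#'
#' @param block A [spectra_block()].
#' @param window Odd window length, `5 <= window <= n_wavenumbers`.
#' @param polyorder Polynomial degree, `0 <= polyorder < window`. Default 2,
#'   the usual chemometrics choice.
#' @return A smoothed `spectra_block` of the same shape.
#' @export
sg_smooth <- function(block, window, polyorder = 2L) {
  stopifnot(inherits(block, "spectra_block"))
  p <- length(block$wavenumbers)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window < 5L || window > p) {
    stop("window must be odd and in [5, ", p, "]", call. = FALSE)
  }
  if (polyorder < 0L || polyorder >= window) {
    stop("polyorder must satisfy 0 <= polyorder < window", call. = FALSE)
  }
  out <- .sg_apply(block$absorbance, block$wavenumbers, window, polyorder)
  spectra_block(out, block$wavenumbers, block$meta)
}

#' Savitzky-Golay derivative
#'
#' Per-point polynomial fit of degree `max(2, order)` over a window of
#' `window` points spaced `gap` grid steps apart; returns the fitted
#' derivative of the requested order with respect to wavenumber. The
#' defaults (window 15, gap 1) are the usual derivative settings for
#' mid-infrared matrices of this kind.
#'
#' @param block A [spectra_block()].
#' @param order Derivative order, 1 or 2.
#' @param window Odd number of points in the fit window (default 15).
#' @param gap Stride between window points in grid steps (default 1; values
#'   above 1 give a gap-segment style derivative).
#' @return A `spectra_block` of derivative spectra (per cm^-1 units).
#' @export
spectral_derivative <- function(block, order, window = 15L, gap = 1L) {
  stopifnot(inherits(block, "spectra_block"))
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (gap < 1L) stop("gap must be >= 1", call. = FALSE)
  p <- length(block$wavenumbers)
  if ((window - 1L) * gap + 1L > p) {
    stop("derivative window exceeds spectrum length", call. = FALSE)
  }
  polyorder <- max(2L, order)
  out <- .sg_apply(block$absorbance, block$wavenumbers, window, polyorder,
                   deriv = as.integer(order), gap = as.integer(gap))
  spectra_block(out, block$wavenumbers, block$meta)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum
#' (`x ~ a * ref + b`, ordinary least squares) and replaced by
#' `(x - b) / a`. The default reference is the column-mean spectrum of the
#' block being fitted; pass the stored reference when transforming test
#' data so no test information leaks into the correction.
#'
#' @param block A [spectra_block()].
#' @param reference Optional reference spectrum (length = grid length). If
#'   `NULL`, the block's own mean spectrum is used.
#' @return A corrected `spectra_block` carrying the reference in
#'   `attr(, "msc_reference")`.
#' @export
msc <- function(block, reference = NULL) {
  stopifnot(inherits(block, "spectra_block"))
  if (is.null(reference)) reference <- colMeans(block$absorbance)
  if (length(reference) != length(block$wavenumbers)) {
    stop("reference length does not match the grid", call. = FALSE)
  }
  v <- stats::var(reference)
  if (!is.finite(v) || v <= 0) {
    stop("zero-variance reference: MSC fit is degenerate", call. = FALSE)
  }
  rm_ <- mean(reference)
  rc <- reference - rm_
  x <- block$absorbance
  a <- (x %*% rc) / sum(rc * rc)              # slope per spectrum
  b <- rowMeans(x) - a[, 1L] * rm_
  out <- sweep(x, 1L, b, `-`) / a[, 1L]
  res <- spectra_block(out, block$wavenumbers, block$meta)
  attr(res, "msc_reference") <- as.numeric(reference)
  res
}

#' Standard normal variate
#'
#' Centers each spectrum by its own mean and scales by its own sample SD
#' (n - 1 denominator), removing per-spectrum offset and gain.
#'
#' @param block A [spectra_block()].
#' @return An SNV-transformed `spectra_block`.
#' @export
snv <- function(block) {
  stopifnot(inherits(block, "spectra_block"))
  x <- block$absorbance
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop("constant spectrum cannot be SNV-scaled: sample ",
         block$meta$sample_id[bad[1L]], call. = FALSE)
  }
  spectra_block((x - m) / s, block$wavenumbers, block$meta)
}

#' Min-max normalisation to the range 1-2
#'
#' Maps each column j by `1 + (x - min_j) / (max_j - min_j)` using ranges
#' computed on the matrix itself (training) or supplied via `fitted_ranges`
#' (test). A constant training column maps to 1.5; test values outside the
#' training range are left unclipped, so they may fall outside [1, 2].
#'
#' @param x Numeric matrix (samples x features).
#' @param fitted_ranges Optional ranges from a previous call
#'   (`attr(out, "ranges")`).
#' @return The normalised matrix with the ranges in `attr(, "ranges")`.
#' @export
minmax_1_2 <- function(x, fitted_ranges = NULL) {
  x <- as.matrix(x)
  if (is.null(fitted_ranges)) {
    fitted_ranges <- list(min = apply(x, 2L, min), max = apply(x, 2L, max))
  }
  lo <- fitted_ranges$min
  hi <- fitted_ranges$max
  span <- hi - lo
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (span[j] > 0) 1 + (x[, j] - lo[j]) / span[j] else 1.5
  }
  attr(out, "ranges") <- fitted_ranges
  out
}

## ---- treatment chains -----------------------------------------------------

#' Parse a treatment chain string
#'
#' Chains are "+"-joined step names applied left to right: `No` (identity),
#' `SNV`, `MSC`, `FD` (first derivative, 15-point window), `SD` (second
#' derivative, 15-point window), `SG(w)` (Savitzky-Golay smoothing, odd
#' window `w`), `MINMAX` (1-2 min-max). At most one derivative step is
#' allowed and SG windows must be odd and at least 5. Whitespace is
#' ignored, so `"FD + SG (7)"` and `"FD+SG(7)"` are the same chain.
#'
#' @param string Chain string, e.g. `"SNV+FD+SG(9)"`.
#' @return An object of class `treatment_chain`.
#' @export
treatment_chain <- function(string) {
  compact <- gsub("[[:space:]]", "", string)
  if (compact == "" || toupper(compact) == "NO") {
    return(structure(list(steps = list()), class = "treatment_chain"))
  }
  tokens <- strsplit(compact, "+", fixed = TRUE)[[1L]]
  steps <- lapply(tokens, function(tok) {
    up <- toupper(tok)
    if (up == "SNV") return(list(kind = "SNV"))
    if (up == "MSC") return(list(kind = "MSC"))
    if (up == "FD") return(list(kind = "DERIV", order = 1L, window = 15L))
    if (up == "SD") return(list(kind = "DERIV", order = 2L, window = 15L))
    if (up == "MINMAX" || up == "MINMAX_1_2") return(list(kind = "MINMAX"))
    m <- regmatches(up, regexec("^SG\\(([0-9]+)\\)$", up))[[1L]]
    if (length(m) == 2L) {
      w <- as.integer(m[2L])
      if (w %% 2L == 0L || w < 5L) {
        stop("SG window must be odd and >= 5, got ", w, call. = FALSE)
      }
      return(list(kind = "SG", window = w))
    }
    stop("unknown treatment step: '", tok, "'", call. = FALSE)
  })
  n_deriv <- sum(vapply(steps, function(s) s$kind == "DERIV", logical(1)))
  if (n_deriv > 1L) {
    stop("a treatment chain may contain at most one derivative step",
         call. = FALSE)
  }
  structure(list(steps = steps), class = "treatment_chain")
}

#' @export
format.treatment_chain <- function(x, ...) {
  if (!length(x$steps)) return("No")
  paste(vapply(x$steps, function(s) {
    switch(s$kind,
           SNV = "SNV", MSC = "MSC", MINMAX = "MINMAX",
           DERIV = if (s$order == 1L) "FD" else "SD",
           SG = sprintf("SG(%d)", s$window))
  }, character(1)), collapse = "+")
}

#' @export
print.treatment_chain <- function(x, ...) {
  cat("treatment chain:", format(x), "\n")
  invisible(x)
}

#' Fit a treatment chain on training spectra
#'
#' Steps with data-dependent state (the MSC reference spectrum, the 1-2
#' min-max column ranges) freeze that state from the training block; the
#' fitted chain then transforms any block with the stored state, so test
#' spectra never influence the correction.
#'
#' @param chain A [treatment_chain()] or chain string.
#' @param block Training [spectra_block()].
#' @return A `fitted_chain` object.
#' @export
fit_chain <- function(chain, block) {
  if (is.character(chain)) chain <- treatment_chain(chain)
  stopifnot(inherits(chain, "treatment_chain"),
            inherits(block, "spectra_block"))
  states <- vector("list", length(chain$steps))
  cur <- block
  for (i in seq_along(chain$steps)) {
    s <- chain$steps[[i]]
    if (s$kind == "MSC") {
      cur <- msc(cur)
      states[[i]] <- attr(cur, "msc_reference")
    } else if (s$kind == "MINMAX") {
      normed <- minmax_1_2(cur$absorbance)
      states[[i]] <- attr(normed, "ranges")
      cur <- spectra_block(normed, cur$wavenumbers, cur$meta)
    } else {
      cur <- .apply_stateless_step(cur, s)
    }
  }
  structure(list(chain = chain, states = states),
            class = "fitted_chain")
}

.apply_stateless_step <- function(block, s) {
  switch(s$kind,
         SNV = snv(block),
         SG = sg_smooth(block, s$window),
         DERIV = spectral_derivative(block, s$order, s$window),
         stop("internal: unexpected step ", s$kind))
}

#' Transform a block with a fitted treatment chain
#'
#' @param fitted A `fitted_chain` from [fit_chain()].
#' @param block The [spectra_block()] to transform.
#' @return The treated `spectra_block`; the canonical chain string is
#'   recorded in `attr(, "treatment")`.
#' @export
transform_chain <- function(fitted, block) {
  stopifnot(inherits(fitted, "fitted_chain"), inherits(block, "spectra_block"))
  cur <- block
  for (i in seq_along(fitted$chain$steps)) {
    s <- fitted$chain$steps[[i]]
    if (s$kind == "MSC") {
      cur <- msc(cur, reference = fitted$states[[i]])
    } else if (s$kind == "MINMAX") {
      normed <- minmax_1_2(cur$absorbance, fitted_ranges = fitted$states[[i]])
      cur <- spectra_block(normed, cur$wavenumbers, cur$meta)
    } else {
      cur <- .apply_stateless_step(cur, s)
    }
  }
  attr(cur, "treatment") <- format(fitted$chain)
  cur
}

#' Apply a treatment chain (fit and transform in one step)
#'
#' Convenience wrapper equivalent to fitting the chain on `block` and
#' transforming `block` itself; use [fit_chain()]/[transform_chain()] when
#' training and test spectra must be treated separately.
#'
#' @inheritParams fit_chain
#' @return The treated `spectra_block`, with the fitted chain in
#'   `attr(, "fitted_chain")`.
#' @export
apply_chain <- function(block, chain) {
  f <- fit_chain(chain, block)
  out <- transform_chain(f, block)
  attr(out, "fitted_chain") <- f
  out
}
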