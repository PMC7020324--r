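#' @keywords internal
"_PACKAGE"

## Closed vocabularies used throughout the package.

#' Species and part vocabularies
#'
#' The four porcini species analysed by the pipeline and the two
#' morphological parts of a fruiting body. All metadata is validated
#' against these closed vocabularies.
#'
#' @return Character vector of levels, in canonical order.
#' @export
mirfuse_species <- function() {
  c("B_edulis", "L_rugosiceps", "B_tomentipes", "B_umbriniporus")
}

#' @rdname mirfuse_species
#' @export
mirfuse_parts <- function() {
  c("cap", "stipe")
}

#' Validate a wavenumber grid
#'
#' A wavenumber grid is a strictly descending numeric vector of mid-infrared
#' wavenumbers in cm^-1, conventionally running from about 4,000 down to
#' about 400 (the instrument axis convention).
#'
#' @param values Numeric vector of wavenumbers, cm^-1.
#' @return The validated grid (invisibly the same vector).
#' @export
wavenumber_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("wavenumber grid must contain at least 2 points", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("wavenumber grid contains non-finite values", call. = FALSE)
  }
  if (any(values <= 0) || any(values >= 10000)) {
    stop("wavenumbers must lie in (0, 10000) cm^-1", call. = FALSE)
  }
  if (any(diff(values) >= 0)) {
    stop("wavenumber grid must be strictly descending", call. = FALSE)
  }
  values
}

#' Construct a spectra block
#'
#' The unit every pipeline stage consumes and produces: an absorbance matrix
#' (samples x wavenumbers) together with per-sample metadata (sample id,
#' fruiting-body id, species, morphological part).
#'
#' @param absorbance Numeric matrix, `n_samples x n_wavenumbers`.
#' @param wavenumbers Descending numeric vector of wavenumbers (cm^-1),
#'   length equal to `ncol(absorbance)`.
#' @param meta Data frame with columns `sample_id`, `fruiting_body_id`,
#'   `species`, `part`; one row per spectrum. `sample_id` must be unique,
#'   `species` and `part` must come from [mirfuse_species()] and
#'   [mirfuse_parts()].
#' @return An object of class `spectra_block`.
#' @export
spectra_block <- function(absorbance, wavenumbers, meta) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- wavenumber_grid(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance has ", ncol(absorbance), " columns but grid has ",
         length(wavenumbers), " wavenumbers", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stop("non-finite absorbance at row ", bad[1L], ", column ", bad[2L],
         call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "fruiting_body_id", "species", "part")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[required]
  meta[] <- lapply(meta, as.character)
  if (nrow(meta) != nrow(absorbance)) {
    stop("metadata has ", nrow(meta), " rows but absorbance has ",
         nrow(absorbance), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- meta$sample_id[duplicated(meta$sample_id)][1L]
    stop("duplicate sample_id: ", dup, call. = FALSE)
  }
  bad_sp <- setdiff(unique(meta$species), mirfuse_species())
  if (length(bad_sp)) {
    stop("unknown species: ", paste(bad_sp, collapse = ", "), call. = FALSE)
  }
  bad_part <- setdiff(unique(meta$part), mirfuse_parts())
  if (length(bad_part)) {
    stop("unknown part: ", paste(bad_part, collapse = ", "), call. = FALSE)
  }
  dimnames(absorbance) <- list(meta$sample_id,
                               format(wavenumbers, trim = TRUE,
                                      scientific = FALSE))
  rownames(meta) <- NULL
  structure(list(absorbance = absorbance,
                 wavenumbers = wavenumbers,
                 meta = meta),
            class = "spectra_block")
}

#' @export
print.spectra_block <- function(x, ...) {
  cat("FT-MIR spectra block: ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumbers), " wavenumbers (",
      format(max(x$wavenumbers)), "-", format(min(x$wavenumbers)),
      " cm^-1)\n", sep = "")
  cat("  species: ", paste(sprintf("%s (%d)",
                                   names(table(x$meta$species)),
                                   as.integer(table(x$meta$species))),
                           collapse = ", "), "\n", sep = "")
  cat("  parts:   ", paste(sprintf("%s (%d)",
                                   names(table(x$meta$part)),
                                   as.integer(table(x$meta$part))),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_block <- function(x) dim(x$absorbance)

#' Subset the samples of a spectra block
#'
#' @param x A `spectra_block`.
#' @param i Row (sample) index vector.
#' @param ... Ignored.
#' @return A `spectra_block` with the selected samples.
#' @export
`[.spectra_block` <- function(x, i, ...) {
  spectra_block(x$absorbance[i, , drop = FALSE], x$wavenumbers,
                x$meta[i, , drop = FALSE])
}
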