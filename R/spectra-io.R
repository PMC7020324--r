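#' Read a spectra block from CSV
#'
#' Canonical exchange format: one header row, metadata columns first
#' (`sample_id, fruiting_body_id, species, part`), then one numeric-header
#' column per wavenumber. Wavenumber columns are reordered to the descending
#' instrument convention regardless of file order.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param meta_columns Names of the leading metadata columns.
#' @return A [spectra_block()].
#' @export
read_spectra_csv <- function(path,
                             meta_columns = c("sample_id", "fruiting_body_id",
                                              "species", "part")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(meta_columns, names(df))
  if (length(missing_cols)) {
    stop("CSV lacks metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  wn_names <- names(df)[!(names(df) %in% meta_columns)]
  wn <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(wn)) {
    stop("non-numeric wavenumber header(s): ",
         paste(wn_names[is.na(wn)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(wn)) {
    stop("duplicated wavenumber header(s): ",
         paste(unique(wn[duplicated(wn)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(wn, decreasing = TRUE)
  raw <- df[wn_names[ord]]
  mat <- matrix(NA_real_, nrow(df), length(wn_names))
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      bad_row <- which(is.na(v))[1L]
      stop("non-numeric absorbance at row ", bad_row, ", column '",
           wn_names[ord][j], "'", call. = FALSE)
    }
    mat[, j] <- v
  }
  meta <- df[meta_columns]
  names(meta) <- c("sample_id", "fruiting_body_id", "species", "part")
  spectra_block(mat, wn[ord], meta)
}

#' Write a spectra block to CSV
#'
#' Inverse of [read_spectra_csv()]: metadata columns first, then one column
#' per wavenumber in descending order. Absorbances are written with 17
#' significant digits so that a read/write round trip is lossless to within
#' double round-off.
#'
#' @param block A `spectra_block`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(block, path) {
  stopifnot(inherits(block, "spectra_block"))
  mat <- format(block$absorbance, digits = 17, trim = TRUE,
                scientific = TRUE)
  out <- cbind(block$meta, as.data.frame(mat, stringsAsFactors = FALSE))
  names(out) <- c(names(block$meta),
                  format(block$wavenumbers, trim = TRUE, scientific = FALSE,
                         digits = 15))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair cap and stipe blocks by fruiting body
#'
#' Reorders both blocks so that row i of the cap block and row i of the
#' stipe block come from the same fruiting body (the precondition of
#' splicing the two matrices). Fruiting bodies present in only one block are
#' dropped with a warning reporting the count.
#'
#' @param caps,stipes `spectra_block`s sharing the same wavenumber grid.
#' @return A list with elements `caps` and `stipes`, both reordered by
#'   ascending `fruiting_body_id`, and `n_dropped`, the number of unmatched
#'   fruiting bodies removed.
#' @export
pair_blocks <- function(caps, stipes) {
  stopifnot(inherits(caps, "spectra_block"), inherits(stipes, "spectra_block"))
  if (length(caps$wavenumbers) != length(stipes$wavenumbers) ||
      any(abs(caps$wavenumbers - stipes$wavenumbers) > 1e-9)) {
    stop("cap and stipe blocks have different wavenumber grids",
         call. = FALSE)
  }
  ids_c <- caps$meta$fruiting_body_id
  ids_s <- stipes$meta$fruiting_body_id
  common <- sort(intersect(ids_c, ids_s))
  n_dropped <- length(setdiff(ids_c, common)) + length(setdiff(ids_s, common))
  if (n_dropped > 0) {
    warning(n_dropped, " unmatched cap/stipe row(s) dropped", call. = FALSE)
  }
  if (length(common) == 0L) {
    stop("no fruiting body is present in both blocks", call. = FALSE)
  }
  list(caps = caps[match(common, ids_c)],
       stipes = stipes[match(common, ids_s)],
       n_dropped = n_dropped)
}
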