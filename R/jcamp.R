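## Minimal JCAMP-DX 4.24 reader: AFFN and SQZ/DIF/DUP (DIFDUP) ordinate
## tables under ##XYDATA=(X++(Y..Y)), plus ##XYPOINTS=(XY..XY).
## Read-only; vendor binary formats are out of scope.

.sqz_chars <- c(`@` = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7,
                H = 8, I = 9, a = -1, b = -2, c = -3, d = -4, e = -5,
                f = -6, g = -7, h = -8, i = -9)
.dif_chars <- c(`%` = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7,
                Q = 8, R = 9, j = -1, k = -2, l = -3, m = -4, n = -5,
                o = -6, p = -7, q = -8, r = -9)
.dup_chars <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8,
                s = 9)

## Split one ASDF data line into pseudo-digit tokens. A new token starts at
## any SQZ/DIF/DUP letter or at +/- (AFFN); spaces and commas also separate.
.asdf_tokens <- function(line) {
  chars <- strsplit(line, "")[[1L]]
  starts <- names(.sqz_chars)
  starts <- c(starts, names(.dif_chars), names(.dup_chars), "+", "-")
  tokens <- character(0)
  cur <- ""
  for (ch in chars) {
    if (ch %in% c(" ", ",", "\t", ";")) {
      if (nzchar(cur)) tokens <- c(tokens, cur)
      cur <- ""
    } else if (ch %in% starts) {
      if (nzchar(cur)) tokens <- c(tokens, cur)
      cur <- ch
    } else {
      cur <- paste0(cur, ch)
    }
  }
  if (nzchar(cur)) tokens <- c(tokens, cur)
  tokens
}

## Decode the ordinate tokens of one line (everything after the leading X).
## DUP counts are total occurrence counts: "K U" emits the +2 difference
## three times in all. Returns the ordinates plus whether the line ended in
## difference mode (the next line then starts with a duplicate Y check).
.decode_ordinates <- function(tokens, last_y = NA_real_) {
  y <- numeric(0)
  last_action <- NULL   # list(kind = "val"/"dif", value/diff)
  in_dif <- FALSE
  for (tok in tokens) {
    first <- substr(tok, 1L, 1L)
    rest <- substr(tok, 2L, nchar(tok))
    if (first %in% names(.dup_chars)) {
      count <- .dup_chars[[first]]
      if (nzchar(rest)) {
        stop("malformed DUP token: ", tok, call. = FALSE)
      }
      if (is.null(last_action)) {
        stop("DUP token with no preceding ordinate", call. = FALSE)
      }
      for (r in seq_len(count - 1L)) {
        if (last_action$kind == "dif") {
          y <- c(y, y[length(y)] + last_action$diff)
        } else {
          y <- c(y, last_action$value)
        }
      }
    } else if (first %in% names(.dif_chars)) {
      digit <- .dif_chars[[first]]
      diff <- .asdf_number(digit, rest)
      base <- if (length(y)) y[length(y)] else last_y
      if (is.na(base)) stop("DIF token with no base ordinate", call. = FALSE)
      y <- c(y, base + diff)
      last_action <- list(kind = "dif", diff = diff)
      in_dif <- TRUE
    } else if (first %in% names(.sqz_chars)) {
      digit <- .sqz_chars[[first]]
      val <- .asdf_number(digit, rest)
      y <- c(y, val)
      last_action <- list(kind = "val", value = val)
      in_dif <- FALSE
    } else {
      val <- suppressWarnings(as.numeric(tok))
      if (is.na(val)) stop("unparseable ordinate token: ", tok, call. = FALSE)
      y <- c(y, val)
      last_action <- list(kind = "val", value = val)
      in_dif <- FALSE
    }
  }
  list(y = y, in_dif = in_dif)
}

.asdf_number <- function(lead_digit, rest) {
  if (!nzchar(rest)) return(lead_digit)
  if (grepl("[^0-9]", rest)) {
    stop("malformed pseudo-digit token tail: ", rest, call. = FALSE)
  }
  sign <- if (lead_digit < 0) -1 else 1
  sign * as.numeric(paste0(abs(lead_digit), rest))
}

#' Read a single JCAMP-DX spectrum
#'
#' Parses a JCAMP-DX 4.24 file containing one spectrum stored either as an
#' `##XYDATA=(X++(Y..Y))` table (AFFN or SQZ/DIF/DUP compressed) or an
#' `##XYPOINTS=(XY..XY)` table. `XFACTOR`/`YFACTOR` scaling is applied; when
#' a line ends in difference mode the duplicate Y check value opening the
#' next line is verified and dropped, as the format prescribes.
#'
#' @param path Path to a JCAMP-DX file.
#' @return A list with `wavenumbers` (numeric, file order) and `absorbance`
#'   (numeric, same length).
#' @export
read_jcamp_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- list()
  data_start <- NA_integer_
  data_kind <- NA_character_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        key <- toupper(gsub("[ _-]", "", substr(ln, 3L, eq - 1L)))
        val <- trimws(substr(ln, eq + 1L, nchar(ln)))
        ldr[[key]] <- val
        if (key == "XYDATA") { data_start <- i + 1L; data_kind <- "xydata" }
        if (key == "XYPOINTS") { data_start <- i + 1L; data_kind <- "xypoints" }
      }
    }
  }
  if (is.na(data_start)) {
    stop("no ##XYDATA or ##XYPOINTS record in ", path, call. = FALSE)
  }
  data_lines <- character(0)
  for (i in data_start:length(lines)) {
    if (startsWith(lines[i], "##")) break
    if (nzchar(trimws(lines[i]))) data_lines <- c(data_lines, trimws(lines[i]))
  }
  xf <- if (!is.null(ldr$XFACTOR)) as.numeric(ldr$XFACTOR) else 1
  yf <- if (!is.null(ldr$YFACTOR)) as.numeric(ldr$YFACTOR) else 1

  if (data_kind == "xypoints") {
    nums <- as.numeric(unlist(regmatches(
      data_lines, gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?",
                           data_lines))))
    if (length(nums) %% 2L != 0L) {
      stop("odd number of values in ##XYPOINTS table", call. = FALSE)
    }
    x <- nums[seq(1L, length(nums), by = 2L)] * xf
    y <- nums[seq(2L, length(nums), by = 2L)] * yf
    return(list(wavenumbers = x, absorbance = y))
  }

  y_raw <- numeric(0)
  x_first <- numeric(0)
  prev_in_dif <- FALSE
  for (ln in data_lines) {
    tokens <- .asdf_tokens(ln)
    if (!length(tokens)) next
    x_first <- c(x_first, suppressWarnings(as.numeric(tokens[1L])))
    dec <- .decode_ordinates(tokens[-1L],
                             last_y = if (length(y_raw)) y_raw[length(y_raw)]
                                      else NA_real_)
    ys <- dec$y
    if (prev_in_dif && length(ys)) {
      if (length(y_raw) &&
          abs(ys[1L] - y_raw[length(y_raw)]) > 1e-6 * max(1, abs(ys[1L]))) {
        warning("DIFDUP Y-value check failed at X = ", tokens[1L],
                call. = FALSE)
      }
      ys <- ys[-1L]
    }
    y_raw <- c(y_raw, ys)
    prev_in_dif <- dec$in_dif
  }
  n <- length(y_raw)
  if (!is.null(ldr$NPOINTS) && as.integer(ldr$NPOINTS) != n) {
    warning("##NPOINTS=", ldr$NPOINTS, " but ", n, " ordinates decoded",
            call. = FALSE)
  }
  if (!is.null(ldr$FIRSTX) && !is.null(ldr$LASTX) && n > 1L) {
    x <- seq(as.numeric(ldr$FIRSTX), as.numeric(ldr$LASTX), length.out = n)
  } else {
    dx <- if (!is.null(ldr$DELTAX)) as.numeric(ldr$DELTAX) else
      stop("cannot reconstruct X axis: need FIRSTX/LASTX or DELTAX",
           call. = FALSE)
    x <- x_first[1L] * xf + dx * (seq_len(n) - 1L)
  }
  list(wavenumbers = x, absorbance = y_raw * yf)
}
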