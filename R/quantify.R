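## Folin-Ciocalteu total-polyphenol bookkeeping: gallic-acid calibration,
## dilution arithmetic, content in mg/g dry weight (gallic-acid
## equivalents), extraction percentage, per-species summaries and the
## cap/stipe bioconcentration factor.

#' Folin-Ciocalteu assay protocol
#'
#' Volumes and masses of the assay chain: `sample_mass` grams of dry powder
#' extracted and made up to `extract_volume` ml; an `aliquot` of that
#' extract diluted into `diluent` ml of water (the dilution fold counts only
#' this step -- the Folin reagent and carbonate additions are applied
#' identically to the calibration standards, so they cancel); absorbance
#' read at `wavelength` nm.
#'
#' @param sample_mass Dry sample mass in g (default 0.2500).
#' @param extract_volume Final extract volume in ml (default 25).
#' @param aliquot Aliquot taken for dilution, ml (default 0.1).
#' @param diluent Water added to the aliquot, ml (default 7.9).
#' @param reagent_folin,reagent_carbonate Recorded reagent volumes, ml
#'   (excluded from the fold factor).
#' @param wavelength Read-out wavelength, nm (default 760).
#' @return List of class `assay_protocol`.
#' @export
assay_protocol <- function(sample_mass = 0.2500, extract_volume = 25,
                           aliquot = 0.1, diluent = 7.9,
                           reagent_folin = 0.5, reagent_carbonate = 1.5,
                           wavelength = 760) {
  stopifnot(sample_mass > 0, extract_volume > 0, aliquot > 0, diluent >= 0)
  structure(list(sample_mass = sample_mass, extract_volume = extract_volume,
                 aliquot = aliquot, diluent = diluent,
                 reagent_folin = reagent_folin,
                 reagent_carbonate = reagent_carbonate,
                 wavelength = wavelength),
            class = "assay_protocol")
}

#' Dilution fold of the assay
#'
#' `(aliquot + diluent) / aliquot`: 0.1 ml into 7.9 ml of water is an
#' 80-fold dilution.
#'
#' @param protocol An [assay_protocol()].
#' @return Scalar fold factor.
#' @export
dilution_fold <- function(protocol = assay_protocol()) {
  (protocol$aliquot + protocol$diluent) / protocol$aliquot
}

#' Fit a gallic-acid calibration line
#'
#' Ordinary least squares of absorbance on standard concentration.
#'
#' @param concentration Standard concentrations, mg/ml gallic acid (>= 3,
#'   not all equal).
#' @param absorbance Measured absorbances at 760 nm.
#' @return List of class `calibration_curve` with `slope` (absorbance per
#'   mg/ml), `intercept` and `r2_fit`.
#' @export
fit_calibration <- function(concentration, absorbance) {
  stopifnot(length(concentration) == length(absorbance))
  if (length(concentration) < 3L) {
    stop("calibration needs at least 3 standards", call. = FALSE)
  }
  if (stats::sd(concentration) == 0) {
    stop("standard concentrations are all equal; design is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope is not positive", call. = FALSE)
  }
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2_fit <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r2_fit = r2_fit,
                 n_standards = length(concentration)),
            class = "calibration_curve")
}

#' Convert 760-nm absorbance to content in mg/g dry weight
#'
#' Inverts the calibration line to the diluted concentration, then undoes
#' the dilution and extraction bookkeeping:
#' `content = (A - intercept)/slope * fold * extract_volume / sample_mass`.
#' Absorbances below the intercept (implying negative concentration) are
#' clamped to zero content with a warning.
#'
#' @param absorbance_760 Numeric absorbance(s) at 760 nm.
#' @param curve A [fit_calibration()] curve.
#' @param protocol An [assay_protocol()].
#' @return Content(s) in mg/g dw, gallic-acid equivalents.
#' @export
absorbance_to_content <- function(absorbance_760, curve,
                                  protocol = assay_protocol()) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (as.numeric(absorbance_760) - curve$intercept) / curve$slope
  n_neg <- sum(conc < 0)
  if (n_neg > 0) {
    warning(n_neg, " absorbance(s) below the calibration intercept ",
            "clamped to zero content", call. = FALSE)
    conc[conc < 0] <- 0
  }
  conc * dilution_fold(protocol) * protocol$extract_volume /
    protocol$sample_mass
}

#' Forward-simulate the assay absorbance for a known content
#'
#' The exact inverse of [absorbance_to_content()], used to generate
#' synthetic assay read-outs from true contents.
#'
#' @param content Content(s) in mg/g dw.
#' @param curve A [fit_calibration()] curve.
#' @param protocol An [assay_protocol()].
#' @return Absorbance(s) at 760 nm.
#' @export
content_to_absorbance <- function(content, curve,
                                  protocol = assay_protocol()) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- as.numeric(content) * protocol$sample_mass /
    (dilution_fold(protocol) * protocol$extract_volume)
  curve$slope * conc + curve$intercept
}

#' Per-species, per-part content summaries and bioconcentration factors
#'
#' For every species x part cell with data: arithmetic mean, sample SD
#' (n - 1; reported as 0 with a flag when n = 1), median (mean of the
#' central pair for even n), min-max range, n, and the extraction
#' percentage `mean / 10` (mg/g dry weight to percent of dry weight). Per
#' species, the cap/stipe bioconcentration factor is the cap median divided
#' by the stipe median.
#'
#' @param records Data frame with columns `species`, `part`, `content`
#'   (mg/g dw).
#' @return List of class `species_summary` with data frames `cells` and
#'   `bcf`.
#' @export
summarize_species <- function(records) {
  stopifnot(all(c("species", "part", "content") %in% names(records)))
  cells <- list()
  for (sp in unique(records$species)) {
    for (pt in unique(records$part[records$species == sp])) {
      v <- records$content[records$species == sp & records$part == pt]
      if (!length(v)) next
      cells[[length(cells) + 1L]] <- data.frame(
        species = sp, part = pt, n = length(v),
        mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        sd_degenerate = length(v) == 1L,
        median = stats::median(v),
        min = min(v), max = max(v),
        extraction_pct = mean(v) / 10,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  bcf <- bcf_cap_stipe(cells)
  structure(list(cells = cells, bcf = bcf), class = "species_summary")
}

#' Cap/stipe bioconcentration factor
#'
#' Median cap content divided by median stipe content, per species, rounded
#' to 2 decimals for display.
#'
#' @param cells Data frame with columns `species`, `part`, `median` (as in
#'   `summarize_species()$cells`), or a `species_summary`.
#' @return Data frame with `species`, `bcf` (exact ratio) and
#'   `bcf_display` (2-decimal rounding).
#' @export
bcf_cap_stipe <- function(cells) {
  if (inherits(cells, "species_summary")) cells <- cells$cells
  out <- list()
  for (sp in unique(cells$species)) {
    cap_med <- cells$median[cells$species == sp & cells$part == "cap"]
    stipe_med <- cells$median[cells$species == sp & cells$part == "stipe"]
    if (!length(cap_med) || !length(stipe_med)) {
      stop("species ", sp, " lacks a cap or stipe median", call. = FALSE)
    }
    if (stipe_med <= 0) {
      stop("stipe median must be positive for BCF", call. = FALSE)
    }
    ratio <- cap_med / stipe_med
    out[[length(out) + 1L]] <- data.frame(species = sp, bcf = ratio,
                                          bcf_display = round(ratio, 2),
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.species_summary <- function(x, ...) {
  for (i in seq_len(nrow(x$cells))) {
    r <- x$cells[i, ]
    cat(sprintf("%-16s %-6s n=%-4d %5.2f +/- %4.2f  median %5.2f  range %.2f-%.2f  extraction %.2f%%\n",
                r$species, r$part, r$n, r$mean, r$sd, r$median, r$min,
                r$max, r$extraction_pct))
  }
  cat("BCF (cap/stipe): ",
      paste(sprintf("%s %.2f", x$bcf$species, x$bcf$bcf_display),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
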