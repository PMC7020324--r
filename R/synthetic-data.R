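## Synthetic FT-MIR generator: Gaussian bands at the positions seen in real
## porcini spectra, species/part-modulated intensities, a designated phenolic
## band whose height is an exact affine function of total-polyphenol content,
## plus scatter, baseline drift and detector noise.

#' Default descending wavenumber grid
#'
#' Arithmetic grid from 4,000 down to 400 cm^-1, the conventional mid-IR
#' acquisition range. Both endpoints are included when the step divides the
#' range.
#'
#' @param step Grid spacing in cm^-1, in (0, 16]. Default 2, the
#'   conventional digitisation at 4 cm^-1 optical resolution.
#' @return A descending numeric wavenumber grid.
#' @export
default_grid <- function(step = 2) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0 || step > 1800) {
    stop("step must be a single positive number", call. = FALSE)
  }
  wavenumber_grid(seq(4000, 400, by = -step))
}

#' Default synthetic band set
#'
#' Gaussian band parameters for the absorptions characteristic of dried
#' mushroom powder: the broad O-H/N-H stretch near 3,350, methylene C-H
#' stretch at 2,928, amide I/II near 1,640 and 1,543, O-C-H and C-H bends at
#' 1,402 and 1,377, the in-plane C-H bend at 1,313, and the polysaccharide
#' C-O stretches at 1,082 and 1,025 cm^-1. Band positions are shared across
#' species; the per-species and per-part columns are multiplicative
#' intensity factors, so only intensities differ between classes.
#'
#' @return Data frame with columns `center`, `width` (Gaussian sigma,
#'   cm^-1), `base_intensity` (absorbance) and multiplicative factors
#'   `d_<species>` and `d_<part>`.
#' @export
default_bands <- function() {
  data.frame(
    center = c(3350, 2928, 1640, 1543, 1402, 1377, 1313, 1082, 1025),
    width  = c(  80,   20,   30,   30,   25,   20,   25,   30,   30),
    base_intensity = c(0.55, 0.30, 0.50, 0.35, 0.22, 0.18, 0.15, 0.40, 0.45),
    d_B_edulis       = c(1.00, 1.10, 1.15, 1.10, 0.95, 1.00, 1.05, 0.90, 0.95),
    d_L_rugosiceps   = c(1.05, 0.95, 1.00, 0.95, 1.10, 1.05, 0.95, 1.00, 1.10),
    d_B_tomentipes   = c(0.95, 1.05, 0.90, 1.00, 1.00, 0.90, 1.10, 1.10, 1.00),
    d_B_umbriniporus = c(1.10, 0.90, 1.05, 1.15, 0.90, 1.10, 1.00, 1.05, 0.90),
    d_cap   = c(1.05, 1.00, 1.10, 1.05, 1.00, 0.95, 1.00, 0.95, 1.00),
    d_stipe = c(0.95, 1.00, 0.90, 0.95, 1.00, 1.05, 1.00, 1.10, 1.00)
  )
}

#' Default per-species, per-part polyphenol content parameters
#'
#' Mean and SD of total-polyphenol content (mg/g dry weight, gallic-acid
#' equivalents) for each species and morphological part, matching the
#' summary statistics the quantification stage is expected to recover.
#'
#' @return Data frame with columns `species`, `part`, `mean`, `sd`.
#' @export
default_content_params <- function() {
  data.frame(
    species = rep(mirfuse_species(), each = 2L),
    part = rep(mirfuse_parts(), times = 4L),
    mean = c(15.10, 15.81, 14.33, 14.00, 12.27, 11.30, 10.22, 10.74),
    sd   = c( 1.37,  3.48,  2.02,  2.10,  1.85,  3.83,  1.97,  1.40)
  )
}

#' Configuration of the synthetic dataset generator
#'
#' @param n_bodies_per_species Fruiting bodies per species; the default 25
#'   (x 4 species = 100 bodies) matches the sampling scale of a typical
#'   porcini survey.
#' @param grid_step Wavenumber spacing in cm^-1 (see [default_grid()]).
#' @param bands Band table as from [default_bands()].
#' @param scatter_slope_sd SD of the multiplicative scatter slope (around 1).
#' @param scatter_offset_sd SD of the additive scatter offset.
#' @param baseline_amp Amplitude of the random quadratic baseline drift
#'   (absorbance units over the full range).
#' @param noise_sd SD of iid additive detector noise.
#' @param phenol_band_center,phenol_band_width Position/width (cm^-1) of the
#'   designated phenolic band (aromatic ring stretch region).
#' @param phenol_link_slope,phenol_link_intercept Affine link between content
#'   (mg/g dw) and phenolic band height:
#'   `height = (content - intercept) / slope`.
#' @param species_content_params Content means/SDs as from
#'   [default_content_params()].
#' @param seed Integer master seed; every random draw is derived from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bodies_per_species = 25L,
                             grid_step = 2,
                             bands = default_bands(),
                             scatter_slope_sd = 0.02,
                             scatter_offset_sd = 0.01,
                             baseline_amp = 0.02,
                             noise_sd = 0.005,
                             phenol_band_center = 1515,
                             phenol_band_width = 12,
                             phenol_link_slope = 50,
                             phenol_link_intercept = 0,
                             species_content_params = default_content_params(),
                             seed = 1L) {
  stopifnot(n_bodies_per_species >= 1L,
            scatter_slope_sd >= 0, scatter_offset_sd >= 0,
            baseline_amp >= 0, noise_sd >= 0,
            phenol_band_width > 0, phenol_link_slope > 0)
  grid <- default_grid(grid_step)
  if (phenol_band_center > max(grid) || phenol_band_center < min(grid)) {
    stop("phenol band center outside the wavenumber grid", call. = FALSE)
  }
  key <- interaction(species_content_params$species,
                     species_content_params$part)
  need <- interaction(rep(mirfuse_species(), each = 2L),
                      rep(mirfuse_parts(), 4L))
  if (!all(as.character(need) %in% as.character(key))) {
    stop("species_content_params must cover all 4 species x 2 parts",
         call. = FALSE)
  }
  if (any(species_content_params$sd < 0)) {
    stop("content SDs must be non-negative", call. = FALSE)
  }
  structure(list(n_bodies_per_species = as.integer(n_bodies_per_species),
                 grid = grid, grid_step = grid_step, bands = bands,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 baseline_amp = baseline_amp, noise_sd = noise_sd,
                 phenol_band_center = phenol_band_center,
                 phenol_band_width = phenol_band_width,
                 phenol_link_slope = phenol_link_slope,
                 phenol_link_intercept = phenol_link_intercept,
                 species_content_params = species_content_params,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## Deterministic substream seed from (master seed, counter): row order of
## generation never matters, only the counter.
.substream_seed <- function(seed, counter) {
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 +
                as.numeric(counter) * 16807) %% 2147483629 + 1)
}

.gaussian_band <- function(grid, center, sigma, height) {
  height * exp(-(grid - center)^2 / (2 * sigma^2))
}

#' Generate one synthetic FT-MIR spectrum
#'
#' The deterministic core is a sum of Gaussian bands whose base intensities
#' are modulated multiplicatively per species and per part, plus the
#' phenolic band whose height is
#' `(content - phenol_link_intercept) / phenol_link_slope`. On top of that:
#' a random quadratic baseline, multiplicative scatter `a * x + b` with
#' `a ~ N(1, scatter_slope_sd)` and `b ~ N(0, scatter_offset_sd)`, and iid
#' Gaussian noise. With all noise scales zero the spectrum is an exact
#' function of (species, part, content).
#'
#' @param config A [synthetic_config()].
#' @param species,part Class labels from the closed vocabularies.
#' @param content Total-polyphenol content in mg/g dw (> 0).
#' @param substream Integer counter selecting the deterministic random
#'   substream for this sample.
#' @return Numeric absorbance vector on `config$grid`.
#' @export
generate_spectrum <- function(config, species, part, content, substream = 0L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!species %in% mirfuse_species()) {
    stop("unknown species: ", species, call. = FALSE)
  }
  if (!part %in% mirfuse_parts()) {
    stop("unknown part: ", part, call. = FALSE)
  }
  if (!is.finite(content) || content <= 0) {
    stop("content must be positive", call. = FALSE)
  }
  grid <- config$grid
  bands <- config$bands
  sp_col <- paste0("d_", species)
  part_col <- paste0("d_", part)
  y <- numeric(length(grid))
  for (b in seq_len(nrow(bands))) {
    h <- bands$base_intensity[b] * bands[[sp_col]][b] * bands[[part_col]][b]
    y <- y + .gaussian_band(grid, bands$center[b], bands$width[b], h)
  }
  phenol_height <- (content - config$phenol_link_intercept) /
    config$phenol_link_slope
  y <- y + .gaussian_band(grid, config$phenol_band_center,
                          config$phenol_band_width, phenol_height)

  rng <- .substream_seed(config$seed, substream)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(rng)
  t <- (max(grid) - grid) / (max(grid) - min(grid))   # 0..1 along the scan
  base_coef <- stats::runif(3, -1, 1) * config$baseline_amp
  baseline <- base_coef[1L] + base_coef[2L] * t + base_coef[3L] * t^2
  a <- stats::rnorm(1, 1, config$scatter_slope_sd)
  off <- stats::rnorm(1, 0, config$scatter_offset_sd)
  noise <- stats::rnorm(length(grid), 0, config$noise_sd)
  a * (y + baseline) + off + noise
}

## Truncated-normal content draw (lower bound 0.1 mg/g) in its own substream.
.draw_content <- function(mean, sd, seed, substream) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(.substream_seed(seed, substream))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0.1) return(x)
  }
  0.1
}

#' Generate a full synthetic cap/stipe dataset
#'
#' For each fruiting body (balanced across the four species) draws a
#' per-part polyphenol content from the configured truncated normal and
#' emits one cap and one stipe spectrum. Fully reproducible from
#' `config$seed`; per-sample substreams are indexed by fruiting-body counter
#' so generation order is irrelevant.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `caps` and
#'   `stipes` ([spectra_block()]s), `contents` (data frame: `sample_id`,
#'   `fruiting_body_id`, `species`, `part`, `content` in mg/g dw) and
#'   `config` (the generating truth).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_sp <- config$n_bodies_per_species
  species <- rep(mirfuse_species(), each = n_sp)
  n_bodies <- length(species)
  body_ids <- sprintf("FB%03d", seq_len(n_bodies))
  cp <- config$species_content_params

  blocks <- list()
  contents <- list()
  for (part in mirfuse_parts()) {
    part_i <- match(part, mirfuse_parts())
    mat <- matrix(0, n_bodies, length(config$grid))
    cont <- numeric(n_bodies)
    for (i in seq_len(n_bodies)) {
      row <- cp[cp$species == species[i] & cp$part == part, ]
      counter <- (i - 1L) * 4L + (part_i - 1L) * 2L
      cont[i] <- .draw_content(row$mean, row$sd, config$seed, counter)
      mat[i, ] <- generate_spectrum(config, species[i], part, cont[i],
                                    substream = counter + 1L)
    }
    meta <- data.frame(sample_id = paste0(body_ids, "_", part),
                       fruiting_body_id = body_ids,
                       species = species, part = part,
                       stringsAsFactors = FALSE)
    blocks[[part]] <- spectra_block(mat, config$grid, meta)
    contents[[part]] <- cbind(meta, content = cont)
  }
  contents <- do.call(rbind, contents)
  rownames(contents) <- NULL
  structure(list(caps = blocks$cap, stipes = blocks$stipe,
                 contents = contents, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic FT-MIR dataset:", nrow(x$caps$absorbance),
      "fruiting bodies (cap + stipe),", length(x$config$grid),
      "wavenumbers, seed", x$config$seed, "\n")
  invisible(x)
}
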