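## Shared fixture builders: everything is generated in code at test time.

## Small, fast generator configuration for unit tests: coarse grid and few
## fruiting bodies. Study-scale runs (default config) live in the
## acceptance suite.
small_config <- function(seed = 1L, n_bodies_per_species = 6L, ...) {
  synthetic_config(n_bodies_per_species = n_bodies_per_species,
                   grid_step = 16, seed = seed, ...)
}

## Hand-built block: rows x wavenumbers, descending grid.
toy_block <- function(mat, wavenumbers,
                      species = rep("B_edulis", nrow(mat)),
                      part = rep("cap", nrow(mat)),
                      ids = sprintf("S%02d", seq_len(nrow(mat)))) {
  spectra_block(mat, wavenumbers,
                data.frame(sample_id = ids, fruiting_body_id = ids,
                           species = species, part = part,
                           stringsAsFactors = FALSE))
}

## Labelled Gaussian-class matrix for classifier tests: k well-separated
## clouds in p dimensions.
class_clouds <- function(n_per_class, centers, sd = 0.3, seed = 1L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    matrix(stats::rnorm(n_per_class * ncol(centers), sd = sd),
           n_per_class) + matrix(centers[k, ], n_per_class,
                                 ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(letters[seq_len(nrow(centers))],
                           each = n_per_class))
}

## JCAMP fixture writers (text built in code).
write_jcamp <- function(data_line, firstx = 4000, lastx = 3992,
                        npoints = 5, yfactor = 0.001) {
  path <- tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=synthetic fixture",
               "##JCAMP-DX=4.24",
               "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
               "##XFACTOR=1",
               paste0("##YFACTOR=", yfactor),
               paste0("##FIRSTX=", firstx),
               paste0("##LASTX=", lastx),
               paste0("##NPOINTS=", npoints),
               "##XYDATA=(X++(Y..Y))",
               data_line,
               "##END="), path)
  path
}
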