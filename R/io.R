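run_config_defaults <- function() {
  list(
    observer = list(age = 30, pigmentation = 0.5),
    scene = list(ambient_luminance_cd_m2 = 13.14, target_contrast = 0.89,
                 target_size_deg = 2.75),
    laser = list(wavelength_nm = 532, power_mW = 100, divergence_mrad = 1.5,
                 initial_beam_diameter_m = 0, distance_m = 100,
                 incidence_angle_deg = 0.5),
    options = list(seed = 42, exposure_time_s = 0.25, safety_weight = 0.5))
}

#' Load and validate a scenario configuration file
#'
#' Reads a YAML or JSON scenario configuration with sections `observer`,
#' `scene`, `laser` and `options`, validates it against the known schema
#' (unknown keys are rejected by name), and fills defaults for anything
#' omitted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `run_config` with the four sections complete.
#' @export
load_scene_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- run_config_defaults()
  bad_sections <- setdiff(names(raw), names(defaults))
  if (length(bad_sections)) {
    abort(paste0("unknown config section(s): ",
                 paste(bad_sections, collapse = ", ")))
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      abort(paste0("unknown key(s) in `", sec, "`: ",
                   paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, raw)
  structure(cfg, class = "run_config")
}

#' Build model objects from a run config
#'
#' @param config A `run_config` from [load_scene_config()].
#' @return A list with `observer`, `scene`, `source` and `exposure` model
#'   objects (irradiance from the far-field model at the configured
#'   distance).
#' @export
config_objects <- function(config) {
  src <- laser_source(config$laser$power_mW, config$laser$divergence_mrad,
                      config$laser$initial_beam_diameter_m,
                      config$laser$distance_m, config$laser$wavelength_nm)
  list(
    observer = observer_profile(config$observer$age,
                                config$observer$pigmentation),
    scene = scene_conditions(config$scene$ambient_luminance_cd_m2,
                             config$scene$target_contrast,
                             config$scene$target_size_deg),
    source = src,
    exposure = laser_exposure(config$laser$wavelength_nm,
                              eye_irradiance_at_distance(src),
                              config$laser$incidence_angle_deg))
}

#' Write a report as stable CSV and/or JSON
#'
#' Deterministic serialization: fixed `%.6g` float formatting, sorted JSON
#' keys, LF line endings, UTF-8. The same report written twice is
#' byte-identical.
#'
#' @param report A data frame.
#' @param path Output path without extension.
#' @param format `"csv"`, `"json"` or both.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  written <- character()
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)
  }
  if ("csv" %in% format) {
    f <- paste0(path, ".csv")
    df <- as.data.frame(lapply(report, fmt), check.names = FALSE,
                        stringsAsFactors = FALSE)
    con <- file(f, open = "wb")
    writeLines(paste(names(report), collapse = ","), con, sep = "\n")
    if (nrow(report) > 0) {
      lines <- apply(df, 1, paste, collapse = ",")
      writeLines(lines, con, sep = "\n")
    }
    close(con)
    written <- c(written, f)
  }
  if ("json" %in% format) {
    f <- paste0(path, ".json")
    cols <- report[order(names(report))]
    jsonlite::write_json(cols, f, dataframe = "columns", digits = 6,
                         pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read and write grayscale images
#'
#' 8- or 16-bit grayscale PNG/TIFF readers and writers returning plain
#' numeric matrices in `[0, 1]`. Multi-channel images are averaged to gray.
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @return `read_gray_image()`: a numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    abort("unsupported image format: use PNG or TIFF.")
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' @rdname read_gray_image
#' @param image Numeric matrix; values are clipped to `[0, 1]`.
#' @param bits 8 or 16 bits per sample.
#' @export
write_gray_image <- function(image, path, bits = 16) {
  image <- pmin(pmax(image, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(image, path, bits.per.sample = bits)
  } else {
    abort("unsupported image format: use PNG or TIFF.")
  }
  invisible(path)
}

#' Volunteer comparison fixture and matching rate
#'
#' The shipped volunteer/system comparison records (two lighting
#' conditions, five observers each) and the visual-effect matching rate
#' computed from them: the fraction of trials whose outcome is recorded as
#' matched.
#'
#' @return `matching_fixture()`: tibble of the comparison records;
#'   `matching_rate()`: the matching percentage (0--100).
#' @export
matching_fixture <- function() {
  path <- system.file("extdata", "volunteer_matching.csv",
                      package = "dazzlesim")
  tibble::as_tibble(read.csv(path))
}

#' @rdname matching_fixture
#' @export
matching_rate <- function() {
  fx <- matching_fixture()
  100 * mean(fx$matched)
}
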