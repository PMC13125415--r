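# ---------------------------------------------------------------------------
# Run configuration: schema, defaults, validation, output writing.
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' Full configuration with the machine defaults (250 MeV, 379 mm range,
#' 3.5 mm spot sigma, 3 mrad divergence, 6.09e6 protons/MU, 400 MU minimum,
#' 0.5 ms minimum spot time, 2 mm dose grid, 5 mm spot spacing) and the
#' standard sweep / head-case parameters.
#'
#' @return nested named list (the RunConfig)
#' @export
default_config <- function() {
  list(
    beam = list(energy = 250, range_water = 379, sigma_iso = 3.5,
                divergence = 0.003, protons_per_mu = 6.09e6,
                mu_rate = 8e5, min_mu = 400, min_spot_time = 5e-4,
                bragg_kleeman_p = 1.77),
    dose_grid = 2,
    sweep = list(field_sizes = c(30, 50), pullbacks = c(100, 200, 300),
                 air_gaps = c(50, 100, 150), spot_spacing = 5, margin = 5),
    head = list(rx = 30, thresholds = c(0, 2, 5), gtv_diameter = 37,
                air_gap = 100),
    field = list(field_size = 30, pullback = 100, air_gap = 50,
                 phantom_size = c(200, 200, 400)),
    metrics = list(dose_path = NULL, rx = NULL),
    output = list(formats = c("csv", "json", "mhd")),
    seed = 20260428
  )
}

# schema: every leaf of default_config() is a leaf here; unknown keys are
# rejected, known keys type/constraint-checked
.check_config <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref))
      stop("unknown config key: ", here, call. = FALSE)
    if (is.list(ref[[nm]]) && !is.list(cfg[[nm]]) && !is.null(ref[[nm]]$.)) {
      stop("config key ", here, " must be an object", call. = FALSE)
    }
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]]))
        stop("config key ", here, " must be an object", call. = FALSE)
      .check_config(cfg[[nm]], ref[[nm]], here)
    } else if (!is.null(cfg[[nm]]) && !is.null(ref[[nm]])) {
      if (!is.numeric(cfg[[nm]]) && is.numeric(ref[[nm]]))
        stop("config key ", here, " must be numeric", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.null(over[[nm]])) next  # JSON null: keep the default
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(over[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

.validate_config <- function(cfg) {
  pos <- function(val, key) {
    if (!is.numeric(val) || any(!is.finite(val)) || any(val <= 0))
      stop("config constraint violated: ", key,
           " must be finite and > 0", call. = FALSE)
  }
  for (k in names(cfg$beam)) pos(cfg$beam[[k]], paste0("beam.", k))
  pos(cfg$dose_grid, "dose_grid")
  for (k in c("field_sizes", "pullbacks", "air_gaps", "spot_spacing",
              "margin"))
    pos(cfg$sweep[[k]], paste0("sweep.", k))
  for (k in c("rx", "gtv_diameter", "air_gap"))
    pos(cfg$head[[k]], paste0("head.", k))
  if (any(cfg$head$thresholds < 0))
    stop("config constraint violated: head.thresholds must be >= 0",
         call. = FALSE)
  if (cfg$seed != round(cfg$seed))
    stop("config constraint violated: seed must be an integer",
         call. = FALSE)
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, rejects unknown keys, validates constraints
#' (all physics/machine scalars finite and positive, integer seed) and fills
#' unspecified values from [default_config()]. An empty JSON object yields
#' the full default configuration.
#'
#' @param path JSON file
#' @return validated RunConfig list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(user)) stop("config must be a JSON object", call. = FALSE)
  ref <- default_config()
  .check_config(user, ref)
  .validate_config(.merge_config(ref, user))
}

#' Save a configuration
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))` is
#' identity.
#'
#' @param cfg a RunConfig
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Beam model from a configuration
#' @param cfg a RunConfig
#' @return a [beam_model()]
#' @export
beam_from_config <- function(cfg) {
  do.call(beam_model, cfg$beam)
}

# ---------------------------------------------------------------------------
# Output writing
# ---------------------------------------------------------------------------

#' Wrap an array as a writable volume
#' @param data 3-D array
#' @param spacing voxel spacing, mm (length 3 or scalar)
#' @return object of class `volume`
#' @export
volume <- function(data, spacing) {
  structure(list(data = data, spacing = rep_len(spacing, 3)),
            class = "volume")
}

#' Write run outputs with a manifest
#'
#' Writes each element of `results` according to its type: data.frames as
#' CSV, [volume()] objects as MHD + raw, everything else as JSON. A
#' `manifest.json` records the config hash, seed, package version, and an
#' MD5 checksum for every emitted file. On any write failure all files
#' created by this call are removed and an error is raised.
#'
#' @param results named list
#' @param out_dir output directory (created if missing)
#' @param config the RunConfig that produced the results (hashed into the
#'   manifest)
#' @param formats which kinds to emit (subset of `"csv"`, `"json"`, `"mhd"`)
#' @return manifest list, invisibly
#' @export
write_outputs <- function(results, out_dir, config = default_config(),
                          formats = c("csv", "json", "mhd")) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a fully named list", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path, fun) {
    fun(path)
    written <<- c(written, path)
  }
  res <- tryCatch({
    for (nm in names(results)) {
      obj <- results[[nm]]
      if (is.data.frame(obj)) {
        if (!"csv" %in% formats) next
        emit(file.path(out_dir, paste0(nm, ".csv")), function(p)
          utils::write.csv(obj, p, row.names = FALSE, quote = FALSE,
                           fileEncoding = "UTF-8"))
      } else if (inherits(obj, "volume")) {
        if (!"mhd" %in% formats) next
        p <- file.path(out_dir, paste0(nm, ".mhd"))
        write_mhd(obj$data, p, spacing = obj$spacing)
        written <- c(written, p, sub("\\.mhd$", ".raw", p))
      } else {
        if (!"json" %in% formats) next
        emit(file.path(out_dir, paste0(nm, ".json")), function(p)
          jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                               null = "null", pretty = TRUE))
      }
    }
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    cfg_file <- tempfile()
    writeLines(cfg_json, cfg_file)
    manifest <- list(
      config_md5 = unname(tools::md5sum(cfg_file)),
      seed = config$seed,
      package = "flashbp",
      version = as.character(utils::packageVersion("flashbp")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      files = lapply(sort(written), function(f)
        list(name = basename(f), md5 = unname(tools::md5sum(f)),
             bytes = file.size(f)))
    )
    unlink(cfg_file)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    unlink(written)
    stop("write_outputs failed (partial files removed): ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
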