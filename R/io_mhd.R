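# ---------------------------------------------------------------------------
# MHD raster I/O: text header (.mhd) + little-endian 32-bit float raw payload.
# ---------------------------------------------------------------------------

#' Write a 3-D array as an MHD volume
#'
#' Writes `path.mhd` (text header) and `path.raw` (little-endian float32,
#' x fastest). Logical arrays are stored as 0/1.
#'
#' @param volume 3-D numeric or logical array
#' @param path output path without extension (or ending in `.mhd`)
#' @param origin mm triplet
#' @param spacing mm triplet
#' @return invisibly, the header path
#' @export
write_mhd <- function(volume, path, origin = c(0, 0, 0),
                      spacing = c(1, 1, 1)) {
  if (length(dim(volume)) != 3) stop("volume must be 3-D", call. = FALSE)
  path <- sub("\\.mhd$", "", path)
  raw_name <- paste0(basename(path), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("Offset = %s", paste(format(origin, trim = TRUE), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(spacing, trim = TRUE), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(volume), collapse = " ")),
    "ElementType = MET_FLOAT",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, paste0(path, ".mhd"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume), con, size = 4, endian = "little")
  invisible(paste0(path, ".mhd"))
}

#' Read an MHD volume
#'
#' @param path path to the `.mhd` header
#' @return list with `volume` (3-D array), `origin`, `spacing`
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (!length(ln)) stop("missing MHD key: ", key, call. = FALSE)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  if (get("ElementType") != "MET_FLOAT")
    stop("only MET_FLOAT payloads are supported", call. = FALSE)
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = prod(dims), size = 4, endian = "little")
  list(volume = array(v, dim = dims), origin = origin, spacing = spacing)
}

#' Write a phantom (rsp + structures) as MHD volumes with a JSON sidecar
#'
#' @param phantom a [voxel_phantom()]
#' @param dir output directory (created if needed)
#' @return invisibly, the sidecar path
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mhd(phantom$rsp, file.path(dir, "rsp"),
            origin = phantom$origin, spacing = phantom$spacing)
  for (nm in names(phantom$structures))
    write_mhd(phantom$structures[[nm]], file.path(dir, paste0("mask_", nm)),
              origin = phantom$origin, spacing = phantom$spacing)
  sidecar <- list(origin = phantom$origin, spacing = phantom$spacing,
                  dim = dim(phantom$rsp),
                  structures = as.list(names(phantom$structures)))
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(file.path(dir, "phantom.json"))
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir directory containing `phantom.json`
#' @return a [voxel_phantom()]
#' @export
read_phantom <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "phantom.json"),
                            simplifyVector = TRUE)
  rsp <- read_mhd(file.path(dir, "rsp.mhd"))
  structures <- list()
  for (nm in sc$structures)
    structures[[nm]] <-
      read_mhd(file.path(dir, paste0("mask_", nm, ".mhd")))$volume > 0.5
  voxel_phantom(rsp$volume, origin = rsp$origin, spacing = rsp$spacing,
                structures = structures)
}
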