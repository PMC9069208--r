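#' Voxel volume with spacing, origin and a value semantic
#'
#' Light-weight container for 3-D image data: a numeric array in (x, y, z)
#' order, voxel spacing in mm, the world coordinate of the first voxel
#' *center* in mm, and a declared semantic for the voxel values.
#'
#' @param values 3-D numeric array (x, y, z).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) center.
#' @param semantic one of `"HU"`, `"ED"`, `"EAN"`, `"SPR"`,
#'   `"MASS_DENSITY"`, `"DOSE_GY"`, `"LABEL"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0), semantic) {
  semantics <- c("HU", "ED", "EAN", "SPR", "MASS_DENSITY", "DOSE_GY", "LABEL")
  semantic <- match.arg(semantic, semantics)
  if (length(dim(values)) != 3)
    stop("values must be a 3-D array, got ",
         length(dim(values)) %||% 1, " dimension(s)")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  if (length(origin) != 3) stop("origin must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin,
                 semantic = semantic),
            class = "ct_volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("<ct_volume> ", x$semantic, " ", paste(d, collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "),
      " mm\n  origin (", paste(format(x$origin), collapse = ", "),
      ") mm; value range [", format(min(x$values, na.rm = TRUE)), ", ",
      format(max(x$values, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

# world coordinates of voxel centers along each axis
axis_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = c("first", "second")) {
  if (!same_grid(a, b))
    stop("volume grids do not match:\n  first:  dim ",
         paste(dim(a$values), collapse = "x"), ", spacing ",
         paste(a$spacing, collapse = "/"), ", origin ",
         paste(a$origin, collapse = "/"), "\n  second: dim ",
         paste(dim(b$values), collapse = "x"), ", spacing ",
         paste(b$spacing, collapse = "/"), ", origin ",
         paste(b$origin, collapse = "/"))
  invisible(TRUE)
}

#' Write a volume to NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is written through the RNifti library; MetaImage
#' (`.mha`, `.mhd`) through a built-in writer following the public MetaIO
#' layout (ASCII header, raw little-endian data; `.mha` single-file, `.mhd`
#' with a companion `.raw`). The value semantic is stored in a JSON sidecar
#' (`<path>.json`) for both formats.
#'
#' @param vol a [ct_volume()].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  ext <- volume_ext(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol$values)
    img <- RNifti::`pixdim<-`(img, vol$spacing)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(vol, path, ext)
  } else {
    stop("unknown volume extension '", ext,
         "'; supported: .nii, .nii.gz, .mha, .mhd")
  }
  jsonlite::write_json(
    list(semantic = vol$semantic, origin = vol$origin,
         spacing = vol$spacing),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param semantic override for the value semantic if no sidecar is present.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, semantic = NULL) {
  ext <- volume_ext(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else NULL
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim = dim(img))
    if (length(dim(vals)) == 2)
      stop("expected a 3-D volume, got a 2-D image")
    if (length(dim(vals)) != 3) stop("expected a 3-D volume")
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- meta$origin %||% c(0, 0, 0)
  } else if (ext %in% c("mha", "mhd")) {
    mi <- read_metaimage(path)
    vals <- mi$values; spacing <- mi$spacing
    origin <- meta$origin %||% mi$origin
  } else {
    stop("unknown volume extension '", ext,
         "'; supported: .nii, .nii.gz, .mha, .mhd")
  }
  sem <- semantic %||% meta$semantic %||%
    stop("no semantic sidecar found for '", path,
         "'; pass `semantic` explicitly")
  ct_volume(vals, spacing = meta$spacing %||% spacing, origin = origin,
            semantic = sem)
}

volume_ext <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

write_metaimage <- function(vol, path, ext) {
  d <- dim(vol$values)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(vol$origin, collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE")
  if (ext == "mha") {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(vol$values), con, size = 8, endian = "little")
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path))
    hdr <- c(hdr, paste("ElementDataFile =", raw_name))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.vector(vol$values), con, size = 8, endian = "little")
  }
}

read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the newline after the ElementDataFile line
  nl <- which(bytes == as.raw(10))
  hdr_end <- NA
  for (p in nl) {
    txt <- rawToChar(bytes[seq_len(p - 1)])
    if (grepl("ElementDataFile", txt)) { hdr_end <- p; break }
  }
  if (is.na(hdr_end)) stop("truncated MetaImage header in '", path, "'")
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1)]), "\r?\n")[[1]]
  get <- function(key) {
    hit <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", hit[[1]]))
  }
  if (!identical(get("NDims"), "3"))
    stop("expected a 3-D volume, got NDims = ", get("NDims") %||% "?")
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing") %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset") %||% "0 0 0", "\\s+")[[1]])
  etype <- get("ElementType")
  size <- switch(etype, MET_DOUBLE = 8, MET_FLOAT = 4,
                 stop("unsupported ElementType ", etype))
  datafile <- get("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    vals <- readBin(bytes[(hdr_end + 1):length(bytes)], "numeric",
                    n = prod(d), size = size, endian = "little")
  } else {
    vals <- readBin(file.path(dirname(path), datafile), "numeric",
                    n = prod(d), size = size, endian = "little")
  }
  list(values = array(vals, dim = d), spacing = spacing, origin = origin)
}
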