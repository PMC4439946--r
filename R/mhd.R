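#' Write a volume as MetaImage (.mhd header + .raw payload)
#'
#' Densities and dose grids are written as 32-bit little-endian floats,
#' boolean masks as 8-bit unsigned integers. The `.raw` file is written next
#' to the header with the same basename.
#'
#' @param vol a `density_volume`, `dose_grid`, or 3D array (logical arrays
#'   are written as MET_UCHAR).
#' @param path output path ending in `.mhd`.
#' @param spacing,origin geometry, required when `vol` is a bare array.
#' @return invisibly, the header path.
#' @export
write_mhd <- function(vol, path, spacing = NULL, origin = NULL) {
  if (inherits(vol, c("density_volume", "dose_grid"))) {
    data <- vol$data; spacing <- vol$spacing; origin <- vol$origin
  } else {
    data <- vol
    if (is.null(spacing) || is.null(origin)) {
      stop("`spacing` and `origin` are required for bare arrays")
    }
  }
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  is_mask <- is.logical(data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementSpacing =", paste(spacing, collapse = " ")),
    paste("Offset =", paste(origin, collapse = " ")),
    paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_FLOAT"),
    paste("ElementDataFile =", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (is_mask) {
    writeBin(as.integer(data), con, size = 1L)
  } else {
    writeBin(as.numeric(data), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage volume written by [write_mhd()]
#'
#' Supports 3D MET_FLOAT, MET_DOUBLE, MET_UCHAR and MET_SHORT payloads with
#' little-endian byte order.
#'
#' @param path path to the `.mhd` header.
#' @param as one of `"density"`, `"dose"`, `"array"`: container for the
#'   result (MET_UCHAR always returns a logical array).
#' @return a `density_volume`, `dose_grid`, or array with attributes
#'   `spacing` and `origin`.
#' @export
read_mhd <- function(path, as = c("density", "dose", "array")) {
  as <- match.arg(as)
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k) vals[match(k, keys)]
  if (!is.na(get("BinaryDataByteOrderMSB")) &&
      toupper(get("BinaryDataByteOrderMSB")) == "TRUE") {
    stop("big-endian MetaImage payloads are not supported")
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  etype <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  data <- switch(etype,
    MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1L, signed = FALSE),
    MET_SHORT = readBin(con, "integer", n, size = 2L, endian = "little"),
    stop("unsupported ElementType: ", etype)
  )
  arr <- array(data, dim = dims)
  if (etype == "MET_UCHAR") {
    arr <- arr > 0
    attr(arr, "spacing") <- spacing
    attr(arr, "origin") <- origin
    return(arr)
  }
  switch(as,
    density = density_volume(arr, spacing, origin),
    dose = dose_grid(arr, spacing, origin),
    array = {
      attr(arr, "spacing") <- spacing
      attr(arr, "origin") <- origin
      arr
    }
  )
}
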