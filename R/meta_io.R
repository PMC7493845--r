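# Minimal MetaImage (.mha/.mhd) reader/writer: uncompressed raster data,
# scalar element types, 3D only. No installed R package reads MetaImage, so
# the dialect subset used by common toolkits is implemented here directly.

.meta_types <- list(
  MET_DOUBLE = list(what = "double", size = 8, signed = TRUE),
  MET_FLOAT  = list(what = "double", size = 4, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2, signed = TRUE)
)

read_meta_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed MetaImage header in '", path, "'")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: '", line, "'")
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") { data_file <- kv[3]; break }
  }
  if (!identical(hdr$ObjectType, "Image"))
    stop("'", path, "' is not a MetaImage image file")
  ndims <- as.integer(hdr$NDims)
  if (!identical(ndims, 3L))
    stop("expected a 3D volume, '", path, "' has ", ndims, " dims")
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage data is not supported: ", path)
  dimsize <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])  # (x, y, z)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  offset <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tinfo <- .meta_types[[hdr$ElementType %||% "MET_DOUBLE"]]
  if (is.null(tinfo)) stop("unsupported MetaImage ElementType: ", hdr$ElementType)
  big <- identical(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE")
  n <- prod(dimsize)
  if (identical(data_file, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = if (big) "big" else "little")
  if (length(vals) != n) stop("truncated MetaImage data in '", path, "'")
  arr <- array(as.double(vals), dim = dimsize)      # (x, y, z), x fastest
  as_volume(aperm(arr, c(3, 2, 1)), spacing = rev(spacing), origin = rev(offset))
}

write_meta_volume <- function(volume, path) {
  d <- dim(volume$data)                              # (z, y, x)
  mhd <- grepl("\\.mhd$", tolower(path))
  data_file <- if (mhd) paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
               else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(rev(volume$origin), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(rev(volume$spacing), collapse = " ")),
    paste("DimSize =", paste(rev(d), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", data_file)
  )
  payload <- as.vector(aperm(volume$data, c(3, 2, 1)))  # x fastest on disk
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (mhd) {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(payload, rcon, size = 8, endian = "little")
  } else {
    writeBin(payload, con, size = 8, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
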