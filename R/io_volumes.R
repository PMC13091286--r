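#' Read a dose grid or structure mask from a volume file
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and uncompressed MetaImage
#' (`.mha` with embedded data, or `.mhd` + `.raw` pair). Spacing is taken
#' from the header; the origin is the translation column of the stored
#' affine (NIfTI) or the `Offset` header field (MetaImage). For
#' `kind = "mask"` the member voxels are exactly the nonzero voxels of the
#' file.
#'
#' @param path file to read.
#' @param kind `"dose"` or `"mask"`.
#' @param name structure label attached to a mask.
#' @return a [dose_grid()] or [struct_mask()].
#' @export
read_volume <- function(path, kind = c("dose", "mask"), name = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim = dim(img))
    spacing <- RNifti::pixdim(img)[1:3]
    aff <- try(RNifti::xform(img), silent = TRUE)
    origin <- if (inherits(aff, "try-error")) c(0, 0, 0) else as.numeric(aff[1:3, 4])
  } else if (ext %in% c(".mha", ".mhd")) {
    v <- read_metaimage(path)
    vals <- v$values; spacing <- v$spacing; origin <- v$origin
  } else {
    stop(sprintf("unsupported volume format '%s' (use .nii/.nii.gz/.mha/.mhd)", ext))
  }
  if (kind == "dose") {
    nbad <- sum(!is.finite(vals) | vals < 0)
    if (nbad > 0L)
      stop(sprintf("'%s' contains %d negative or non-finite dose voxel(s)",
                   path, nbad))
    dose_grid(vals, spacing, origin)
  } else {
    struct_mask(vals != 0, spacing, origin,
                name = if (is.null(name)) sub("\\.(nii(\\.gz)?|mha|mhd)$", "",
                                              basename(path)) else name,
                allow_empty = TRUE)
  }
}

#' Write a dose grid or structure mask to a volume file
#'
#' Doses are written as float64 NIfTI (or `MET_DOUBLE` MetaImage); masks as
#' 8-bit 0/1.
#'
#' @param x a `dose_grid` or `struct_mask`.
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "struct_mask")
  vals <- if (is_mask) array(as.integer(x$membership), dim = x$shape) else x$values
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- x$spacing
    aff <- diag(c(x$spacing, 1))
    aff[1:3, 4] <- x$origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "double")
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(vals, x$spacing, x$origin, path,
                    type = if (is_mask) "MET_UCHAR" else "MET_DOUBLE")
  } else {
    stop(sprintf("unsupported volume format '%s'", ext))
  }
  invisible(path)
}

# Minimal uncompressed MetaImage IO. Only the fields this package writes are
# required on read; data are little-endian, Fortran (x-fastest) order, which
# matches R array layout.
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # byte-at-a-time line reader: keeps the connection positioned at the first
  # data byte after the header (readLines would read ahead)
  read_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) return(NULL)
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  hdr <- list()
  repeat {
    line <- read_line()
    if (is.null(line)) stop("MetaImage header ended before ElementDataFile")
    kv <- strsplit(line, "\\s*=\\s*")[[1]]
    if (length(kv) != 2L) stop(sprintf("bad MetaImage header line: '%s'", line))
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(dims))
  type <- hdr$ElementType
  sz <- switch(type, MET_UCHAR = 1L, MET_SHORT = 2L, MET_FLOAT = 4L,
               MET_DOUBLE = 8L, stop(sprintf("unsupported ElementType %s", type)))
  n <- prod(dims)
  raw_con <- con
  if (hdr$ElementDataFile != "LOCAL") {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop(sprintf("missing raw file '%s'", raw_path))
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- if (sz <= 2L)
    readBin(raw_con, "integer", n = n, size = sz, signed = sz > 1L,
            endian = "little")
  else
    readBin(raw_con, "double", n = n, size = sz, endian = "little")
  list(values = array(as.numeric(vals), dim = dims),
       spacing = spacing, origin = origin)
}

write_metaimage <- function(vals, spacing, origin, path, type = "MET_DOUBLE") {
  ext <- tolower(sub("^.*(\\.[a-z]+)$", "\\1", path))
  local <- ext == ".mha"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("ElementSpacing = %s", paste(format(spacing), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(vals), collapse = " ")),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s",
            if (local) "LOCAL" else paste0(basename(sub("\\.mhd$", "", path)), ".raw"))
  )
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (local) {
    write_meta_data(vals, con, type)
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), paste0(basename(sub("\\.mhd$", "", path)), ".raw")), "wb")
    write_meta_data(vals, rcon, type)
    close(rcon)
  }
  invisible(path)
}

write_meta_data <- function(vals, con, type) {
  if (type == "MET_UCHAR")
    writeBin(as.integer(vals), con, size = 1L, endian = "little")
  else
    writeBin(as.double(vals), con, size = 8L, endian = "little")
}
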