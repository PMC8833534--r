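#' Read a binary structure mask from NIfTI or NRRD
#'
#' Supports single-label binary volumes in NIfTI (`.nii`, `.nii.gz`,
#' via RNifti) or NRRD (`.nrrd`; raw, gzip or ascii encodings with
#' diagonal space directions).  Any nonzero voxel is treated as
#' inside the structure.  Spacing and origin are taken from the file
#' header.
#'
#' @param path file path.
#' @return List with `mask` (3-D logical array) and `grid`
#'   ([VoxelGrid-class]).
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE))
    return(.readNrrd(path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    return(.readNiftiMask(path))
  stop("unsupported mask format (need .nii, .nii.gz or .nrrd): ", path)
}

.readNiftiMask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume in ", path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(as.numeric(pd[1:3]))
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf) && all(dim(xf) == c(4, 4)))
    as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  list(mask = array(arr != 0, dim = dim(arr)),
       grid = voxelGrid(dim(arr), spacing = spacing, origin = origin))
}

#' Write a binary mask to NIfTI or NRRD
#'
#' @param mask 3-D logical array.
#' @param grid the [VoxelGrid-class] supplying spacing and origin.
#' @param path output path; format chosen by extension (`.nii`,
#'   `.nii.gz` or `.nrrd`).
#' @param nrrd_encoding `"gzip"` (default) or `"raw"` for NRRD
#'   output.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, grid, path, nrrd_encoding = c("gzip", "raw")) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!identical(dim(mask), grid@shape))
    stop("mask shape does not match grid")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    .writeNrrd(mask, grid, path, match.arg(nrrd_encoding))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
    RNifti::pixdim(img) <- grid@spacing
    RNifti::writeNifti(img, path)
  } else stop("unsupported mask format: ", path)
  invisible(path)
}

# Minimal NRRD support: the header subset emitted by common medical
# imaging tools for label maps (3-D, raw/gzip/ascii attached data,
# diagonal space directions or explicit spacings).
.readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3-D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  n <- prod(dims)
  rtype <- switch(type,
    "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" =
      list(what = "integer", size = 1L, signed = FALSE),
    "char" = , "signed char" = , "int8" = , "int8_t" =
      list(what = "integer", size = 1L, signed = TRUE),
    "short" = , "signed short" = , "int16" = , "int16_t" =
      list(what = "integer", size = 2L, signed = TRUE),
    "unsigned short" = , "ushort" = , "uint16" = , "uint16_t" =
      list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "signed int" = , "int32" = , "int32_t" =
      list(what = "integer", size = 4L, signed = TRUE),
    "float" = list(what = "numeric", size = 4L, signed = TRUE),
    "double" = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported NRRD type: ", type))
  endian <- if (!is.null(fields[["endian"]]) &&
                fields[["endian"]] == "big") "big" else "little"
  if (enc %in% c("raw", "gzip", "gz")) {
    payload <- readBin(con, "raw", n = 1e9)
    if (enc != "raw") payload <- memDecompress(payload, type = "gzip")
    vals <- readBin(payload, rtype$what, n = n, size = rtype$size,
                    signed = rtype$signed, endian = endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data in ", path)

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    if (length(vecs) == 3L)
      spacing <- vapply(vecs, function(v) {
        x <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(x^2))
      }, numeric(1))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]),
                                  ",")[[1]])
  list(mask = array(vals != 0, dim = dims),
       grid = voxelGrid(dims, spacing = abs(as.numeric(spacing)),
                        origin = origin))
}

.writeNrrd <- function(mask, grid, path, encoding) {
  hdr <- c("NRRD0004",
           "# binary structure mask",
           "type: unsigned char",
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(grid@shape, collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                          grid@spacing[1], grid@spacing[2],
                          grid@spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", if (encoding == "gzip") "gzip" else "raw"),
           paste0("space origin: ",
                  sprintf("(%g,%g,%g)", grid@origin[1], grid@origin[2],
                          grid@origin[3])))
  payload <- writeBin(as.integer(as.vector(mask)), raw(), size = 1L)
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  writeBin(payload, con)
}

#' Read a patient's StructureSet from a mask manifest
#'
#' The manifest (YAML or JSON) maps structure names to mask files and
#' lists anatomically absent OARs:
#' \preformatted{
#' patient_id: P001
#' structures:
#'   PTV_7000: ptv70.nii.gz
#'   PTV_5425: ptv54.nii.gz
#'   parotid_left: parotid_l.nrrd
#' absent: [submandibular_left]
#' }
#' Relative paths are resolved against the manifest's directory.  All
#' masks must agree on shape and spacing (resampling is out of
#' scope).
#'
#' @param manifest_path path to the YAML/JSON manifest.
#' @return A [StructureSet-class]; the `patient_id` (if present) is
#'   attached as attribute `patient_id`.
#' @export
readStructureSet <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- if (grepl("\\.json$", manifest_path, ignore.case = TRUE))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else yaml::read_yaml(manifest_path)
  if (is.null(man$structures) || !length(man$structures))
    stop("manifest lists no structures")
  base <- dirname(manifest_path)
  masks <- list()
  grid <- NULL
  for (nm in names(man$structures)) {
    p <- man$structures[[nm]]
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    got <- readMask(p)
    if (is.null(grid)) {
      grid <- got$grid
    } else {
      if (!identical(got$grid@shape, grid@shape))
        stop("mask '", nm, "' is on a different grid shape; ",
             "masks must be pre-resampled to a shared grid")
      if (max(abs(got$grid@spacing - grid@spacing)) > 1e-6)
        stop("mask '", nm, "' has different voxel spacing")
    }
    masks[[nm]] <- got$mask
  }
  ss <- structureSet(grid, masks,
                     absent = as.character(unlist(man$absent)))
  attr(ss, "patient_id") <- man$patient_id
  ss
}
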