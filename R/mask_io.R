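#' Structure set: co-registered binary masks on a shared voxel grid
#'
#' Container for a tumor mask, up to five named vessel masks and optional
#' pancreas/intensity volumes, all sharing shape, spacing and origin.  All
#' geometric computation in the package assumes the grid has been made
#' isotropic (see [resample_isotropic()]); the `isotropic` attribute records
#' this.
#'
#' @param tumor logical 3D array (tumor mask), must contain at least 1 voxel.
#' @param vessels named list of logical 3D arrays; names must come from
#'   [VESSEL_NAMES].
#' @param pancreas optional logical 3D array.
#' @param intensity optional numeric 3D array on the same grid.
#' @param spacing voxel size in mm per axis (length 3).
#' @param origin physical position of the first voxel in mm (length 3).
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(tumor, vessels = list(), pancreas = NULL,
                          intensity = NULL, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  stopifnot(length(dim(tumor)) == 3, is.logical(tumor))
  if (!any(tumor)) stop("tumor mask is empty")
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (length(vessels)) {
    if (is.null(names(vessels)) || !all(names(vessels) %in% VESSEL_NAMES))
      stop("vessel names must come from: ", paste(VESSEL_NAMES, collapse = ", "))
    for (v in vessels) {
      stopifnot(is.logical(v))
      if (!identical(dim(v), dim(tumor))) stop("vessel grid mismatch")
    }
  }
  for (extra in list(pancreas, intensity)) {
    if (!is.null(extra) && !identical(dim(extra), dim(tumor)))
      stop("member volume grid mismatch")
  }
  s <- list(tumor = tumor, vessels = vessels, pancreas = pancreas,
            intensity = intensity, spacing = as.numeric(spacing),
            origin = as.numeric(origin))
  class(s) <- "structure_set"
  attr(s, "isotropic") <- isTRUE(max(abs(diff(spacing))) < 1e-9)
  s
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set:", paste(dim(x$tumor), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  tumor:", sum(x$tumor), "voxels\n")
  for (nm in names(x$vessels))
    cat("  vessel", nm, ":", sum(x$vessels[[nm]]), "voxels\n")
  if (!is.null(x$pancreas)) cat("  pancreas:", sum(x$pancreas), "voxels\n")
  if (!is.null(x$intensity)) cat("  intensity volume present\n")
  invisible(x)
}

is_isotropic <- function(s) isTRUE(attr(s, "isotropic"))

#' Read a label volume into a structure set
#'
#' Reads a NIfTI (`.nii`/`.nii.gz`) or NRRD (`.nrrd`) integer label volume and
#' splits it into named binary masks according to `label_map`.
#'
#' @param path path to the label volume.
#' @param label_map named integer vector or list mapping structure names
#'   (`tumor`, `pancreas`, and vessel names from [VESSEL_NAMES]) to label
#'   codes, or a path to a JSON file with that mapping.
#' @param optional character vector of structure names that may be absent from
#'   the file; absent optional structures are recorded in the
#'   `missing_structures` attribute instead of raising an error.
#' @param intensity_path optional path to a scalar volume on the same grid.
#' @return a [structure_set()].
#' @export
read_label_volume <- function(path, label_map, optional = character(),
                              intensity_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(label_map) && length(label_map) == 1)
    label_map <- read_label_map(label_map)
  label_map <- unlist(label_map)
  if (is.null(names(label_map)) || !"tumor" %in% names(label_map))
    stop("label_map must be named and include 'tumor'")
  vol <- read_volume(path)
  voxels <- vol$voxels
  present <- unique(as.integer(voxels))
  masks <- list()
  missing <- character()
  for (nm in names(label_map)) {
    code <- as.integer(label_map[[nm]])
    if (!code %in% present) {
      if (nm %in% optional) { missing <- c(missing, nm); next }
      stop("label code ", code, " for structure '", nm,
           "' absent from ", path)
    }
    masks[[nm]] <- array(voxels == code, dim(voxels))
  }
  intensity <- NULL
  if (!is.null(intensity_path)) {
    iv <- read_volume(intensity_path)
    if (!identical(dim(iv$voxels), dim(voxels))) stop("intensity grid mismatch")
    intensity <- iv$voxels
  }
  s <- structure_set(
    tumor = masks$tumor,
    vessels = masks[intersect(names(masks), VESSEL_NAMES)],
    pancreas = masks$pancreas,
    intensity = intensity,
    spacing = vol$spacing, origin = vol$origin)
  attr(s, "missing_structures") <- missing
  s
}

#' Read a label map from JSON
#' @param path JSON file mapping structure names to integer label codes.
#' @return named integer vector.
#' @export
read_label_map <- function(path) {
  m <- jsonlite::read_json(path)
  unlist(m)
}

# Dispatch on file extension; returns list(voxels, spacing, origin).
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- attr(img, "pixdim")
    if (is.null(sp)) sp <- RNifti::pixdim(img)
    hdr <- RNifti::niftiHeader(img)
    org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    list(voxels = array(as.vector(img), dim(img)),
         spacing = abs(as.numeric(sp[1:3])), origin = as.numeric(org))
  } else if (grepl("\\.nrrd$", path)) {
    read_nrrd(path)
  } else {
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz or .nrrd)")
  }
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param voxels 3D numeric/integer/logical array.
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param spacing voxel size (mm) per axis.
#' @param origin physical origin (mm).
#' @return `path`, invisibly.
#' @export
write_volume <- function(voxels, path, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3)
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(voxels)
    RNifti::pixdim(img) <- spacing
    hdr <- list(qoffset_x = origin[1], qoffset_y = origin[2],
                qoffset_z = origin[3])
    img <- RNifti::asNifti(img, hdr)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path)) {
    write_nrrd(voxels, path, spacing, origin)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

# --- Minimal NRRD support (raw / gzip encodings, 3D, little endian) --------

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw_all == as.raw(10))
  hdr_end <- NA
  for (i in seq_along(nl)[-1]) {
    if (nl[i] == nl[i - 1] + 1) { hdr_end <- nl[i]; break }
    # allow \r\n line endings
    if (nl[i] == nl[i - 1] + 2 && raw_all[nl[i] - 1] == as.raw(13)) {
      hdr_end <- nl[i]; break
    }
  }
  if (is.na(hdr_end)) stop("malformed NRRD header: ", path)
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\r?\n")[[1]]
  fields <- list()
  for (ln in hdr_lines[-1]) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr(": *", ln), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  if (is.null(fields$sizes)) stop("NRRD missing sizes field")
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  type <- tolower(fields$type %||% "int")
  enc <- tolower(fields$encoding %||% "raw")
  data <- raw_all[(hdr_end + 1):length(raw_all)]
  if (enc %in% c("gzip", "gz")) data <- memDecompress(data, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  rtype <- switch(type,
    "unsigned char" = , "uchar" = , "uint8" = list("integer", 1L, FALSE),
    "short" = , "int16" = list("integer", 2L, TRUE),
    "unsigned short" = , "uint16" = list("integer", 2L, FALSE),
    "int" = , "int32" = , "signed int" = list("integer", 4L, TRUE),
    "float" = list("numeric", 4L, TRUE),
    "double" = list("numeric", 8L, TRUE),
    stop("unsupported NRRD type: ", type))
  vals <- readBin(data, rtype[[1]], n = prod(sizes), size = rtype[[2]],
                  signed = rtype[[3]], endian = "little")
  spacing <- c(1, 1, 1)
  if (!is.null(fields$`space directions`)) {
    vecs <- regmatches(fields$`space directions`,
                       gregexpr("\\(([^)]*)\\)", fields$`space directions`))[[1]]
    if (length(vecs) == 3) {
      spacing <- vapply(vecs, function(v) {
        xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(xyz^2))
      }, numeric(1), USE.NAMES = FALSE)
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, " +")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`)) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields$`space origin`), ",")[[1]])
  }
  list(voxels = array(vals, sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(voxels, path, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  con <- file(path, "wb")
  on.exit(close(con))
  is_int <- is.integer(voxels) || all(voxels == round(voxels))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", if (is_int) "int" else "double"),
    "dimension: 3",
    paste0("sizes: ", paste(dim(voxels), collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space: left-posterior-superior",
    paste0("space directions: ",
           sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                   spacing[1], spacing[2], spacing[3])),
    paste0("space origin: ",
           sprintf("(%g,%g,%g)", origin[1], origin[2], origin[3])),
    "")
  writeLines(hdr, con, sep = "\n")
  if (is_int) {
    writeBin(as.integer(voxels), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(voxels), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a structure set to an isotropic grid
#'
#' Nearest-neighbour resampling of every member volume to cubic voxels of side
#' `target` mm.  Labels are categorical, so no interpolation is performed and
#' no new labels can appear.
#'
#' @param s a [structure_set()].
#' @param target isotropic voxel size in mm (default 1, so voxel units and mm
#'   coincide downstream).
#' @return a [structure_set()] with `isotropic = TRUE`.
#' @export
resample_isotropic <- function(s, target = 1) {
  stopifnot(inherits(s, "structure_set"))
  if (target <= 0) stop("target spacing must be positive")
  sp <- s$spacing
  if (max(abs(sp - target)) < 1e-9) {
    attr(s, "isotropic") <- TRUE
    return(s)
  }
  old_dim <- dim(s$tumor)
  new_dim <- pmax(1L, as.integer(round(old_dim * sp / target)))
  idx <- lapply(1:3, function(ax) {
    phys <- (seq_len(new_dim[ax]) - 0.5) * target
    pmin(old_dim[ax], pmax(1L, as.integer(round(phys / sp[ax] + 0.5))))
  })
  res <- function(v) {
    if (is.null(v)) return(NULL)
    v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out <- structure_set(
    tumor = res(s$tumor),
    vessels = lapply(s$vessels, res),
    pancreas = res(s$pancreas),
    intensity = res(s$intensity),
    spacing = rep(target, 3), origin = s$origin)
  attr(out, "isotropic") <- TRUE
  attr(out, "missing_structures") <- attr(s, "missing_structures")
  out
}

#' Write a per-case, per-vessel feature table to CSV
#'
#' Columns are ordered stably: identifier columns (`case`, `vessel`), the 14
#' anatomical features ([ANATOMICAL_FEATURES]), then any further columns in
#' alphabetical order.  Missing values are written as empty cells.
#'
#' @param rows data.frame of feature rows.
#' @param path output CSV path.
#' @return number of rows written, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  lead <- intersect(c("case", "vessel", "vessel_class"), names(rows))
  anat <- intersect(ANATOMICAL_FEATURES, names(rows))
  rest <- sort(setdiff(names(rows), c(lead, anat)))
  rows <- rows[, c(lead, anat, rest), drop = FALSE]
  ok <- tryCatch({
    write.csv(rows, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write feature table: ",
                              conditionMessage(e)))
  invisible(nrow(rows))
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with empty cells read back as `NA`.
#' @export
read_feature_table <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
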