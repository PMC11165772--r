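# Voxel volumes and a minimal NIfTI-1 codec.
#
# Axis convention throughout the package: array index i -> +X (mediolateral,
# left to right), j -> +Y (anteroposterior, front to back), k -> +Z
# (inferosuperior). `origin` is the world coordinate (mm) of the centre of
# voxel [1,1,1]; voxel centres are origin + (index-1) * spacing.

#' Construct a voxel volume
#'
#' A 3D scalar or binary grid with physical spacing and origin, the container
#' for cavity masks.
#'
#' @param data 3D array (logical or numeric).
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world coordinate (mm) of the centre of voxel `[1,1,1]`.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive mm values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite mm values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing (%g, %g, %g) mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$data != 0)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# world coordinates of all voxel centres with index in `idx` (n x 3 matrix)
voxel_to_world <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

# physical bounding box of the foreground (voxel extents, i.e. centre +- h/2)
mask_bbox <- function(vol) {
  idx <- which(vol$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  w <- voxel_to_world(vol, idx)
  h <- vol$spacing / 2
  rbind(min = apply(w, 2, min) - h, max = apply(w, 2, max) + h)
}

# 6-connected component labelling via vectorised frontier expansion.
label_components <- function(mask) {
  d <- dim(mask)
  nxy <- d[1] * d[2]
  lab <- integer(length(mask))
  fg <- which(mask != 0)
  if (length(fg) == 0L) return(array(lab, d))
  # precompute subscripts for wraparound guards
  ii <- ((fg - 1L) %% d[1]) + 1L
  jj <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  kk <- ((fg - 1L) %/% nxy) + 1L
  pos <- integer(length(mask)); pos[fg] <- seq_along(fg)  # lin idx -> fg row
  infg <- logical(length(mask)); infg[fg] <- TRUE
  comp <- 0L
  unvisited <- rep(TRUE, length(fg))
  while (any(unvisited)) {
    comp <- comp + 1L
    seed <- fg[which.max(unvisited)]
    frontier <- seed
    lab[seed] <- comp
    unvisited[pos[seed]] <- FALSE
    while (length(frontier)) {
      fi <- pos[frontier]
      cand <- c(frontier[ii[fi] < d[1]] + 1L,
                frontier[ii[fi] > 1L] - 1L,
                frontier[jj[fi] < d[2]] + d[1],
                frontier[jj[fi] > 1L] - d[1],
                frontier[kk[fi] < d[3]] + nxy,
                frontier[kk[fi] > 1L] - nxy)
      cand <- unique(cand[infg[cand] & lab[cand] == 0L])
      lab[cand] <- comp
      unvisited[pos[cand]] <- FALSE
      frontier <- cand
    }
  }
  array(lab, d)
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  list(mask = lab == which.max(sizes), sizes = sort(sizes, decreasing = TRUE))
}

# ---- NIfTI-1 I/O -------------------------------------------------------
# Minimal single-file NIfTI-1 (.nii / .nii.gz) support, diagonal affines
# only. No NIfTI package is available in the target R stack, and masks are
# simple axis-aligned grids, so this small codec is self-contained.

nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64", `256` = "int8",
                     `512` = "uint16")

#' Write a voxel volume as NIfTI-1
#'
#' Binary masks are stored as uint8; other data as float32. The affine is
#' diagonal (spacing on the diagonal, origin in the translation column) with
#' `sform_code = 1`.
#'
#' @param vol a [voxel_volume].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  is_mask <- is.logical(vol$data) || all(vol$data %in% c(0, 1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                  # sizeof_hdr
  wc(35); writeBin(as.raw(0L), con)            # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                    # intent_p*, intent_code
  wi(if (is_mask) 2L else 16L, 2)              # datatype
  wi(if (is_mask) 8L else 32L, 2)              # bitpix
  wi(0L, 2)                                    # slice_start
  wf(c(1, vol$spacing, 1, 1, 1, 1))            # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0L, 2); wc(1); writeBin(as.raw(2L), con)  # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                            # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                             # glmax, glmin
  wc(80 + 24)                                  # descrip, aux_file
  wi(c(0L, 1L), 2)                             # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                      # quatern_*, qoffset_*
  wf(c(vol$spacing[1], 0, 0, vol$origin[1]))   # srow_x
  wf(c(0, vol$spacing[2], 0, vol$origin[2]))   # srow_y
  wf(c(0, 0, vol$spacing[3], vol$origin[3]))   # srow_z
  wc(16)                                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  wc(4)                                        # extension flag
  if (is_mask) {
    writeBin(as.raw(as.integer(vol$data != 0)), con)
  } else {
    writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the datatypes this package writes plus common integer/float
#' types; requires an axis-aligned (diagonal) affine.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [voxel_volume].
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size, endian = "little")
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)],
                                 "numeric", n = n, size = 4, endian = "little")
  if (ri(0, 1, 4) != 348L) stop("not a NIfTI-1 file: ", path)
  dims <- ri(40, 8, 2)
  if (dims[1] < 3L) stop("expected a 3D volume")
  d <- dims[2:4]
  dtype <- ri(70, 1, 2)
  tname <- nifti_datatypes[as.character(dtype)]
  if (is.na(tname)) stop("unsupported NIfTI datatype code ", dtype)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  sform_code <- ri(254, 1, 2)
  if (sform_code > 0L) {
    sx <- rf(280, 4); sy <- rf(296, 4); sz <- rf(312, 4)
    offdiag <- c(sx[2:3], sy[c(1, 3)], sz[1:2])
    if (any(abs(offdiag) > 1e-5 * max(abs(c(sx, sy, sz)))))
      stop("oblique NIfTI affines are not supported")
    spacing <- abs(c(sx[1], sy[2], sz[3]))
    origin <- c(sx[4], sy[4], sz[4])
  } else {
    spacing <- abs(pixdim[2:4])
    origin <- c(0, 0, 0)
  }
  skip <- as.integer(round(vox_offset)) - 352L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- switch(tname,
    uint8   = as.integer(readBin(con, "raw", n)),
    int8    = readBin(con, "integer", n, size = 1, endian = "little"),
    int16   = readBin(con, "integer", n, size = 2, endian = "little"),
    uint16  = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    int32   = readBin(con, "integer", n, size = 4, endian = "little"),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8, endian = "little"))
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  voxel_volume(array(vals, d), spacing = spacing, origin = origin)
}
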