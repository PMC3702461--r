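#' Read a volume from NIfTI or MetaImage
#'
#' NIfTI (\code{.nii}, \code{.nii.gz}) is read through RNifti; spacing and
#' origin come from the sform when present, else from pixdim.  MetaImage
#' (\code{.mhd} with a companion \code{.raw}, or inline \code{.mha}) is read
#' by a small built-in parser since no installed R package handles the
#' format.
#'
#' @param path File path.
#' @param role Role tag for the resulting \code{\link{volume}}.
#' @return A \code{volume}.
#' @export
read_volume <- function(path, role = "ct") {
  ext <- tolower(sub("^.*?(\\.[a-zA-Z]+(\\.gz)?)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L) stopf("expected a 3D image in %s", path)
    vals <- array(as.numeric(img), dim = dim(img))
    x <- RNifti::xform(img)
    if (!is.null(attr(x, "code")) && attr(x, "code") > 0) {
      spacing <- abs(diag(x[1:3, 1:3]))
      origin <- x[1:3, 4]
    } else {
      spacing <- RNifti::pixdim(img)[1:3]
      origin <- c(0, 0, 0)
    }
    volume(vals, spacing = spacing, origin = origin, role = role)
  } else if (ext %in% c(".mhd", ".mha")) {
    read_metaimage(path, role = role)
  } else stopf("unsupported volume format: %s", path)
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param vol A \code{volume}.
#' @param path Output path; format chosen by extension (\code{.nii},
#'   \code{.nii.gz}, \code{.mhd}, \code{.mha}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(sub("^.*?(\\.[a-zA-Z]+(\\.gz)?)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    vals <- vol$values
    if (vol$role %in% c("mask", "label")) storage.mode(vals) <- "integer"
    img <- RNifti::asNifti(vals)
    m <- diag(4)
    m[1, 1] <- vol$spacing[1]; m[2, 2] <- vol$spacing[2]; m[3, 3] <- vol$spacing[3]
    m[1:3, 4] <- vol$origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (ext %in% c(".mhd", ".mha")) {
    write_metaimage(vol, path)
  } else stopf("unsupported volume format: %s", path)
  invisible(path)
}

read_metaimage <- function(path, role = "ct") {
  # parse the text header byte-wise: .mha files carry binary data after it
  raw_all <- readBin(path, "raw", file.size(path))
  nl <- which(raw_all == as.raw(10L))
  hdr <- character(); offset <- NA_integer_; start <- 1L
  for (pos in nl) {
    ln <- rawToChar(raw_all[start:(pos - 1L)])
    ln <- sub("\r$", "", ln)
    hdr <- c(hdr, ln)
    start <- pos + 1L
    if (grepl("^ElementDataFile", ln)) { offset <- pos; break }
  }
  if (is.na(offset)) stopf("no ElementDataFile key in %s", path)
  kv <- function(key, default = NULL) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub("^[^=]*= *", "", ln[1]))
  }
  dims <- as.integer(strsplit(kv("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(kv("ElementSpacing", "1 1 1"), " +")[[1]])
  origin <- as.numeric(strsplit(kv("Offset", "0 0 0"), " +")[[1]])
  etype <- kv("ElementType", "MET_DOUBLE")
  datafile <- kv("ElementDataFile")
  rtype <- switch(etype,
                  MET_DOUBLE = list(what = "double", size = 8L),
                  MET_FLOAT  = list(what = "double", size = 4L),
                  MET_INT    = list(what = "integer", size = 4L),
                  MET_SHORT  = list(what = "integer", size = 2L),
                  MET_UCHAR  = list(what = "integer", size = 1L),
                  stopf("unsupported ElementType %s", etype))
  n <- prod(dims)
  if (identical(datafile, "LOCAL")) {
    vals <- readBin(raw_all[(offset + 1L):length(raw_all)], rtype$what, n,
                    size = rtype$size, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    vals <- readBin(rawpath, rtype$what, n, size = rtype$size,
                    endian = "little")
  }
  volume(array(as.numeric(vals), dim = dims), spacing = spacing,
         origin = origin, role = role)
}

write_metaimage <- function(vol, path) {
  dims <- dim(vol$values)
  inline <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (inline) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
           paste("Offset =", paste(vol$origin, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  if (inline) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(vol$values), con, size = 8L, endian = "little")
  } else {
    writeLines(hdr, path)
    writeBin(as.numeric(vol$values),
             file.path(dirname(path), datafile), size = 8L, endian = "little")
  }
  invisible(path)
}

#' Resample a volume onto another volume's grid by trilinear interpolation
#'
#' Target voxel centres are mapped into the source grid's continuous index
#' space and interpolated trilinearly.  Points outside the source extent
#' take the padding value (air-equivalent by default: 0 for MR intensities,
#' -1000 HU for CT).  Both grids are assumed already rigidly aligned in the
#' same world frame.
#'
#' @param vol Source \code{volume}.
#' @param target \code{volume} (only its grid is used).
#' @param pad Padding value; default -1000 for role \code{"ct"}, else 0.
#' @return A \code{volume} on the target grid with the source's role.
#' @export
resample_to <- function(vol, target, pad = NULL) {
  if (is.null(pad)) pad <- if (vol$role == "ct") -1000 else 0
  sd3 <- dim(vol$values); td3 <- dim(target$values)
  # reject non-overlapping extents
  for (ax in 1:3) {
    s0 <- vol$origin[ax]; s1 <- vol$origin[ax] + sd3[ax] * vol$spacing[ax]
    t0 <- target$origin[ax]; t1 <- target$origin[ax] + td3[ax] * target$spacing[ax]
    if (t1 <= s0 || t0 >= s1)
      stopf("source and target extents do not overlap on axis %d", ax)
  }
  # continuous source index (1-based voxel-centre) of each target centre
  ci <- lapply(1:3, function(ax) {
    (axis_centers(target, ax) - vol$origin[ax]) / vol$spacing[ax] + 0.5
  })
  # pad source by one voxel each side so edge/outside lookups read 'pad'
  pv <- array(pad, dim = sd3 + 2L)
  pv[2:(sd3[1] + 1L), 2:(sd3[2] + 1L), 2:(sd3[3] + 1L)] <- vol$values
  interp1 <- function(x, n) {
    # clamp into the padded support; anything beyond one voxel outside is pad
    x <- pmin(pmax(x, 0), n + 1)
    i0 <- pmin(floor(x), n)     # lower neighbour in unpadded coords (0..n)
    list(lo = as.integer(i0) + 1L, w = x - i0)  # +1 -> padded 1-based
  }
  gx <- interp1(ci[[1]], sd3[1]); gy <- interp1(ci[[2]], sd3[2]); gz <- interp1(ci[[3]], sd3[3])
  nx <- td3[1]; ny <- td3[2]; nz <- td3[3]
  ix <- rep(gx$lo, times = ny * nz); wx <- rep(gx$w, times = ny * nz)
  iy <- rep(rep(gy$lo, each = nx), times = nz); wy <- rep(rep(gy$w, each = nx), times = nz)
  iz <- rep(gz$lo, each = nx * ny); wz <- rep(gz$w, each = nx * ny)
  pd <- dim(pv)
  lin <- function(a, b, c) a + pd[1] * ((b - 1L) + pd[2] * (c - 1L))
  v000 <- pv[lin(ix,      iy,      iz)]
  v100 <- pv[lin(ix + 1L, iy,      iz)]
  v010 <- pv[lin(ix,      iy + 1L, iz)]
  v110 <- pv[lin(ix + 1L, iy + 1L, iz)]
  v001 <- pv[lin(ix,      iy,      iz + 1L)]
  v101 <- pv[lin(ix + 1L, iy,      iz + 1L)]
  v011 <- pv[lin(ix,      iy + 1L, iz + 1L)]
  v111 <- pv[lin(ix + 1L, iy + 1L, iz + 1L)]
  out <- (1 - wz) * ((1 - wy) * ((1 - wx) * v000 + wx * v100) +
                       wy * ((1 - wx) * v010 + wx * v110)) +
         wz * ((1 - wy) * ((1 - wx) * v001 + wx * v101) +
                 wy * ((1 - wx) * v011 + wx * v111))
  volume(array(out, dim = td3), spacing = target$spacing,
         origin = target$origin, role = vol$role)
}

# --- binary morphology on 3D logical arrays (26-connected cube element) ----

shift_pad <- function(a, dx, dy, dz, pad) {
  d <- dim(a)
  out <- array(pad, dim = d)
  if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

morph3d <- function(a, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  pad <- FALSE  # outside the grid counts as background for both ops
  acc <- NULL
  offs <- seq(-radius, radius)
  for (dx in offs) for (dy in offs) for (dz in offs) {
    s <- shift_pad(a, dx, dy, dz, pad)
    acc <- if (is.null(acc)) s else if (op == "dilate") acc | s else acc & s
  }
  acc
}

#' Label connected components of a binary 3D array (6-connectivity)
#' @keywords internal
label_components <- function(a) {
  d <- dim(a)
  lab <- array(0, dim = d)
  lab[a] <- seq_len(sum(a))
  repeat {
    nb <- lab
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      sh <- shift_pad(lab, s[1], s[2], s[3], 0)
      upd <- a & sh > 0 & (nb == 0 | sh < nb)
      nb[upd] <- sh[upd]
    }
    if (all(nb == lab)) break
    lab <- nb
  }
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Build the air-exclusion mask from a CT volume
#'
#' Thresholds the CT, applies a morphological closing (dilate then erode with
#' a cubic element) to seal thin gaps, and discards connected components
#' smaller than \code{min_component} voxels.  All downstream feature
#' extraction, training and evaluation operate on voxels inside this mask.
#'
#' @param ct CT \code{volume}.
#' @param threshold HU threshold; voxels with CT > threshold are candidate
#'   tissue.  Default -800 HU.
#' @param min_component Minimum connected-component size in voxels kept
#'   (6-connectivity).  Default 27.
#' @param closing_radius Radius (voxels) of the cubic closing element;
#'   0 disables closing.  Default 1.
#' @return A mask \code{volume} (values 0/1).
#' @export
air_mask <- function(ct, threshold = -800, min_component = 27,
                     closing_radius = 1) {
  if (ct$role != "ct") stopf("air_mask expects a CT volume")
  m <- ct$values > threshold
  if (any(m) && closing_radius > 0) {
    m <- morph3d(m, closing_radius, "dilate")
    m <- morph3d(m, closing_radius, "erode")
  }
  if (any(m) && min_component > 1) {
    lab <- label_components(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_component)
      m <- array(lab %in% keep & m, dim = dim(m))
    }
  }
  volume(array(as.numeric(m), dim = dim(m)), spacing = ct$spacing,
         origin = ct$origin, role = "mask")
}

#' Inject an integer-voxel misalignment into a volume
#'
#' Shifts the contents by whole voxels, filling exposed space with a padding
#' value.  Intended for studying the sensitivity of the classifier to small
#' residual registration errors; the synthetic phantoms are otherwise
#' generated perfectly co-registered.
#'
#' @param vol A \code{volume}.
#' @param shift Integer length-3 shift in voxels.
#' @param pad Fill value; default -1000 for CT, else 0.
#' @return The shifted \code{volume}.
#' @export
misalign <- function(vol, shift, pad = NULL) {
  if (is.null(pad)) pad <- if (vol$role == "ct") -1000 else 0
  shift <- as.integer(round(shift))
  out <- vol
  out$values <- shift_pad_num(vol$values, shift[1], shift[2], shift[3], pad)
  out
}

shift_pad_num <- function(a, dx, dy, dz, pad) {
  d <- dim(a)
  out <- array(pad, dim = d)
  if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}
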