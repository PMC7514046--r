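## Scene serialization, mesh export, and a minimal NIfTI-1 writer/reader.

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Serialize a scene (segment, subject or cohort) to JSON
#'
#' Plain, documented JSON: the object tree with classes recorded in a
#' `.class` field so [read_scene_json()] can rebuild the parametric
#' objects. Serialization is byte-deterministic for a fixed object.
#'
#' @param x a `segment_model`, `subject` or `cohort`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_scene_json <- function(x, path) {
  tag <- function(o) {
    if (is.list(o)) {
      cl <- class(o)[1]
      o <- lapply(o, tag)
      if (cl != "list") o$.class <- cl
    } else if (is.matrix(o)) {
      o <- list(.matrix = as.numeric(o), .dim = dim(o),
                .rownames = rownames(o))
    }
    o
  }
  json <- jsonlite::toJSON(tag(x), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a scene serialized by [write_scene_json()]
#' @param path JSON file
#' @return the reconstructed object
#' @export
read_scene_json <- function(path) {
  untag <- function(o) {
    if (is.list(o)) {
      if (!is.null(o$.matrix)) {
        m <- matrix(unlist(o$.matrix), nrow = o$.dim[[1]])
        if (!is.null(o$.rownames)) rownames(m) <- unlist(o$.rownames)
        return(m)
      }
      cl <- o$.class
      o$.class <- NULL
      o <- lapply(o, untag)
      if (!is.null(cl)) class(o) <- cl
      return(o)
    }
    o
  }
  untag(jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE))
}

quad_faces <- function(nu, nv, closed_u = TRUE) {
  f <- NULL
  for (j in seq_len(nv - 1)) for (i in seq_len(nu)) {
    i2 <- if (i == nu) { if (closed_u) 1L else next } else i + 1L
    a <- (j - 1) * nu + i
    b <- (j - 1) * nu + i2
    cc <- j * nu + i2
    dd <- j * nu + i
    f <- rbind(f, c(a, b, cc), c(a, cc, dd))
  }
  f
}

#' Export segment (and optional screw) surfaces as a Wavefront OBJ mesh
#'
#' Triangulated parametric surfaces of the two root tubes and, when a
#' placement is given, the screw frustum; intended for visualization.
#'
#' @param segment a [make_segment()] object
#' @param path output `.obj` file
#' @param placement optional `screw_placement` to include
#' @param n_depth,n_theta surface resolution
#' @return `path`, invisibly
#' @export
write_obj <- function(segment, path, placement = NULL, n_depth = 24,
                      n_theta = 32) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# miniscrewsim scene export", con)
  offset <- 0L
  emit <- function(V, Fc, name) {
    writeLines(sprintf("o %s", name), con)
    writeLines(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", Fc[, 1] + offset, Fc[, 2] + offset,
                       Fc[, 3] + offset), con)
    offset <<- offset + nrow(V)
  }
  for (side in c("anterior", "posterior")) {
    for (ri in seq_along(segment[[side]]$roots)) {
      r <- segment[[side]]$roots[[ri]]
      V <- root_surface_points(r, n_depth, n_theta)
      emit(V, quad_faces(n_theta, n_depth),
           sprintf("%s_root_%s", side, segment[[side]]$label))
    }
  }
  if (!is.null(placement)) {
    sc <- placement$screw
    eb <- screw_basis(placement$axis)
    ss <- seq(0, sc$length, length.out = n_depth)
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
    V <- NULL
    for (s in ss) {
      p <- matrix(placement$neck_point + s * placement$axis, n_theta, 3,
                  byrow = TRUE) +
        screw_radius(sc, s) * (outer(cos(th), eb$e1) + outer(sin(th), eb$e2))
      V <- rbind(V, p)
    }
    emit(V, quad_faces(n_theta, n_depth), "miniscrew")
  }
  invisible(path)
}

#' Write a labeled volume as NIfTI-1
#'
#' Minimal single-file NIfTI-1 output (int16, little-endian, sform only)
#' with a sidecar JSON carrying the label legend. `.nii.gz` paths are
#' gzip-compressed.
#'
#' @param volume a `label_volume`
#' @param path output `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_nifti <- function(volume, path) {
  dm <- dim(volume$arr)
  vs <- volume$voxel_size
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348, 4); wc("", 10); wc("", 18); wi(0, 4); wi(0, 2); wc("", 1); wc("r", 1)
  wi(c(3, dm, 1, 1, 1, 1), 2)            # dim[8]
  wf(c(0, 0, 0))                         # intent_p1..p3
  wi(0, 2)                               # intent_code
  wi(4, 2); wi(16, 2)                    # datatype int16, bitpix
  wi(0, 2)                               # slice_start
  wf(c(1, vs, vs, vs, 0, 0, 0, 0))       # pixdim[8]
  wf(352)                                # vox_offset
  wf(c(1, 0))                            # scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)         # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                         # cal_max, cal_min, slice_duration
  wf(0)                                  # toffset
  wi(c(0, 0), 4)                         # glmax, glmin
  wc("miniscrewsim label volume", 80)
  wc("", 24)
  wi(0, 2); wi(1, 2)                     # qform_code 0, sform_code 1
  wf(rep(0, 6))                          # quaternions
  wf(c(vs, 0, 0, volume$origin[1]))
  wf(c(0, vs, 0, volume$origin[2]))
  wf(c(0, 0, vs, volume$origin[3]))
  wc("", 16)                             # intent_name
  wc("n+1", 4)
  writeBin(raw(4), con)                  # extension flag
  wi(as.vector(volume$arr), 2)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  writeLines(jsonlite::toJSON(as.list(volume$legend), auto_unbox = TRUE,
                              pretty = TRUE), sidecar)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#' @param path `.nii` or `.nii.gz` file
#' @return a `label_volume` (legend from the sidecar if present)
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 1, 4, endian = "little")
  if (hdr != 348) stop("not a NIfTI-1 file")
  readBin(con, "raw", 36)
  dm <- readBin(con, "integer", 8, 2, endian = "little")
  readBin(con, "raw", 14)
  datatype <- readBin(con, "integer", 1, 2, endian = "little")
  if (datatype != 4) stop("only int16 volumes are supported")
  readBin(con, "integer", 1, 2, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")
  pixdim <- readBin(con, "numeric", 8, 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, 4, endian = "little")
  readBin(con, "raw", 168)
  srow <- matrix(readBin(con, "numeric", 12, 4, endian = "little"), 3,
                 byrow = TRUE)
  readBin(con, "raw", 24)  # intent_name, magic, extension flag
  n <- prod(dm[2:4])
  arr <- array(readBin(con, "integer", n, 2, endian = "little"), dm[2:4])
  legend <- c(background = 0, bone = 1, anterior_root = 2,
              posterior_root = 3, screw = 4)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  if (file.exists(sidecar))
    legend <- unlist(jsonlite::fromJSON(sidecar))
  structure(list(arr = arr, origin = srow[, 4], voxel_size = pixdim[2],
                 legend = legend),
            class = "label_volume")
}
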