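#' Write an image stack to disk with a manifest
#'
#' One 16-bit grayscale file per light (TIFF or PNG) plus a JSON manifest
#' recording the pixel pitch and, per light, the filename, direction and
#' relative intensity. This is the interchange format between the renderer
#' and the photometric-stereo estimator.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if missing).
#' @param format `"tiff"` or `"png"`.
#' @return The manifest path, invisibly.
#' @export
write_image_stack <- function(stack, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  L <- stack$rig$L
  files <- sprintf("light_%02d.%s", seq_len(L), ext)
  for (i in seq_len(L)) {
    img <- pmin(pmax(stack$pixels[i, , ], 0), 1)
    path <- file.path(dir, files[i])
    if (format == "tiff") {
      tiff::writeTIFF(img, path, bits.per.sample = 16L)
    } else {
      png::writePNG(img, path)
    }
  }
  manifest <- list(
    pitch_um = stack$pitch,
    lights = lapply(seq_len(L), function(i) {
      list(file = files[i],
           direction = as.numeric(stack$rig$directions[i, ]),
           intensity = stack$rig$intensities[i])
    }))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read an image stack from a manifest
#'
#' Loads the stack written by [write_image_stack()] (or a user-supplied
#' stack in the same schema, JSON or YAML): per-light image files are
#' loaded as linear intensities in `[0, 1]` and the rig is validated
#' (directions renormalised with a warning above 1e-6 norm deviation,
#' rejected above 1e-2; light count must match the image count).
#'
#' @param path Path to the manifest file, or a directory containing
#'   `manifest.json`.
#' @return An [image_stack()].
#' @export
read_stack_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stopf("manifest '%s' does not exist", path)
  man <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(man$lights) || !length(man$lights))
    stopf("manifest lists no lights")
  base <- dirname(path)
  dirs <- t(vapply(man$lights, function(l) as.numeric(unlist(l$direction)),
                   numeric(3)))
  ints <- vapply(man$lights, function(l) as.numeric(l$intensity %||% 1),
                 numeric(1))
  rig <- light_rig(dirs, ints)
  imgs <- lapply(man$lights, function(l) {
    f <- file.path(base, l$file)
    if (!file.exists(f)) stopf("image file '%s' is missing", f)
    img <- if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
      tiff::readTIFF(f)
    } else {
      png::readPNG(f)
    }
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    img
  })
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) identical(dim(i), d1), logical(1))))
    stopf("stack images differ in size")
  pix <- array(0, c(length(imgs), d1[1], d1[2]))
  for (i in seq_along(imgs)) pix[i, , ] <- imgs[[i]]
  image_stack(pix, rig, as.numeric(man$pitch_um %||% 4.9))
}

#' Write a height field as a scaled 32-bit TIFF with sidecar
#'
#' TIFF images carry values in `[0, 1]`, so heights are affinely mapped to
#' that range at 32-bit depth (relative resolution about 2e-10) and the
#' offset/scale, pitch and mask are recorded in a JSON sidecar next to the
#' image. [read_height_tiff()] undoes the mapping.
#'
#' @param hf A [height_field()].
#' @param path Output TIFF path; the sidecar gets the extra extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_height_tiff <- function(hf, path) {
  z <- hf$heights
  zmin <- min(z[hf$mask]); zmax <- max(z[hf$mask])
  scale <- if (zmax > zmin) zmax - zmin else 1
  zn <- (z - zmin) / scale
  zn[!hf$mask] <- 0
  zn <- pmin(pmax(zn, 0), 1)
  tiff::writeTIFF(zn, path, bits.per.sample = 32L)
  meta <- list(offset_um = zmin, scale_um = scale, pitch_um = hf$pitch,
               invalid = which(!hf$mask))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_height_tiff
#' @export
read_height_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  zn <- tiff::readTIFF(path)
  z <- zn * meta$scale_um + meta$offset_um
  mask <- matrix(TRUE, nrow(z), ncol(z))
  if (length(meta$invalid)) mask[meta$invalid] <- FALSE
  height_field(z, meta$pitch_um, mask)
}

#' Read or write a blur series as CSV
#'
#' Two columns, `time_s` and `blur`.
#'
#' @param series A [blur_series()].
#' @param path CSV path.
#' @return `path` invisibly for the writer; a [blur_series()] for the
#'   reader.
#' @export
write_blur_csv <- function(series, path) {
  utils::write.csv(data.frame(time_s = series$times, blur = series$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blur_csv
#' @export
read_blur_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "blur") %in% names(df)))
    stopf("blur CSV must have columns 'time_s' and 'blur'")
  fps <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else 30
  blur_series(df$time_s, df$blur, fps)
}

# Triangulate a height field over its pixel grid: two triangles per cell
# whose four corners are all valid. Heights/pitch in um are converted to
# the mm mesh units here, the single conversion point for export.
height_to_mesh <- function(hf) {
  z <- hf$heights; s <- hf$pitch / 1000 # mm
  H <- nrow(z); W <- ncol(z)
  vid <- matrix(seq_len(H * W), H, W)
  vertices <- cbind(rep((seq_len(H) - 1) * s, W),
                    rep((seq_len(W) - 1) * s, each = H),
                    as.vector(z) / 1000)
  i <- rep(1:(H - 1), W - 1)
  j <- rep(1:(W - 1), each = H - 1)
  ok <- hf$mask[cbind(i, j)] & hf$mask[cbind(i + 1, j)] &
    hf$mask[cbind(i, j + 1)] & hf$mask[cbind(i + 1, j + 1)]
  i <- i[ok]; j <- j[ok]
  v00 <- vid[cbind(i, j)]; v10 <- vid[cbind(i + 1, j)]
  v01 <- vid[cbind(i, j + 1)]; v11 <- vid[cbind(i + 1, j + 1)]
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  used <- sort(unique(as.vector(faces)))
  remap <- integer(H * W); remap[used] <- seq_along(used)
  structure(list(vertices = vertices[used, , drop = FALSE],
                 faces = matrix(remap[faces], ncol = 3L)),
            class = "surface_mesh")
}

#' Export a surface as a PLY or OBJ mesh
#'
#' Height fields are triangulated on the pixel grid (two triangles per
#' cell; cells touching invalid pixels are omitted); hull meshes from
#' [hull_surface()] are written as-is. Vertex coordinates are in mm
#' (height fields are converted from micrometres); the unit is recorded in
#' a header comment. Both formats carry identical vertex coordinates.
#'
#' @param geometry A [height_field()] or `surface_mesh`.
#' @param path Output path.
#' @param format `"ply"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(geometry, path, format = c("ply", "obj")) {
  format <- match.arg(format)
  mesh <- if (inherits(geometry, "height_field")) {
    height_to_mesh(geometry)
  } else if (inherits(geometry, "surface_mesh")) {
    geometry
  } else stopf("'geometry' must be a height_field or surface_mesh")
  if (!nrow(mesh$faces)) stopf("geometry is empty")
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  vfmt <- function(m) apply(m, 1, function(r) paste(format(r, digits = 9,
                                                           trim = TRUE),
                                                    collapse = " "))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 "comment units millimetres",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(vfmt(v), con)
    writeLines(paste("3", vfmt(f - 1L)), con)
  } else {
    writeLines("# units millimetres", con)
    writeLines(paste("v", vfmt(v)), con)
    writeLines(paste("f", vfmt(f)), con)
  }
  invisible(path)
}

#' Read or write a run configuration
#'
#' A run configuration is a flat named list of subcommand parameters
#' (paths, numeric settings, a seed) serialised as a single YAML or JSON
#' document. Reading validates against the set of known keys and rejects
#' unknown ones with a clear error, so typos never silently change a run.
#'
#' @param config Named list to write.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param allowed Character vector of permitted keys, or `NULL` to accept
#'   any.
#' @return The configuration list (reader) or `path` invisibly (writer).
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stopf("config '%s' does not exist", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown))
      stopf("unknown configuration key(s): %s (allowed: %s)",
            paste(unknown, collapse = ", "), paste(allowed, collapse = ", "))
  }
  cfg
}
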