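#' Calibrated pinhole camera pose
#'
#' Position and orientation of a pinhole camera plus the intrinsics needed
#' to project world points: focal length, sensor pixel pitch and image
#' size. The rotation maps world coordinates to camera coordinates; the
#' camera looks along its +z axis, image rows grow with camera y and
#' columns with camera x, and the principal point is the image centre.
#'
#' @param position World position of the optical centre (mm), length 3.
#' @param rotation 3 x 3 world-to-camera rotation, orthonormal to 1e-9.
#' @param focal_mm Focal length in mm, `> 0`.
#' @param pixel_pitch_um Sensor pixel pitch in micrometres.
#' @param image_size Image size as `c(rows, cols)` in pixels.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(position, rotation, focal_mm, pixel_pitch_um = 4.9,
                        image_size = c(480L, 640L)) {
  position <- as.numeric(position)
  if (length(position) != 3L) stopf("'position' must have length 3")
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stopf("'rotation' must be 3 x 3")
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9)
    stopf("'rotation' must be orthonormal (within 1e-9)")
  check_number(focal_mm, "focal_mm", min = 0, strict_min = TRUE)
  check_number(pixel_pitch_um, "pixel_pitch_um", min = 0, strict_min = TRUE)
  structure(list(position = position, rotation = rotation,
                 focal_mm = focal_mm, pixel_pitch_um = pixel_pitch_um,
                 image_size = as.integer(image_size)),
            class = "camera_pose")
}

#' Camera pose looking at a target point
#'
#' Convenience constructor: places the camera at `position` with its
#' optical axis through `target` and image columns aligned as closely as
#' possible with the `up` hint.
#'
#' @inheritParams camera_pose
#' @param target World point on the optical axis (mm).
#' @param up Approximate world direction mapped to image columns.
#' @return A [camera_pose()].
#' @export
look_at_pose <- function(position, target, focal_mm,
                         pixel_pitch_um = 4.9, image_size = c(480L, 640L),
                         up = c(0, 0, 1)) {
  zc <- target - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- up - sum(up * zc) * zc
  if (sqrt(sum(xc^2)) < 1e-9) stopf("'up' is parallel to the optical axis")
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  camera_pose(position, rbind(xc, yc, zc), focal_mm, pixel_pitch_um,
              image_size)
}

#' Project world points through a camera pose
#'
#' @param pose A [camera_pose()].
#' @param pts N x 3 matrix of world points (mm).
#' @return List with `row`, `col` (fractional pixel coordinates) and
#'   `in_front` (logical, point in front of the camera).
#' @export
project_points <- function(pose, pts) {
  pts <- as.matrix(pts)
  cam <- sweep(pts, 2, pose$position) %*% t(pose$rotation)
  zc <- cam[, 3]
  in_front <- zc > 1e-9
  pitch_mm <- pose$pixel_pitch_um / 1000
  u <- pose$focal_mm * cam[, 1] / zc / pitch_mm + (pose$image_size[2] + 1) / 2
  v <- pose$focal_mm * cam[, 2] / zc / pitch_mm + (pose$image_size[1] + 1) / 2
  list(row = v, col = u, in_front = in_front)
}

#' Silhouette set
#'
#' Binary masks (TRUE = object) with one calibrated [camera_pose()] per
#' mask.
#'
#' @param masks List of logical matrices.
#' @param poses List of [camera_pose()] objects, one per mask.
#' @return An object of class `silhouette_set`.
#' @export
silhouette_set <- function(masks, poses) {
  if (length(masks) != length(poses))
    stopf("need one pose per mask (%d masks, %d poses)",
          length(masks), length(poses))
  if (!length(masks)) stopf("at least one view is required")
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!is.matrix(m) || !is.logical(m) || !length(m))
      stopf("mask %d is not a non-empty logical matrix", i)
    if (!identical(dim(m), as.integer(poses[[i]]$image_size)))
      stopf("mask %d dimensions do not match its pose image size", i)
    if (!inherits(poses[[i]], "camera_pose"))
      stopf("pose %d is not a camera_pose", i)
  }
  structure(list(masks = masks, poses = poses), class = "silhouette_set")
}

#' Render the silhouette of a sphere (synthetic fixture)
#'
#' Conservative rasterisation of the exact silhouette of a ball: a pixel is
#' inside when its centre lies within half a pixel diagonal of the
#' projected silhouette, so boundary pixels count as inside and the carved
#' hull is guaranteed to contain the ball.
#'
#' @param pose A [camera_pose()].
#' @param center Ball centre (mm).
#' @param radius Ball radius (mm).
#' @return Logical mask matching the pose image size.
#' @export
render_sphere_silhouette <- function(pose, center, radius) {
  H <- pose$image_size[1]; W <- pose$image_size[2]
  pitch_mm <- pose$pixel_pitch_um / 1000
  ## pixel centre rays in camera coordinates
  u <- ((1:W) - (W + 1) / 2) * pitch_mm
  v <- ((1:H) - (H + 1) / 2) * pitch_mm
  f <- pose$focal_mm
  cc <- drop(pose$rotation %*% (center - pose$position))
  ## distance from the ball centre to each pixel ray; half-pixel-diagonal
  ## tolerance at the ball's depth keeps the rasterisation conservative
  dir_x <- matrix(u, H, W, byrow = TRUE)
  dir_y <- matrix(v, H, W)
  nrm <- sqrt(dir_x^2 + dir_y^2 + f^2)
  t <- (dir_x * cc[1] + dir_y * cc[2] + f * cc[3]) / nrm
  d2 <- sum(cc^2) - pmax(t, 0)^2
  tol <- pitch_mm * sqrt(2) / 2 * cc[3] / f
  d2 <= (radius + tol)^2
}

#' Voxel grid specification / container
#'
#' @param origin World coordinates of the corner of voxel `[1, 1, 1]` (mm).
#' @param voxel_mm Edge length of a voxel (mm), `> 0`.
#' @param dims Lattice size `c(nx, ny, nz)`.
#' @param occupancy Optional logical array of occupied voxels.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, voxel_mm, dims, occupancy = NULL) {
  check_number(voxel_mm, "voxel_mm", min = 0, strict_min = TRUE)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stopf("'dims' must be 3 positive sizes")
  if (is.null(occupancy)) occupancy <- array(FALSE, dims)
  if (!identical(dim(occupancy), dims)) stopf("occupancy dimensions mismatch")
  structure(list(origin = as.numeric(origin), voxel_mm = voxel_mm,
                 dims = dims, occupancy = occupancy),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of %.3g mm, %d occupied (%.3g mm^3)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_mm,
              sum(x$occupancy), hull_volume(x)))
  invisible(x)
}

voxel_centers <- function(grid) {
  ix <- (seq_len(grid$dims[1]) - 0.5) * grid$voxel_mm + grid$origin[1]
  iy <- (seq_len(grid$dims[2]) - 0.5) * grid$voxel_mm + grid$origin[2]
  iz <- (seq_len(grid$dims[3]) - 0.5) * grid$voxel_mm + grid$origin[3]
  as.matrix(expand.grid(x = ix, y = iy, z = iz))
}

#' Carve a visual hull from calibrated silhouettes
#'
#' Voxel carving: a voxel stays occupied iff its centre projects inside
#' the silhouette in every view whose image frame contains it, and it is
#' seen by at least one view. Silhouette boundary pixels count as inside
#' (nearest-pixel lookup), making the hull conservative. The hull of exact
#' silhouettes always contains the true object, and adding views can only
#' remove voxels.
#'
#' @param sil A [silhouette_set()].
#' @param grid A [voxel_grid()] specifying the carving lattice.
#' @return The carved [voxel_grid()].
#' @export
carve <- function(sil, grid) {
  if (!inherits(sil, "silhouette_set")) stopf("'sil' must be a silhouette_set")
  if (!inherits(grid, "voxel_grid")) stopf("'grid' must be a voxel_grid")
  if (any(!vapply(sil$masks, any, logical(1)))) {
    warning("a view has an empty silhouette; the hull is empty")
    return(voxel_grid(grid$origin, grid$voxel_mm, grid$dims))
  }
  pts <- voxel_centers(grid)
  keep <- rep(TRUE, nrow(pts))
  seen <- rep(FALSE, nrow(pts))
  for (i in seq_along(sil$masks)) {
    pose <- sil$poses[[i]]; mask <- sil$masks[[i]]
    pr <- project_points(pose, pts)
    r <- as.integer(round(pr$row)); c <- as.integer(round(pr$col))
    visible <- pr$in_front & r >= 1L & r <= nrow(mask) &
      c >= 1L & c <= ncol(mask)
    seen <- seen | visible
    idx <- which(visible & keep)
    if (length(idx)) {
      inside <- mask[cbind(r[idx], c[idx])]
      keep[idx[!inside]] <- FALSE
    }
  }
  occ <- array(keep & seen, grid$dims)
  voxel_grid(grid$origin, grid$voxel_mm, grid$dims, occ)
}

#' Volume of the occupied region
#'
#' @param grid A carved [voxel_grid()].
#' @return Volume in mm^3.
#' @export
hull_volume <- function(grid) sum(grid$occupancy) * grid$voxel_mm^3

#' Extract the boundary surface of a voxel hull
#'
#' Emits two triangles for every voxel face that separates an occupied
#' voxel from an unoccupied one (or from outside the lattice), with
#' outward-facing winding and shared vertices, yielding a closed mesh of
#' the occupied region.
#'
#' @param grid A non-empty carved [voxel_grid()].
#' @return An object of class `surface_mesh`: list with `vertices`
#'   (V x 3, mm) and `faces` (F x 3 vertex indices).
#' @export
hull_surface <- function(grid) {
  occ <- grid$occupancy
  if (!any(occ)) stopf("the voxel grid is empty")
  d <- grid$dims
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  idx <- which(occ, arr.ind = TRUE)
  ## vertex index on the (d+1)^3 corner lattice
  corner_id <- function(i, j, k) {
    (i - 1) + (d[1] + 1) * ((j - 1) + (d[2] + 1) * (k - 1)) + 1
  }
  tris <- vector("list", 6L)
  ## each face: offset of the neighbour and the 4 corner offsets (CCW from
  ## outside)
  face_def <- list(
    list(n = c(-1L, 0L, 0L), v = rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0))),
    list(n = c( 1L, 0L, 0L), v = rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))),
    list(n = c(0L, -1L, 0L), v = rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1))),
    list(n = c(0L,  1L, 0L), v = rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0))),
    list(n = c(0L, 0L, -1L), v = rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0))),
    list(n = c(0L, 0L,  1L), v = rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))))
  all_faces <- list()
  for (f in face_def) {
    nb <- cbind(idx[, 1] + f$n[1] + 1L, idx[, 2] + f$n[2] + 1L,
                idx[, 3] + f$n[3] + 1L)
    exposed <- !pad[nb]
    if (!any(exposed)) next
    e <- idx[exposed, , drop = FALSE]
    vid <- sapply(1:4, function(k) {
      corner_id(e[, 1] + f$v[k, 1], e[, 2] + f$v[k, 2], e[, 3] + f$v[k, 3])
    })
    vid <- matrix(vid, ncol = 4L)
    all_faces[[length(all_faces) + 1L]] <-
      rbind(vid[, c(1, 2, 3), drop = FALSE], vid[, c(1, 3, 4), drop = FALSE])
  }
  faces_cid <- do.call(rbind, all_faces)
  used <- sort(unique(as.vector(faces_cid)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  faces <- matrix(remap[faces_cid], ncol = 3L)
  ## corner lattice coordinates back to mm
  u0 <- used - 1L
  ci <- u0 %% (d[1] + 1L)
  cj <- (u0 %/% (d[1] + 1L)) %% (d[2] + 1L)
  ck <- u0 %/% ((d[1] + 1L) * (d[2] + 1L))
  vertices <- cbind(grid$origin[1] + ci * grid$voxel_mm,
                    grid$origin[2] + cj * grid$voxel_mm,
                    grid$origin[3] + ck * grid$voxel_mm)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}
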