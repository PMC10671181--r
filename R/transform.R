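#' Rigid (6 degree-of-freedom) spatial transform
#'
#' A 3D Euler rigid transform parameterised by three rotation angles
#' (radians, applied as Rz * Ry * Rx), a translation (mm) and a rotation
#' centre (mm). A point `x` maps to `R %*% (x - centre) + centre +
#' translation`.
#'
#' @param angles_rad numeric triple of Euler angles (about x, y, z).
#' @param translation_mm numeric triple, mm.
#' @param centre_mm rotation centre in world coordinates, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_rad = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            centre_mm = c(0, 0, 0)) {
  stopifnot(length(angles_rad) == 3L, length(translation_mm) == 3L,
            length(centre_mm) == 3L)
  if (any(!is.finite(c(angles_rad, translation_mm, centre_mm))))
    stop("transform parameters must be finite")
  structure(
    list(angles_rad = as.numeric(angles_rad),
         translation_mm = as.numeric(translation_mm),
         centre_mm = as.numeric(centre_mm)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (deg): %s; translation (mm): %s\n",
              paste(format(x$angles_rad * 180 / pi, digits = 4),
                    collapse = ", "),
              paste(format(x$translation_mm, digits = 4), collapse = ", ")))
  invisible(x)
}

# Rotation matrix Rz(cz) Ry(cy) Rx(cx).
euler_to_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Euler angles (x, y, z) with R = Rz Ry Rx; gimbal-safe branch at |r31| = 1.
matrix_to_euler <- function(R) {
  if (abs(R[3, 1]) < 1 - 1e-12) {
    y <- asin(-R[3, 1])
    x <- atan2(R[3, 2], R[3, 3])
    z <- atan2(R[2, 1], R[1, 1])
  } else {
    y <- if (R[3, 1] <= -1 + 1e-12) pi / 2 else -pi / 2
    x <- atan2(-R[1, 2], R[2, 2])
    z <- 0
  }
  c(x, y, z)
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return 4x4 matrix acting on homogeneous world coordinates.
#' @export
transform_matrix <- function(transform) {
  R <- euler_to_matrix(transform$angles_rad)
  offset <- transform$centre_mm + transform$translation_mm -
    R %*% transform$centre_mm
  rbind(cbind(R, offset), c(0, 0, 0, 1))
}

#' Invert / compose rigid transforms
#'
#' `invert_transform(t)` returns the transform mapping back, with the same
#' rotation centre; `compose_transforms(a, b)` returns the transform whose
#' action is "apply `b`, then `a`", centred at `a`'s centre. Both are exact
#' (closed form), so composing a transform with its inverse yields the
#' identity to machine precision.
#'
#' @param transform,a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  R <- euler_to_matrix(transform$angles_rad)
  rigid_transform(
    angles_rad = matrix_to_euler(t(R)),
    translation_mm = as.numeric(-t(R) %*% transform$translation_mm),
    centre_mm = transform$centre_mm
  )
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  M <- transform_matrix(a) %*% transform_matrix(b)
  R <- M[1:3, 1:3]
  centre <- a$centre_mm
  # offset = centre + translation - R centre  =>  translation
  translation <- M[1:3, 4] - centre + R %*% centre
  rigid_transform(matrix_to_euler(R), as.numeric(translation), centre)
}

#' Apply a rigid transform to world-space points
#'
#' @param transform a [rigid_transform()].
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  M <- transform_matrix(transform)
  t(M[1:3, 1:3] %*% t(xyz) + M[1:3, 4])
}

#' Serialise rigid transforms as JSON
#'
#' @param transform a [rigid_transform()].
#' @param path JSON file path.
#' @return `read_transform_json` returns a [rigid_transform()].
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(angles_rad = transform$angles_rad,
         translation_mm = transform$translation_mm,
         centre_mm = transform$centre_mm),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angles_rad, x$translation_mm, x$centre_mm)
}
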