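#' Six-parameter rigid transform
#'
#' Rotations are in degrees and are applied about a centre point (by
#' convention the volume centre) in the fixed order x, then y, then z
#' (i.e. the rotation matrix is `Rz %*% Ry %*% Rx`); translations are in mm
#' and applied after rotation. The identity transform has all six
#' parameters zero.
#'
#' @param tx,ty,tz translations, mm.
#' @param rx,ry,rz rotations about the x, y, z axes, degrees.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = unname(tx), ty = unname(ty), tz = unname(tz),
         rx = unname(rx), ry = unname(ry), rz = unname(rz))
  if (any(!is.finite(p))) stop("rigid_transform: non-finite parameter")
  structure(list(params = p), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  p <- x$params
  cat(sprintf("rigid: t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              p["tx"], p["ty"], p["tz"], p["rx"], p["ry"], p["rz"]))
  invisible(x)
}

rotation_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' 4x4 homogeneous matrix of a rigid transform
#'
#' Maps world point `p` to `R (p - centre) + centre + t`.
#'
#' @param t a [rigid_transform()].
#' @param centre rotation centre, world mm (length 3).
#' @return 4x4 matrix.
#' @export
rigid_matrix <- function(t, centre = c(0, 0, 0)) {
  p <- t$params
  R <- rotation_matrix(p["rx"], p["ry"], p["rz"])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- centre - R %*% centre + p[c("tx", "ty", "tz")]
  M
}

#' Rigid transform from a 4x4 rigid matrix
#'
#' Inverse of [rigid_matrix()]: extracts ZYX Euler angles (degrees) and the
#' translation relative to the given rotation centre.
#'
#' @param M 4x4 rigid homogeneous matrix.
#' @param centre rotation centre, world mm.
#' @return a [rigid_transform()].
#' @export
rigid_from_matrix <- function(M, centre = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold everything into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  tr <- M[1:3, 4] - (centre - R %*% centre)
  rigid_transform(tr[1], tr[2], tr[3],
                  rx * 180 / pi, ry * 180 / pi, rz * 180 / pi)
}

#' Compose two rigid transforms (a then b)
#' @param a,b [rigid_transform()] objects.
#' @param centre common rotation centre, world mm.
#' @return a [rigid_transform()] equal to applying `a` first, then `b`.
#' @export
rigid_compose <- function(a, b, centre = c(0, 0, 0)) {
  rigid_from_matrix(rigid_matrix(b, centre) %*% rigid_matrix(a, centre), centre)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @param centre rotation centre, world mm.
#' @return the inverse [rigid_transform()].
#' @export
rigid_invert <- function(t, centre = c(0, 0, 0)) {
  rigid_from_matrix(solve(rigid_matrix(t, centre)), centre)
}

#' Serialise / deserialise a rigid transform as JSON
#'
#' @param t a [rigid_transform()].
#' @param path output JSON path.
#' @param fixed,moving optional image identifiers recorded for provenance.
#' @return `path` invisibly; `read_rigid` returns the transform.
#' @export
write_rigid <- function(t, path, fixed = NULL, moving = NULL) {
  obj <- c(as.list(t$params),
           list(convention = "mm/deg, rotations Rz*Ry*Rx about volume centre",
                fixed = fixed, moving = moving))
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(obj$tx, obj$ty, obj$tz, obj$rx, obj$ry, obj$rz)
}
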