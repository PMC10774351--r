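# Sensor montage handling: standard positions, 2-D projection, spatial
# adjacency, and the posterior-weighted topography used by the generator.

#' Read a sensor montage
#'
#' Whitespace-delimited text with columns \code{name x y z} (head frame:
#' +x right, +y anterior, +z superior); lines starting with \code{#} are
#' skipped.
#'
#' @param path file path.
#' @return data.frame with columns \code{name, x, y, z}.
#' @export
readMontage <- function(path) {
  m <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("name", "x", "y", "z"),
                         colClasses = c("character", rep("numeric", 3)),
                         skip = 0, fill = FALSE,
                         stringsAsFactors = FALSE)
  m
}

#' Write a sensor montage
#'
#' @param montage data.frame with columns \code{name, x, y, z}.
#' @param path file path.
#' @export
writeMontage <- function(montage, path) {
  utils::write.table(montage[, c("name", "x", "y", "z")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Default montage for a given sensor count
#'
#' Returns the shipped BioSemi 64-channel extended 10-20 montage, subset to
#' the first \code{n} sensors when \code{n < 64}, or \code{n} points on a
#' posterior-to-anterior spiral on the unit sphere when \code{n > 64} (so
#' arbitrary synthetic sensor counts still carry usable geometry).
#'
#' @param n number of sensors.
#' @return montage data.frame.
#' @export
defaultMontage <- function(n = 64) {
  path <- system.file("extdata", "biosemi64.txt", package = "vividEEG")
  if (nzchar(path)) {
    m <- readMontage(path)
    if (n <= nrow(m)) return(m[seq_len(n), , drop = FALSE])
  }
  # Fibonacci spiral on the upper hemisphere
  i <- seq_len(n)
  zc <- 0.05 + 0.95 * (i - 0.5) / n
  th <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - zc^2)) * 0.095
  data.frame(name = paste0("S", i), x = r * cos(th), y = r * sin(th),
             z = zc * 0.095, stringsAsFactors = FALSE)
}

#' Azimuthal-equidistant 2-D projection of 3-D sensor positions
#'
#' Projects positions on (approximately) a sphere about the head centre onto
#' the plane, preserving angular distance from the vertex; the standard
#' flattening used for topographic maps and spatial adjacency.
#'
#' @param montage montage data.frame.
#' @return n x 2 matrix of planar coordinates.
#' @export
projectMontage <- function(montage) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  r <- sqrt(rowSums(xyz^2))
  r[r == 0] <- 1
  u <- xyz / r
  theta <- acos(pmin(1, pmax(-1, u[, 3])))    # polar angle from vertex
  hor <- sqrt(u[, 1]^2 + u[, 2]^2)
  hor[hor == 0] <- 1
  cbind(theta * u[, 1] / hor, theta * u[, 2] / hor)
}

#' Delaunay-based sensor adjacency
#'
#' Triangulates the 2-D projected montage by the empty-circumcircle property
#' (every triangle whose circumcircle contains no other sensor is kept) and
#' marks triangle edges as neighbours. Symmetric, no self-adjacency.
#'
#' @param montage montage data.frame, or an n x 2 matrix of planar positions.
#' @return symmetric logical n x n adjacency matrix.
#' @export
delaunayAdjacency <- function(montage) {
  xy <- if (is.matrix(montage)) montage else projectMontage(montage)
  n <- nrow(xy)
  if (n < 3) {
    adj <- matrix(TRUE, n, n)
    diag(adj) <- FALSE
    return(adj)
  }
  tri <- t(utils::combn(n, 3))
  ax <- xy[tri[, 1], 1]; ay <- xy[tri[, 1], 2]
  bx <- xy[tri[, 2], 1]; by <- xy[tri[, 2], 2]
  cx <- xy[tri[, 3], 1]; cy <- xy[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-12                       # drop collinear triples
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  # squared distance from every circumcenter to every point
  dist2 <- outer(ux, xy[, 1], "-")^2 + outer(uy, xy[, 2], "-")^2
  inside <- dist2 < r2 - 1e-12 * pmax(r2, 1)
  for (j in 1:3) inside[cbind(seq_len(nrow(tri)), tri[, j])] <- FALSE
  keep <- ok & rowSums(inside) == 0
  adj <- matrix(FALSE, n, n)
  for (i in which(keep)) {
    v <- tri[i, ]
    adj[v[1], v[2]] <- adj[v[2], v[1]] <- TRUE
    adj[v[1], v[3]] <- adj[v[3], v[1]] <- TRUE
    adj[v[2], v[3]] <- adj[v[3], v[2]] <- TRUE
  }
  if (is.data.frame(montage)) dimnames(adj) <- list(montage$name, montage$name)
  adj
}

#' Read a sensor adjacency matrix from file
#'
#' Whitespace-delimited 0/1 matrix, one row per sensor; overrides the
#' Delaunay default where an explicit neighbour template is preferred.
#'
#' @param path file path.
#' @return symmetric logical adjacency matrix.
#' @export
readAdjacency <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  adj <- m != 0
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  dimnames(adj) <- NULL
  adj
}

#' Posterior-maximal sensor weights
#'
#' Per-sensor weights in [0.3, 1], largest at the most posterior (occipital)
#' sensor and decaying linearly with the anterior-posterior coordinate; used
#' to make synthetic condition effects maximal occipitally while every sensor
#' still carries some effect.
#'
#' @param montage montage data.frame.
#' @return numeric weight per sensor.
#' @export
occipitalWeights <- function(montage) {
  y <- montage$y
  if (diff(range(y)) == 0) return(rep(1, nrow(montage)))
  w <- (max(y) - y) / (max(y) - min(y))
  0.3 + 0.7 * w
}

# Resolve a topography spec ("occipital", "uniform", or numeric) to weights.
resolveTopography <- function(topography, montage, nSensors) {
  if (is.numeric(topography)) {
    if (length(topography) != nSensors)
      stop("numeric topography must have one weight per sensor")
    return(topography)
  }
  switch(topography,
         occipital = occipitalWeights(montage)[seq_len(nSensors)],
         uniform = rep(1, nSensors),
         stop("unknown topography: ", topography))
}
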