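#' @useDynLib tractconcord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention (used everywhere in the package):
#   * world coordinates are in mm;
#   * voxel indices are 1-based in R (0-based in C++);
#   * the center of voxel (i, j, k) is at ((i - 0.5) vs, (j - 0.5) vs, (k - 0.5) vs)
#     for isotropic voxel size vs;
#   * the sectioning axis is the third array axis;
#   * 2D slice coordinates follow the same rule in-plane: pixel (i, j) has its
#     center at ((i - 0.5) sp, (j - 0.5) sp).

tc_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "tc_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Attach voxel-size metadata to a 3D array
#'
#' Volumes in this package are plain R arrays carrying their isotropic voxel
#' size (mm) as the `voxel_size_mm` attribute.
#'
#' @param x 3D array (or 4D, e.g. a per-slice displacement-field stack whose
#'   first three axes are spatial).
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @return the array with metadata attached.
#' @export
as_volume <- function(x, voxel_size_mm) {
  if (!length(dim(x)) %in% c(3L, 4L))
    tc_stop("tc_bad_geometry", "a volume must be a 3D (or 4D) array")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L || voxel_size_mm <= 0)
    tc_stop("tc_bad_geometry", "voxel_size_mm must be a single positive number")
  attr(x, "voxel_size_mm") <- as.numeric(voxel_size_mm)
  x
}

#' Voxel size of a volume
#' @param x a volume created with [as_volume()] or read from file.
#' @return isotropic voxel size in mm.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_mm")
  if (is.null(vs)) tc_stop("tc_bad_geometry", "volume carries no voxel_size_mm metadata")
  vs
}

# World coordinates (mm) of all voxel centers along one axis.
axis_centers <- function(n, vs) (seq_len(n) - 0.5) * vs

#' Derive a child seed from a master seed and a stage name
#'
#' Named substreams keep every stage's randomness independent of the others:
#' adding a stage never perturbs the draws of an existing one. The hash is a
#' 32-bit FNV-1a over the stage name mixed with the master seed, reduced below
#' 2^31.
#'
#' @param master_seed integer master seed.
#' @param name substream name (e.g. "geometry", "warps", "tracking_left").
#' @return a positive integer seed < 2^31.
#' @export
derive_seed <- function(master_seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  h <- fnv1a32(paste0(name, ":", as.integer(master_seed)))
  as.integer((h + as.double(master_seed)) %% 2147483629) + 1L
}

# 32-bit FNV-1a hash of a string, returned as double in [0, 2^32).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# Euclidean norm of rows of a matrix / of a vector.
vnorm <- function(x) {
  if (is.matrix(x)) sqrt(rowSums(x^2)) else sqrt(sum(x^2))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) tc_stop("tc_degenerate", "cannot normalize a zero vector")
  v / n
}

# Gaussian smoothing of a 2D matrix (separable, reflected boundaries).
# sigma in pixels; sigma <= 0 returns the input unchanged.
gauss_smooth2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  cpp_sepconv2(img, k)
}

# Canonicalize a (nested) list: sort names recursively. Used for config hashing.
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

#' Hash a configuration
#'
#' Stable under field reordering: the list is recursively name-sorted before
#' being serialized to JSON and hashed (FNV-1a, 32 bit, hex).
#'
#' @param config a (nested) list.
#' @return an 8-character hex string.
#' @export
config_hash <- function(config) {
  j <- jsonlite::toJSON(canonicalize(config), auto_unbox = TRUE, digits = NA)
  h <- fnv1a32(as.character(j))  # double in [0, 2^32): format as two halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
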