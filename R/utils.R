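# Small numeric helpers shared across modules.

#' Convert radians to degrees
#'
#' All tropism reports carry angles in both units; the conversion factor is
#' 180/pi (1 radian = 57.3 degrees to three significant figures).
#'
#' @param rad numeric vector of angles in radians.
#' @return numeric vector of angles in degrees.
#' @export
#' @examples
#' rad_to_deg(1)      # 57.29578
#' rad_to_deg(pi / 2) # 90
rad_to_deg <- function(rad) rad * 180 / pi

#' Convert degrees to radians
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of angles in radians.
#' @export
deg_to_rad <- function(deg) deg * pi / 180

## Euclidean norm of a single 3-vector.
.norm3 <- function(v) sqrt(sum(v * v))

## Unit vector; errors on (near-)zero input.
.unit <- function(v, what = "vector") {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize zero-length ", what, call. = FALSE)
  v / n
}

## Row-wise Euclidean norms of an n x 3 matrix.
.rownorms <- function(m) sqrt(rowSums(m * m))

## Deterministic 32-bit FNV-1a hash of an R object (for run manifests).
## Returns an 8-char hex string; stable across sessions for the same input.
.manifest_digest <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

## Derive a child seed from a base seed and an index, staying < 2^31.
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}

## Stop with a structured message naming the module operation.
.fail <- function(...) stop(..., call. = FALSE)
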