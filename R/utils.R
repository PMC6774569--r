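## Shared internal numerics.

## displacement vectors a - b under the minimum-image convention for an
## orthorhombic box; box numeric(0) means non-periodic
.displacement <- function(a, b, box = numeric(0)) {
  d <- a - b
  if (length(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

## pairwise distance matrix between coordinate sets A (n x 3) and B (m x 3)
.distMatrix <- function(A, B, box = numeric(0)) {
  n <- nrow(A); m <- nrow(B)
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (length(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

## mass-weighted centre of a coordinate block; falls back to the geometric
## centre when no positive masses are available is an error (spec: zero total
## mass -> error)
.centerOfMass <- function(pos, mass) {
  w <- sum(mass)
  if (w <= 0) stop("zero total mass in selection")
  colSums(pos * mass) / w
}

.movingAverage3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y[1] <- mean(x[1:2]); y[n] <- mean(x[(n - 1):n])
  y
}

.degrees <- function(rad) rad * 180 / pi
.radians <- function(deg) deg * pi / 180

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

## any unit vector orthogonal to v
.orthonormalBasis <- function(n) {
  n <- .normalize(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .normalize(ref - sum(ref * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v, n = n)
}

## rotation matrix about unit axis by angle (radians), Rodrigues form
.rotationMatrix <- function(axis, angle) {
  a <- .normalize(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items; 1
#' means identical partitions (up to label permutation), 0 the chance level.
#' Used to score recovery of planted cluster structure.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
#' @examples
#' adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
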