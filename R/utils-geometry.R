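## small vector helpers used across the geometry code

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## angle at vertex b (degrees) between rays b->a and b->c
vangle <- function(a, b, c) {
  u <- unitv(a - b); w <- unitv(c - b)
  acos(max(-1, min(1, sum(u * w)))) * 180 / pi
}

deg2rad <- function(x) x * pi / 180

## wrap an angle in degrees into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

## coordinates of an atom-table subset as an N x 3 matrix
atom_xyz <- function(at) {
  as.matrix(at[, c("x", "y", "z"), drop = FALSE])
}
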