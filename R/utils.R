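#' @keywords internal
"_PACKAGE"

# Numeric tolerance used for unit-vector and orthonormality checks.
.TOL_UNIT <- 1e-9

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x)) stop(what, " must be a finite 3-vector", call. = FALSE)
  x
}

as_points_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
    storage.mode(x) <- "double"
    return(x)
  }
  matrix(as_point3(x), nrow = 1L)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "direction") {
  v <- as_point3(v, what)
  n <- vnorm(v)
  if (n < 1e-12) stop(what, " is degenerate (zero length)", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product of two n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# Two unit vectors spanning the plane orthogonal to unit n.
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(n, ref))
  e2 <- cross3(n, e1)
  cbind(e1, e2)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the code, then restores the caller's RNG state so that
#' seeded helpers never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Round half away from zero
#'
#' Display rounding used for millimetre tables (0.85 -> 0.9, -0.85 -> -0.9),
#' unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}
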