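# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# population standard deviation (divisor n, not n-1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_finite_matrix <- function(m) is.numeric(m) && all(is.finite(m))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L))
    stopf("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# rotation matrix about a unit axis (Rodrigues)
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

vec_norm <- function(v) sqrt(sum(v^2))

# least-squares plane through rows of xyz: list(centroid, normal, rms)
lsq_plane <- function(xyz) {
  if (nrow(xyz) < 3) stopf("need at least 3 points to define a plane")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stopf("points are collinear; plane is undefined")
  normal <- sv$v[, 3]
  d <- as.numeric(X %*% normal)
  list(centroid = ctr, normal = normal, rms = sqrt(mean(d^2)))
}

# angle in [0, 90] degrees between two plane normals (sign-independent)
interplane_angle <- function(n1, n2) {
  c1 <- abs(sum(n1 * n2)) / (vec_norm(n1) * vec_norm(n2))
  rad2deg(acos(min(1, c1)))
}
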