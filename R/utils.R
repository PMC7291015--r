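# Internal helpers: seeded RNG scopes, rotation algebra, FWHM conversion,
# and a dense linear-assignment solver used by the tracker.

#' Run code with a fixed RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage substream seed from a global seed
#'
#' Deterministic, stays within 32-bit integer range so the result is a valid
#' argument to [set.seed()].
#' @param seed integer global seed.
#' @param stage character stage name (e.g. "simulate", "render").
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647L)
}

## conversion between FWHM and Gaussian sigma: FWHM = 2*sqrt(2*ln 2) * sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

fwhm_to_sigma <- function(fwhm) fwhm * FWHM_TO_SIGMA

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#' @noRd
rotation_about_axis <- function(axis, angle_rad) {
  k <- unit_vec(axis)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Minimal rotation taking unit vector u onto unit vector v
#'
#' The rotation axis is u x v; when u and v are antiparallel the rotation is
#' underdetermined and a deterministic 180 degree rotation about +z is used
#' (or +y when both vectors lie on the z axis).
#' @noRd
minimal_rotation <- function(u, v) {
  u <- unit_vec(u); v <- unit_vec(v)
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- vec_norm(ax)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: 180 deg about an axis orthogonal to u, fixed convention
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    ref <- unit_vec(ref - sum(ref * u) * u)
    return(rotation_about_axis(ref, pi))
  }
  rotation_about_axis(ax, atan2(s, c_))
}

#' Solve the linear assignment problem on a square cost matrix
#'
#' Jonker-Volgenant style shortest augmenting path (O(n^3)). Forbidden
#' assignments should be encoded as a large finite cost.
#' @param cost square numeric matrix.
#' @return integer vector a with a[i] = column assigned to row i.
#' @noRd
lap_solve <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  stopifnot(ncol(cost) == n)
  # 1-based port of the classic potentials + augmenting-path algorithm;
  # column index 0 (virtual) lives at slot 1 of the length-(n+1) vectors.
  u <- numeric(n + 1)          # row potentials, u[i + 1]
  v <- numeric(n + 1)          # col potentials, v[j + 1]
  p <- integer(n + 1)          # p[j + 1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      idx <- which(used)
      u[p[idx] + 1] <- u[p[idx] + 1] + delta
      v[idx] <- v[idx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}
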