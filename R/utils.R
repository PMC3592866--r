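# internal helpers shared across modules

`%||%` <- rlang::`%||%`

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) {
    rlang::abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) rlang::abort("Cannot normalize a zero vector.")
  v / n
}

# Rodrigues rotation matrix: rotate by `angle` radians about unit axis `k`
.rotation_about <- function(k, angle) {
  k <- .unit(k)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation taking unit vector a onto unit vector b
.rotation_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross3(a, b)
  s <- sqrt(sum(v^2))
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    perp <- if (abs(a[1]) < 0.9) .cross3(a, c(1, 0, 0)) else .cross3(a, c(0, 1, 0))
    return(.rotation_about(perp, pi))
  }
  .rotation_about(v, atan2(s, c_))
}

# dihedral angle (degrees, in (-180, 180]) defined by four points (rows)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# centered running mean with odd window k, ends handled by shrinking window
.rollk <- function(x, k) {
  n <- length(x)
  k <- min(k - (1 - k %% 2), n) # force odd, cap at n
  if (k < 3) return(x)
  half <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# rolling mean with window 3, ends handled by shrinking window
.roll3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- mean(x[1:2]); out[n] <- mean(x[(n - 1):n])
  out
}

# contiguous runs of TRUE, tolerating isolated single-FALSE gaps
.runs_with_gaps <- function(ok, min_len, bridge_single = TRUE) {
  n <- length(ok)
  if (bridge_single && n >= 3) {
    inner <- 2:(n - 1)
    fill <- inner[!ok[inner] & ok[inner - 1] & ok[inner + 1]]
    ok[fill] <- TRUE
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start = starts[keep], end = ends[keep])
}
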