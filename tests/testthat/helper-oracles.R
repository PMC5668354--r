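# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Disc-slice (midpoint) quadrature of the solid of revolution with circular
# side profile: profile radius R(z) = r_c + sqrt(r^2 - z^2), r = h/2.
oracle_volume <- function(r_m, h, n_slices = 1e5) {
  r <- h / 2
  r_c <- r_m - r
  z <- (seq_len(n_slices) - 0.5) / n_slices * h - r
  dz <- h / n_slices
  sum(pi * (r_c + sqrt(pmax(r^2 - z^2, 0)))^2) * dz
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# choose(n1 + n2, n1) group labelings (small samples, no ties).
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  u_obs <- min(u_obs, n1 * length(b) - u_obs)
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2, function(idx) {
    u <- u_of(idx)
    min(u, n1 * length(b) - u)
  })
  mean(us <= u_obs)
}

# Pooled-variance two-sample t statistic and two-sided p, written out longhand.
oracle_student_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Analytic disk image: intensity `inside` on a centered disk of radius
# `radius_px`, `bg` elsewhere; optional concentric second disk.
make_disk_image <- function(radius_px, pixel_size = 0.2, n = NULL,
                            inside = 100, bg = 0) {
  n <- n %||% (2L * ceiling(1.3 * radius_px) + 1L)
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  m <- matrix(bg, n, n)
  m[d <= radius_px] <- inside
  midplane_image(m, pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
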