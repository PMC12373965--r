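# Small 2D filter primitives used by the processing chain. All filters use
# reflect padding, which avoids edge darkening when subtracting local means.

# reflected index into 1..n (triangular fold, edge duplicated)
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p      # 0 .. 2n-1
  ifelse(j < n, j + 1L, p - j)
}

pad_reflect <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- reflect_idx(seq.int(1L - r, nr + r), nr)
  ci <- reflect_idx(seq.int(1L - r, nc + r), nc)
  img[ri, ci, drop = FALSE]
}

# mean over a (2r+1)^2 window via an integral image, reflect-padded
box_mean <- function(img, k) {
  if (k %% 2 != 1 || k < 3) stop("kernel size must be odd and >= 3",
                                 call. = FALSE)
  r <- (k - 1L) / 2L
  p <- pad_reflect(img, r)
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  nr <- nrow(img); nc <- ncol(img)
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  (s[i1 + k, j1 + k, drop = FALSE] - s[i1, j1 + k, drop = FALSE] -
     s[i1 + k, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (k * k)
}

# separable Gaussian with a (2r+1)-tap kernel, reflect-padded
gaussian_smooth <- function(img, sigma, r = max(1L, ceiling(2 * sigma))) {
  t1 <- seq.int(-r, r)
  k <- exp(-t1^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  p <- pad_reflect(img, r)
  # rows
  acc <- matrix(0, nr, nc + 2L * r)
  for (t in seq_along(k)) {
    acc <- acc + k[t] * p[seq_len(nr) + t - 1L, , drop = FALSE]
  }
  # cols
  out <- matrix(0, nr, nc)
  for (t in seq_along(k)) {
    out <- out + k[t] * acc[, seq_len(nc) + t - 1L, drop = FALSE]
  }
  out
}

# square max filter of radius r (Chebyshev), via shifted pmax with edge clamp
max_filter <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  idx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)
  for (dr in seq.int(-r, r)) {
    shifted_r <- img[idx(nr, dr), , drop = FALSE]
    for (dc in seq.int(-r, r)) {
      out <- pmax(out, shifted_r[, idx(nc, dc), drop = FALSE])
    }
  }
  out
}
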