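# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the implementation they check.

# Median filter: reflect padding, output pixel at offset
# (floor((h-1)/2), floor((w-1)/2)) in the window, lower median.
oracle_median_filter <- function(mat, wh, ww) {
  nr <- nrow(mat); nc <- ncol(mat)
  reflect <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  orow <- (wh - 1) %/% 2
  ocol <- (ww - 1) %/% 2
  out <- mat
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- integer(0)
      for (dr in 0:(wh - 1)) {
        for (dc in 0:(ww - 1)) {
          vals <- c(vals, mat[reflect(r - orow + dr, nr),
                              reflect(c - ocol + dc, nc)])
        }
      }
      sv <- sort(vals)
      out[r, c] <- sv[(length(sv) + 1) %/% 2]  # lower median
    }
  }
  out
}

# Otsu: exhaustive scan of omega0*omega1*(mu1-mu0)^2 over all k with
# 0 < omega(k) < 1; smallest maximizing k.
oracle_otsu <- function(counts) {
  S <- length(counts)
  p <- counts / sum(counts)
  best_k <- NA_integer_
  best <- -Inf
  for (k in seq_len(S - 1)) {
    w0 <- sum(p[1:k])
    if (w0 <= 0 || w0 >= 1) next
    w1 <- 1 - w0
    mu0 <- sum((1:k) * p[1:k]) / w0
    mu1 <- sum(((k + 1):S) * p[(k + 1):S]) / w1
    crit <- w0 * w1 * (mu1 - mu0)^2
    if (is.na(best_k) || crit > best + 1e-12 * max(1, best)) {
      best <- crit
      best_k <- k
    }
  }
  list(k = best_k, criterion = best)
}

# Foreground pixels 8-adjacent to a given background region. `bg_region`
# is a logical matrix; `include_oob` treats out-of-frame as background.
oracle_boundary <- function(mask, bg_region, include_oob = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  res <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          oob <- rr < 1 || rr > nr || cc < 1 || cc > nc
          if (oob) {
            if (include_oob) res[r, c] <- TRUE
          } else if (bg_region[rr, cc]) {
            res[r, c] <- TRUE
          }
        }
      }
    }
  }
  res
}

# A gray_image as a bare integer matrix (drop class and level attributes).
strip_img <- function(img) {
  x <- unclass(img)
  attributes(x) <- list(dim = dim(x))
  x
}

# Coordinates (0-based Y, X) as a canonical sorted key for set comparison.
coord_key <- function(coords) {
  sort(paste(coords[, 1], coords[, 2], sep = ","))
}

mask_key <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  sort(paste(idx[, 1] - 1L, idx[, 2] - 1L, sep = ","))
}

# Random test images under a fixed caller-side seed.
random_gray <- function(nr, nc, S = 256L) {
  gray_image(matrix(sample.int(S, nr * nc, replace = TRUE), nr, nc), S = S)
}

# A blobby random mask: union of a few random disks.
random_blob_mask <- function(n = 24L, ndisks = 3L) {
  m <- matrix(FALSE, n, n)
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  for (i in seq_len(ndisks)) {
    cy <- runif(1, 5, n - 4); cx <- runif(1, 5, n - 4)
    rad <- runif(1, 2, 6)
    m <- m | (sqrt((r - cy)^2 + (c - cx)^2) <= rad)
  }
  m
}

as_binary <- function(mask) {
  structure(mask, class = "binary_image", threshold = NA, polarity = NA)
}
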