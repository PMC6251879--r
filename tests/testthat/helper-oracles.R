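# Brute-force reference implementations used as independent oracles.
# All are naive loops kept deliberately separate from the package's code.

bf_reflect_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

bf_conv_reflect <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  hr <- (kr - 1) %/% 2; hc <- (kc - 1) %/% 2
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    acc <- 0
    for (i in 1:kr) for (j in 1:kc) {
      rr <- bf_reflect_idx(r + i - 1 - hr, nr)
      cc <- bf_reflect_idx(c + j - 1 - hc, nc)
      acc <- acc + img[rr, cc] * kern[i, j]
    }
    out[r, c] <- acc
  }
  out
}

bf_disc_offsets <- function(diameter) {
  rad <- diameter / 2
  R <- floor(rad)
  off <- expand.grid(dr = -R:R, dc = -R:R)
  off[off$dr^2 + off$dc^2 <= rad^2, ]
}

bf_morph <- function(img, diameter, erode) {
  off <- bf_disc_offsets(diameter)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    vals <- c()
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) vals <- c(vals, img[rr, cc])
    }
    out[r, c] <- if (erode) min(vals) else max(vals)
  }
  out
}

bf_tophat <- function(img, diameter) {
  img - bf_morph(bf_morph(img, diameter, TRUE), diameter, FALSE)
}

bf_sobel <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sqrt(bf_conv_reflect(img, kx)^2 + bf_conv_reflect(img, t(kx))^2)
}

# exhaustive local-maxima scan with the same contract as the package:
# in-mask comparisons only, equal-valued neighbours suppress all but the
# lexicographically smallest pixel, and a strictly smaller neighbour must
# exist (constant regions hold no maximum)
bf_maxima <- function(img, mask = NULL, radius = 3) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  res <- NULL
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    keep <- TRUE; any_lower <- FALSE
    for (rr in 1:nr) for (cc in 1:nc) {
      if (rr == r && cc == c) next
      if (!mask[rr, cc]) next
      if ((rr - r)^2 + (cc - c)^2 > radius^2) next
      u <- img[rr, cc]; v <- img[r, c]
      if (u > v || (u == v && (rr < r || (rr == r && cc < c)))) keep <- FALSE
      if (u < v) any_lower <- TRUE
    }
    if (keep && any_lower) res <- rbind(res, c(r, c))
  }
  if (is.null(res)) matrix(integer(), 0, 2) else res
}

# stack-based flood fill from one seed over pixels >= max(frac * seed, floor)
bf_flood <- function(img, seed, frac = 0.5, floor_val = -Inf, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  lim <- max(frac * img[seed[1], seed[2]], floor_val)
  seen <- matrix(FALSE, nrow(img), ncol(img))
  stack <- list(seed)
  out <- NULL
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    r <- p[1]; c <- p[2]
    if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) next
    if (seen[r, c] || !mask[r, c] || img[r, c] < lim) next
    seen[r, c] <- TRUE
    out <- rbind(out, c(r, c))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr || dc) stack[[length(stack) + 1]] <- c(r + dr, c + dc)
    }
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

bf_compactness <- function(px, ints) {
  tot <- sum(ints)
  cr <- sum(px[, 1] * ints) / tot
  cc <- sum(px[, 2] * ints) / tot
  1 / sum(((px[, 1] - cr)^2 + (px[, 2] - cc)^2) * ints)
}

# classical Spearman formula, valid for tie-free rankings
bf_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

sorted_px <- function(m) {
  m <- unname(as.matrix(m)[, 1:2, drop = FALSE])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
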