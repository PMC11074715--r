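# Independent oracles and fixture builders shared across the suite. Every
# oracle here deliberately uses a different algorithm from the package
# implementation it checks.

# queue-based flood fill, 8-connected: returns the number of components
flood_fill_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    n <- n + 1L
    queue <- matrix(c(i, j), 1, 2)
    seen[i, j] <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            !seen[ni, nj] && mask[ni, nj] != 0) {
          seen[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  n
}

# exhaustive Otsu: maximize w0*w1*(m0-m1)^2 over all 256 candidate
# thresholds, smallest maximizer, both classes non-empty
otsu_bruteforce <- function(img) {
  v <- as.integer(round(img))
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:255) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# all-pairs ROC-AUC: ties count one half
auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# direct (non-separable) 2-D convolution with edge replication
convolve_direct <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  kh <- (nrow(kern) - 1) / 2; kw <- (ncol(kern) - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in -kh:kh) for (b in -kw:kw) {
      ii <- min(max(i + a, 1), h); jj <- min(max(j + b, 1), w)
      acc <- acc + img[ii, jj] * kern[a + kh + 1, b + kw + 1]
    }
    out[i, j] <- acc
  }
  out
}

# small-footprint phantom spec for tests (intensity/separability conditions
# are the package defaults; only the image size is scaled down)
test_ranges <- function(noise_sd = 3) {
  r <- phantom_ranges()
  r$side <- c(72, 96)
  r$noise_sd <- c(noise_sd, noise_sd)
  r
}

small_phantom <- function(seed, tumor = TRUE, noise_sd = 3, side = 90) {
  spec <- phantom_spec(height = side, width = side,
                       brain_axes = c(0.36 * side, 0.33 * side),
                       brain_intensity = 125, tumor_present = tumor,
                       tumor_radius = 0.25 * 0.33 * side,
                       tumor_intensity = 215, noise_sd = noise_sd)
  generate_phantom(spec, seed)
}

# segmented classifier-ready image from a small phantom
small_segmented <- function(seed, tumor = TRUE, noise_sd = 3, side = 90,
                            net_side = 144, threshold = NULL) {
  ph <- small_phantom(seed, tumor, noise_sd, side)
  crop <- extract_brain(ph$image)
  segment_pipeline(crop, side = net_side, threshold = threshold)$image
}

random_mask <- function(seed, h, w, p = 0.3) {
  set.seed(seed)
  (matrix(stats::runif(h * w), h, w) < p) * 255
}
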