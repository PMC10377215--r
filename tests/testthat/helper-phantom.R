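# Small test device: 256 x 256 at 0.5 mm isotropic (128 mm FOV) keeps the
# whole anatomy and the 70 mm ROI inside the frame while rendering fast,
# at a resolution where the plate's wavy boundary is well sampled.
test_device <- function(spacing = 0.5, matrix_size = c(256L, 256L),
                        thickness = 4, field = 1.5) {
  device_profile("TestDev", field, spacing, matrix_size, thickness)
}

test_phantom <- function(age = 11, noise_sd = 0, seed = 1, n_slices = 3,
                         device = test_device(), sex = "F") {
  generate_subject(phantom_spec(age = age, sex = sex, device = device,
                                n_slices = n_slices, noise_sd = noise_sd,
                                seed = seed))
}

# Brute-force per-pixel range-threshold oracle.
oracle_threshold <- function(img, tmin, tmax) {
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img)))
      if (img[i, j] >= tmin && img[i, j] <= tmax) out[i, j] <- 1L
  out
}

# Brute-force positive-pixel counting oracle.
oracle_count <- function(mask) {
  n <- 0L
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      if (mask[i, j] != 0) n <- n + 1L
  n
}

# All-pairs Mann-Whitney U oracle for group A (ties count 1/2).
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# BFS 8-connected component count oracle for small masks.
oracle_components8 <- function(mask) {
  m <- mask != 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  ncomp <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j] || seen[i, j]) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            m[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  ncomp
}
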