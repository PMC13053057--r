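# Shared in-code fixtures: small seeded configurations and brute-force
# oracles that recompute results by direct enumeration, independently of the
# implementation paths they check.

small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, field_size_px = c(160L, 160L), duration_h = 6,
         n_cancer = 12L, n_caf = 4L),
    list(...))
  do.call(sim_config, args)
}

noiseless_args <- list(read_sd = 0, shot_scale = 0, gradient_amp = 0)

# Direct-summation local mean: recomputes every window by explicit looping.
brute_local_mean <- function(img, side) {
  r <- (side - 1) / 2
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ri <- max(1, i - r):min(n, i + r)
    rj <- max(1, j - r):min(m, j + r)
    out[i, j] <- sum(img[ri, rj]) / (length(ri) * length(rj))
  }
  out
}

# Exhaustive pixel-enumeration oracles for the proximity metrics.
brute_min_mask_dist <- function(centroid, mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(Inf)
  r0 <- (idx - 1) %% nrow(mask)
  c0 <- (idx - 1) %/% nrow(mask)
  min(sqrt((r0 - centroid[1])^2 + (c0 - centroid[2])^2))
}

brute_min_boundary_dist <- function(centroid, mask) {
  n <- nrow(mask); m <- ncol(mask)
  bnd <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j]) next
    nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
            if (i < n) mask[i + 1, j] else FALSE,
            if (j > 1) mask[i, j - 1] else FALSE,
            if (j < m) mask[i, j + 1] else FALSE)
    if (!all(nb)) bnd[i, j] <- TRUE
  }
  brute_min_mask_dist(centroid, bnd)
}

brute_iou <- function(centroid, mask, radius_px) {
  n <- nrow(mask); m <- ncol(mask)
  disc <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    disc[i, j] <- (i - 1 - centroid[1])^2 + (j - 1 - centroid[2])^2 <= radius_px^2
  a <- sum(mask); inter <- sum(mask & disc); uni <- sum(mask | disc)
  if (a == 0) 0 else inter / uni
}

# Random blob mask: a few rectangles/discs scattered over the field.
random_mask <- function(n = 48, m = 48, n_blobs = 3) {
  mk <- matrix(FALSE, n, m)
  for (b in seq_len(n_blobs)) {
    if (runif(1) < 0.5) {
      r0 <- sample(n - 6, 1); c0 <- sample(m - 6, 1)
      mk[r0:(r0 + sample(5, 1)), c0:(c0 + sample(5, 1))] <- TRUE
    } else {
      cr <- runif(1, 5, n - 5); cc <- runif(1, 5, m - 5); rad <- runif(1, 2, 5)
      for (i in seq_len(n)) for (j in seq_len(m))
        if ((i - 1 - cr)^2 + (j - 1 - cc)^2 <= rad^2) mk[i, j] <- TRUE
    }
  }
  mk
}
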