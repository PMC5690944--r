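# Independent brute-force oracles, deliberately written with plain loops and
# direct formulas so they share no code path with the implementation.

# direct O(N^4) DFT periodogram with the CT-NPS normalisation
oracle_periodogram <- function(patch, spacing) {
  n1 <- nrow(patch); n2 <- ncol(patch)
  out <- matrix(0, n1, n2)
  for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1)) {
    acc <- 0 + 0i
    for (a in 0:(n1 - 1)) for (b in 0:(n2 - 1)) {
      acc <- acc + patch[a + 1, b + 1] *
        exp(-2i * pi * (u * a / n1 + v * b / n2))
    }
    out[u + 1, v + 1] <- Mod(acc)^2
  }
  out * spacing[1] * spacing[2] / (n1 * n2)
}

# voxel-by-voxel error map recomputation
oracle_error_map <- function(gt_vecs, test_vecs) {
  d <- dim(gt_vecs)[1:3]
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    s <- 0
    for (c in 1:3) s <- s + (test_vecs[i, j, k, c] - gt_vecs[i, j, k, c])^2
    out[i, j, k] <- sqrt(s)
  }
  out
}

# independent exhaustive SSD rescan (mean squared difference), returning the
# first minimiser under the smallest-norm then (z, y, x) lexicographic rule
oracle_box_rescan <- function(fixed_vox, moving_vox, center, half, search) {
  best <- NULL
  for (tz in -search[3]:search[3]) for (ty in -search[2]:search[2])
    for (tx in -search[1]:search[1]) {
      s <- 0; n <- 0
      for (dz in -half[3]:half[3]) for (dy in -half[2]:half[2])
        for (dx in -half[1]:half[1]) {
          f <- fixed_vox[center[1] + dx, center[2] + dy, center[3] + dz]
          m <- moving_vox[center[1] + dx + tx, center[2] + dy + ty,
                          center[3] + dz + tz]
          s <- s + (f - m)^2; n <- n + 1
        }
      cand <- list(t = c(tx, ty, tz), msd = s / n,
                   nrm = tx^2 + ty^2 + tz^2)
      if (is.null(best) || cand$msd < best$msd ||
          (cand$msd == best$msd &&
           (cand$nrm < best$nrm ||
            (cand$nrm == best$nrm &&
             (tz < best$t[3] ||
              (tz == best$t[3] && (ty < best$t[2] ||
               (ty == best$t[2] && tx < best$t[1]))))))))
        best <- cand
    }
  best
}

# shared small fixtures ------------------------------------------------------

# deterministic smooth textured volume (sum of sinusoids, no RNG)
textured_volume <- function(d, spacing = c(1, 1, 1)) {
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  g <- outer(outer(sin(0.9 * x), cos(1.3 * y)), sin(0.7 * z)) * 100 +
    outer(outer(cos(0.31 * x), sin(0.23 * y)), cos(0.41 * z)) * 60
  image_volume(array(g, d), spacing = spacing)
}

const_field <- function(d, v, spacing = c(1, 1, 1), direction = "SOT->EOT") {
  vecs <- array(0, c(d, 3))
  for (c in 1:3) vecs[, , , c] <- v[c]
  vector_field(vecs, spacing = spacing, direction = direction)
}
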