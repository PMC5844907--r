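# Fixtures are built in code; nothing is stored on disk.

# A bright disk (tissue) on a dark noisy surround (imaging medium).
make_disk_plane <- function(seed, size = 128, radius = 40,
                            bg = 100, fg = 600, bg_sd = 20, fg_sd = 40) {
  withr::with_seed(seed, {
    p <- matrix(bg + stats::rnorm(size^2, 0, bg_sd), size, size)
    truth <- (row(p) - size / 2)^2 + (col(p) - size / 2)^2 < radius^2
    p[truth] <- fg + stats::rnorm(sum(truth), 0, fg_sd)
    list(plane = pmax(p, 0), truth = truth)
  })
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Independent flood-fill oracle for connected components (26-connectivity in
# 3D, 8 in 2D): plain breadth-first search over an explicit queue.
flood_fill_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) { mask <- array(mask, c(d, 1)); d <- dim(mask) }
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        i <- ci[1] + dx; j <- ci[2] + dy; k <- ci[3] + dz
        if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) next
        if (mask[i, j, k] && lab[i, j, k] == 0L) {
          lab[i, j, k] <- nxt
          queue <- c(queue, (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i)
        }
      }
    }
  }
  lab
}

# voxel sets per component as canonical sorted lists, for label-free
# comparison of two labelings
component_voxel_sets <- function(lab) {
  s <- split(which(lab > 0), lab[lab > 0])
  unname(s[order(vapply(s, min, 0))])
}

# small flat-background stack
constant_stack <- function(value = 50, size = 16, z = 3, bit_depth = 16) {
  image_stack(replicate(z, matrix(value, size, size), simplify = FALSE),
              bit_depth = bit_depth)
}

# phantom small enough for fast tests
tiny_phantom_spec <- function(seed = 3, ...) {
  phantom_spec(dims = c(48, 48, 32), n_spheres = 4, margin = 12,
               min_separation = 8, seed = seed, ...)
}
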