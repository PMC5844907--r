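all_true_masks <- function(stack) {
  replicate(stack$z_count, matrix(TRUE, stack$height, stack$width),
            simplify = FALSE)
}

test_that("MBI propagation matches distributions across planes", {
  A <- withr::with_seed(1, matrix(stats::runif(400, 0, 100), 20, 20))
  cfg <- norm_config(mbi = 60, sfs = 7, reference_plane_index = 1)
  # identical planes: every plane inherits the user's MBI exactly
  st <- image_stack(list(A, A, A))
  prop <- propagate_mbi(st, all_true_masks(st), cfg)
  expect_equal(prop$mbi, rep(60, 3))
  # plane B = 2 * A: the propagated MBI doubles
  st2 <- image_stack(list(A, 2 * A))
  prop2 <- propagate_mbi(st2, all_true_masks(st2), cfg)
  expect_equal(prop2$mbi, c(60, 120))
  expect_true(prop2$uq_rank > 0 && prop2$uq_rank <= 1)
  # an MBI above the whole reference range gives rank 1
  cfg_hi <- norm_config(mbi = 1000, sfs = 7)
  prop3 <- propagate_mbi(st, all_true_masks(st), cfg_hi)
  expect_equal(prop3$uq_rank, 1)
})

test_that("signal removal replaces supra-MBI pixels from the background law", {
  mask <- matrix(TRUE, 10, 10)
  p <- matrix(5, 10, 10)
  res <- remove_signal(p, 10, mask, seed = 1)
  expect_identical(res$plane, p)           # nothing above the MBI
  expect_equal(res$n_replaced, 0)
  p2 <- p; p2[3, 4] <- 100
  res2 <- remove_signal(p2, 10, mask, seed = 1)
  expect_equal(res2$plane[3, 4], 5)        # the only donor value is 5
  expect_equal(res2$n_replaced, 1)
  expect_error(remove_signal(matrix(50, 4, 4), 10, matrix(TRUE, 4, 4)),
               "raise MBI")
})

test_that("replaced values reproduce the donor empirical distribution", {
  n <- 10000
  plane <- withr::with_seed(42, {
    v <- sample(c(1, 2, 3, 5, 8), n, replace = TRUE,
                prob = c(.3, .25, .2, .15, .1))
    sig <- sample(n, n / 10)
    v[sig] <- 100
    matrix(v, 100, 100)
  })
  mask <- matrix(TRUE, 100, 100)
  res <- remove_signal(plane, 10, mask, seed = 7)
  donors <- plane[plane <= 10]
  replaced <- res$plane[plane > 10]
  donor_prob <- table(factor(donors, levels = c(1, 2, 3, 5, 8))) /
    length(donors)
  gof <- stats::chisq.test(table(factor(replaced, levels = c(1, 2, 3, 5, 8))),
                           p = donor_prob)
  expect_gt(gof$p.value, 0.01)
})

test_that("the background mask reproduces flat and ramp backgrounds and applies the floor", {
  cfg <- norm_config(mbi = 60, sfs = 9)
  mask <- matrix(TRUE, 30, 30)
  flat <- matrix(77, 30, 30)
  bg <- compute_background_mask(flat, mask, cfg)
  expect_equal(bg$grid, flat, tolerance = 1e-10)
  expect_false(bg$floor_applied)
  ramp <- outer(seq_len(30), seq_len(30), function(i, j) 2 * i + 3 * j)
  bg2 <- compute_background_mask(ramp, mask, cfg)
  expect_equal(bg2$grid, ramp, tolerance = 1e-8)
  zero <- matrix(0, 30, 30)
  bg3 <- compute_background_mask(zero, mask, cfg)
  expect_true(all(bg3$grid == 1))
  expect_true(bg3$floor_applied)
  expect_error(compute_background_mask(matrix(1, 5, 5), matrix(TRUE, 5, 5),
                                       norm_config(mbi = 10, sfs = 7)),
               "SFS too large")
})

test_that("division normalization satisfies its algebraic identities", {
  mask <- matrix(TRUE, 5, 5)
  M <- list(grid = outer(1:5, 1:5, function(i, j) 100 + 5 * i + 2 * j),
            floor_applied = FALSE)
  # I = M: pure background maps to the constant median of M
  res <- normalize_plane(M$grid, M, mask)
  expect_equal(unique(round(as.vector(res$plane), 9)),
               round(stats::median(M$grid), 9))
  # one pixel at twice the background: ratio preserved
  I2 <- M$grid; I2[2, 3] <- 2 * M$grid[2, 3]
  res2 <- normalize_plane(I2, M, mask)
  expect_equal(res2$plane[2, 3], 2 * stats::median(M$grid))
  # all-false tissue mask: passthrough
  res3 <- normalize_plane(I2, M, matrix(FALSE, 5, 5))
  expect_identical(res3$plane, I2)
})

test_that("signal-to-background ratios survive normalization on a flat background", {
  b <- 100; s <- 700
  p <- matrix(b, 40, 40)
  p[20, 20] <- s
  st <- image_stack(list(p))
  cfg <- norm_config(mbi = 150, sfs = 9, z_mode = "none", seed = 1)
  out <- normalize_stack(st, cfg)$stack$planes[[1]]
  expect_equal(out[20, 20] / out[10, 10], s / b, tolerance = 1e-9)
})

test_that("a flat stack passes through the full pipeline unchanged", {
  st <- constant_stack(50)
  for (zm in c("none", "upper_quantile", "contrast_stretch",
               "semi_quantile")) {
    cfg <- norm_config(mbi = 60, sfs = 7, z_mode = zm)
    out <- normalize_stack(st, cfg)
    expect_equal(max(abs(unlist(out$stack$planes) - 50)), 0,
                 tolerance = 1e-10, info = zm)
  }
})

test_that("background masks recover a multiplicative gradient on noisy planes", {
  spec <- phantom_spec(dims = c(64, 64, 26), n_spheres = 2, margin = 12,
                       min_separation = 8, seed = 5)
  ph <- generate_phantom(spec)
  dst <- apply_distortion(ph, spec, "linear_x")
  mbi <- phantom_user_mbi(spec, dst$field, 13L)
  cfg <- norm_config(mbi = mbi, sfs = 25, reference_plane_index = 13,
                     z_mode = "none", seed = 1)
  xy <- normalize_stack_xy(dst$stack, cfg)
  for (z in seq_len(spec$dims[3])) {
    M <- xy$bg_masks[[z]]
    g <- dst$field[, , z]
    expect_gte(stats::cor(as.vector(M / mean(M)), as.vector(g / mean(g))),
               0.99)
  }
  expect_true(all(vapply(xy$bg_masks, min, 0) >= cfg$mask_floor))
})

test_that("results are bit-identical across reruns and worker counts", {
  spec <- tiny_phantom_spec()
  ph <- generate_phantom(spec)
  cfg <- norm_config(mbi = 450, sfs = 25, reference_plane_index = 16,
                     z_mode = "semi_quantile", seed = 9)
  r1 <- normalize_stack(ph$stack, cfg)
  r2 <- normalize_stack(ph$stack, cfg)
  expect_identical(r1$stack$planes, r2$stack$planes)
  cfg$workers <- 2L
  r3 <- normalize_stack(ph$stack, cfg)
  expect_identical(r1$stack$planes, r3$stack$planes)
})
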