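fake_prop <- function(n, uq_rank) {
  list(uq_rank = uq_rank, skip = rep(FALSE, n))
}

mask_for <- function(p) matrix(TRUE, nrow(p), ncol(p))

test_that("quantile profiles follow the interpolation contract", {
  cfg <- norm_config(mbi = 60, sfs = 7)
  # constant plane: every quantile equals the constant
  p <- matrix(3.5, 10, 10)
  pr <- build_profiles(list(p), list(mask_for(p)), fake_prop(1, 0.9), cfg)[[1]]
  expect_true(all(pr$quantiles == 3.5))
  # values 1..10000 once each: rank 0.5 interpolates to 5000.5
  v <- withr::with_seed(9, matrix(sample(1:10000), 100, 100))
  pr2 <- build_profiles(list(v), list(mask_for(v)), fake_prop(1, 0.9),
                        cfg)[[1]]
  mid <- pr2$quantiles[5000]  # rank 5000/10001
  expect_equal(mid, 1 + (5000 / 10001) * 9999, tolerance = 1e-9)
  expect_equal(stats::quantile(as.vector(v), 0.5, names = FALSE), 5000.5)
  # shift equivariance: profiles of A + 7 differ from A by exactly 7
  A <- withr::with_seed(2, matrix(stats::rnorm(400, 50, 5), 20, 20))
  prs <- build_profiles(list(A, A + 7), list(mask_for(A), mask_for(A)),
                        fake_prop(2, 0.9), cfg)
  expect_equal(prs[[2]]$quantiles - prs[[1]]$quantiles, rep(7, 10000),
               tolerance = 1e-9)
  expect_true(all(diff(prs[[1]]$quantiles) >= 0))
})

test_that("the cross-stack target is the mean of the per-plane profiles", {
  cfg <- norm_config(mbi = 60, sfs = 7)
  A <- withr::with_seed(3, matrix(stats::runif(400, 0, 100), 20, 20))
  prs <- build_profiles(list(A, A * 2), list(mask_for(A), mask_for(A)),
                        fake_prop(2, 0.9), cfg)
  tgt <- build_target(prs, "semi_quantile")
  expect_equal(tgt$target_uq, mean(c(prs[[1]]$uq_value, prs[[2]]$uq_value)))
  expect_equal(tgt$target_quantiles,
               (prs[[1]]$quantiles + prs[[2]]$quantiles) / 2)
  expect_true(all(diff(tgt$target_quantiles) >= 0))
  # single-plane stack: target equals the plane's own profile
  tgt1 <- build_target(prs[1], "semi_quantile")
  expect_equal(tgt1$target_uq, prs[[1]]$uq_value)
  expect_equal(tgt1$target_quantiles, prs[[1]]$quantiles)
})

test_that("upper-quantile mode rescales to the shared upper quantile", {
  cfg <- norm_config(mbi = 60, sfs = 7, z_mode = "upper_quantile")
  A <- withr::with_seed(4, matrix(stats::runif(2500, 10, 100), 50, 50))
  planes <- list(A, 2 * A)
  masks <- list(mask_for(A), mask_for(A))
  prs <- build_profiles(planes, masks, fake_prop(2, 0.95), cfg)
  tgt <- build_target(prs, "upper_quantile")
  outs <- lapply(1:2, function(z)
    apply_upper_quantile(planes[[z]], prs[[z]], tgt, masks[[z]])$plane)
  # scaled versions of the same plane coincide after normalization
  expect_equal(outs[[1]], outs[[2]], tolerance = 1e-12)
  # recomputed upper quantile equals the target
  for (z in 1:2) {
    uq <- stats::quantile(outs[[z]], 0.95, names = FALSE, type = 7)
    expect_equal(uq, tgt$target_uq, tolerance = 1e-9)
  }
  # identity when already at the target
  pr_id <- prs[[1]]; pr_id$uq_value <- tgt$target_uq
  expect_equal(apply_upper_quantile(planes[[1]] * tgt$target_uq /
                                      prs[[1]]$uq_value,
                                    pr_id, tgt, masks[[1]])$plane,
               planes[[1]] * tgt$target_uq / prs[[1]]$uq_value)
})

test_that("contrast stretch applies the anchored affine map with a zero floor", {
  tgt <- list(mode = "contrast_stretch", target_lq = 4, target_uq = 20,
              target_max = 50)
  prof <- list(lq_value = 2, uq_value = 10, max_value = 30, uq_rank = 0.9,
               quantiles = seq(0, 30, length.out = 10000))
  p <- matrix(c(6, 2, 10, 0.5), 2, 2)
  out <- apply_contrast_stretch(p, prof, tgt, matrix(TRUE, 2, 2))$plane
  expect_equal(out[1, 1], 12)  # (6-2)/(10-2)*(20-4)+4
  expect_equal(out[2, 1], 4)
  expect_equal(out[1, 2], 20)
  expect_equal(out[2, 2], 1)   # extrapolated below the anchor, still >= 0
  # severely low pixels clamp at zero
  p2 <- matrix(c(-100, 2, 10, 6), 2, 2)  # synthetic corrected values
  out2 <- apply_contrast_stretch(p2, prof, tgt, matrix(TRUE, 2, 2))$plane
  expect_equal(out2[1, 1], 0)
  # degenerate anchors fall back to the upper-quantile map
  prof_d <- prof; prof_d$lq_value <- 10
  res <- apply_contrast_stretch(p, prof_d, tgt, matrix(TRUE, 2, 2))
  expect_true(res$fallback)
})

test_that("semi-quantile mode matches sub-UQ quantiles and is continuous at the junction", {
  cfg <- norm_config(mbi = 60, sfs = 7, z_mode = "semi_quantile")
  A <- withr::with_seed(6, matrix(stats::rgamma(10000, 4, 0.05), 100, 100))
  B <- sqrt(A) * 30  # monotone transform of A
  planes <- list(A, B)
  masks <- list(mask_for(A), mask_for(A))
  prs <- build_profiles(planes, masks, fake_prop(2, 0.97), cfg)
  tgt <- build_target(prs, "semi_quantile")
  for (z in 1:2) {
    out <- apply_semi_quantile(planes[[z]], prs[[z]], tgt, masks[[z]])$plane
    # pixel exactly at the upper quantile maps to the target upper quantile
    probe <- planes[[z]]; probe[1, 1] <- prs[[z]]$uq_value
    pout <- apply_semi_quantile(probe, prs[[z]], tgt, masks[[z]])$plane
    expect_equal(pout[1, 1], tgt$target_uq, tolerance = 1e-9)
    # monotone: no rank inversions
    o <- order(planes[[z]])
    expect_true(all(diff(out[o]) >= -1e-9))
  }
  # identity when the profile equals the target (single-plane stack)
  tgt1 <- build_target(prs[1], "semi_quantile")
  out1 <- apply_semi_quantile(planes[[1]], prs[[1]], tgt1, masks[[1]])$plane
  expect_equal(out1, planes[[1]], tolerance = 1e-6)
})

test_that("stack-level Z normalization matches upper quantiles for every mode", {
  spec <- tiny_phantom_spec(seed = 8)
  ph <- generate_phantom(spec)
  # per-plane scalar dimming emulating a depth artifact
  fac <- seq(1, 0.4, length.out = ph$stack$z_count)
  planes <- lapply(seq_along(ph$stack$planes),
                   function(z) ph$stack$planes[[z]] * fac[z])
  st <- ph$stack; st$planes <- planes
  for (zm in c("upper_quantile", "contrast_stretch", "semi_quantile")) {
    cfg <- norm_config(mbi = 450, sfs = 25, reference_plane_index = 16,
                       z_mode = zm, seed = 2)
    out <- normalize_stack(st, cfg)
    uqs <- vapply(seq_along(out$stack$planes), function(z)
      stats::quantile(out$stack$planes[[z]][out$masks[[z]]], out$uq_rank,
                      names = FALSE, type = 7), 0)
    # the affine modes hit the target exactly; the semi-quantile junction
    # carries an interpolation error of order one inter-order-statistic gap
    tol <- if (zm == "semi_quantile") 0.01 else 1e-9
    expect_equal(uqs, rep(out$target$target_uq, length(uqs)),
                 tolerance = tol, info = zm)
  }
  # mode none is the identity
  cfg_n <- norm_config(mbi = 450, sfs = 25, reference_plane_index = 16,
                       z_mode = "none", seed = 2)
  xy <- normalize_stack_xy(st, cfg_n)
  zout <- normalize_stack_z(xy$planes, xy$profiles, xy$masks, cfg_n)
  expect_identical(zout$planes, xy$planes)
})
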