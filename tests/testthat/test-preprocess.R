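# Otsu, head-mask morphology, background cleaning, CT intensity transform.

# direct exhaustive between-class variance search over the intensity
# histogram (independent oracle; same binned representation, explicit loop)
otsu_brute <- function(x, nbins = 256) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(pmin(nbins, findInterval(x, edges,
                                              rightmost.closed = TRUE)),
                     nbins)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  best <- -Inf; best_k <- 1
  for (k in 1:(nbins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * centers[(k + 1):nbins]) / n1
    v <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_k <- k }
  }
  edges[best_k + 1]
}

test_that("otsu_threshold equals an exhaustive between-class-variance search", {
  set.seed(10)
  for (rep in 1:8) {
    x <- switch(1 + rep %% 4,
                c(rnorm(400, -1000, 30), rnorm(300, 40, 20)),
                c(runif(500, -100, 100), rnorm(200, 900, 50)),
                rnorm(1000, 0, 50),
                c(rep(-1000, 500), rep(40, 500)) + rnorm(1000, 0, 5))
    expect_equal(otsu_threshold(x), otsu_brute(x), tolerance = 1e-9)
  }
  # two-value image: threshold strictly between the modes
  x2 <- c(rep(-1000, 512), rep(40, 512))
  t2 <- otsu_threshold(x2)
  expect_gt(t2, -1000); expect_lt(t2, 40)
  expect_equal(t2, otsu_brute(x2), tolerance = 1e-9)
})

test_that("otsu threshold is translation equivariant and rejects constants", {
  set.seed(11)
  x <- c(rnorm(300, 0, 10), rnorm(300, 100, 10))
  expect_equal(otsu_threshold(x + 250), otsu_threshold(x) + 250,
               tolerance = 1e-9)
  expect_error(otsu_threshold(rep(3, 100)), "degenerate")
})

test_that("head mask excludes nuisance blobs, is connected and hole-free", {
  ph <- generate_head_phantom(desk_spec())   # 2 blobs + rim by default
  hm <- extract_head_mask(ph$ct)
  expect_gte(dice(hm, ph$masks$head), 0.98)
  expect_equal(mask_n_components(hm), 1)
  # no blob voxels: blobs live outside the true head
  outside_true <- ph$masks$head$data == 0
  blobby <- outside_true & ph$ct$data > -500 & ph$ct$data < 500
  expect_equal(sum(hm$data[blobby]), 0)
  # hole-free: filling is a no-op
  expect_identical(mask_fill_holes(hm)$data, hm$data)
  # all-air volume fails cleanly
  expect_error(extract_head_mask(volume(array(-1000 + rnorm(8^3),
                                              c(8, 8, 8)))),
               "segmentation failure|degenerate")
})

test_that("head mask is invariant to the sub-air rim", {
  with_rim <- generate_head_phantom(desk_spec(seed = 4L))
  no_rim <- generate_head_phantom(desk_spec(seed = 4L, rim_value = -1000))
  m1 <- extract_head_mask(with_rim$ct)
  m2 <- extract_head_mask(no_rim$ct)
  expect_gte(dice(m1, m2), 0.999)
})

test_that("clean_background assigns exactly -1000 outside and is idempotent", {
  ph <- generate_head_phantom(desk_spec())
  hm <- extract_head_mask(ph$ct)
  cc <- clean_background(ph$ct, hm)
  outside <- hm$data == 0
  expect_true(all(cc$data[outside] == -1000))
  expect_equal(min(cc$data), -1000)               # the -3000 rim is gone
  expect_identical(cc$data[!outside], ph$ct$data[!outside])
  expect_identical(clean_background(cc, hm)$data, cc$data)
  # grid mismatch errors
  other <- binary_mask(array(0, c(8, 8, 8)))
  expect_error(clean_background(ph$ct, other), "grid")
})

test_that("CT intensity transform hits the printed anchor points", {
  expect_equal(transform_ct_intensity(-1000), 0)
  expect_equal(transform_ct_intensity(-100), 900)
  expect_equal(transform_ct_intensity(-99), 901)
  expect_equal(transform_ct_intensity(100), 3100)
  expect_equal(transform_ct_intensity(500), 3500)
  # linear interpolation inside segment 1
  expect_equal(transform_ct_intensity(-550), 450)
})

test_that("CT intensity transform is strictly increasing and exactly
           invertible", {
  xs <- seq(-1000, 2000, by = 0.25)
  tx <- transform_ct_intensity(xs)
  expect_true(all(diff(tx) > 0))
  expect_lt(max(abs(inverse_ct_intensity(tx) - xs)), 1e-9)
  set.seed(12)
  xr <- runif(1e4, -1000, 2000)
  expect_lt(max(abs(inverse_ct_intensity(transform_ct_intensity(xr)) - xr)),
            1e-9)
  # inverse of printed endpoints
  expect_equal(inverse_ct_intensity(0), -1000)
  expect_equal(inverse_ct_intensity(3100), 100)
  # domain handling
  expect_message(transform_ct_intensity(-3000), "clamping")
  expect_equal(suppressMessages(transform_ct_intensity(-3000)), 0)
  expect_error(inverse_ct_intensity(-5), "range")
  expect_error(transform_ct_intensity(NaN), "NaN|NA")
  # volumes go through elementwise
  v <- volume(array(c(-1000, -100, 100, 500, 0, 25, 40, 1000), c(2, 2, 2)))
  expect_equal(transform_ct_intensity(v)$data,
               array(transform_ct_intensity(as.vector(v$data)), c(2, 2, 2)))
})

test_that("morphology helpers behave on a simple cube", {
  m <- binary_mask(array(0, c(16, 16, 16)))
  m$data[5:12, 5:12, 5:12] <- 1
  er <- mask_erode(m, 2)
  expect_true(all(er$data <= m$data))
  expect_gt(sum(er$data), 0)
  di <- mask_dilate(m, 2)
  expect_true(all(di$data >= m$data))
  # Euclidean opening rounds the cube edges but keeps the core; an isolated
  # voxel disappears entirely
  op <- mask_open(m, 1)
  expect_true(all(op$data <= m$data))
  expect_true(all(op$data[6:11, 6:11, 6:11] == 1))
  speck <- binary_mask(array(0, c(16, 16, 16)))
  speck$data[3, 3, 3] <- 1
  expect_equal(sum(mask_open(speck, 1)$data), 0)
  holey <- m
  holey$data[8:9, 8:9, 8:9] <- 0
  expect_identical(mask_fill_holes(holey)$data, m$data)
})
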