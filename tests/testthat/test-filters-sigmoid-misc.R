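test_that("flat images give zero response under zero-DC filters", {
  v <- image_volume(array(70, c(16, 16, 2)))
  m <- array(FALSE, c(16, 16, 2)); m[4:13, 4:13, ] <- TRUE
  laws <- filter_response_features(v, m, "Laws")
  expect_true(all(abs(laws) < 1e-8))
  lg <- filter_response_features(v, m, "LoG")
  expect_lt(abs(lg["LoG Z MGI"]), 1e-8)
  expect_equal(unname(lg["LoG Z Entropy"]), 0)
})

test_that("LoG response to an impulse equals the kernel centre weight", {
  dims <- c(21, 21, 1)
  arr <- array(0, dims); arr[11, 11, 1] <- 500
  m <- array(TRUE, dims)
  kern <- dceradiomics:::log_kernel(2)
  resp <- dceradiomics:::conv2d_bank(arr[, , 1], list(kern))[[1]][11, 11, 1]
  centre <- kern[(nrow(kern) + 1) / 2, (ncol(kern) + 1) / 2]
  expect_equal(resp, centre * 500, tolerance = 1e-9)
})

test_that("unknown filter family is rejected with the valid list", {
  f <- tiny_volume()
  expect_error(filter_response_features(f$vol, f$mask, "Sobel"),
               "Gabor, Laws, LoG, DWF")
})

test_that("Gabor statistics are ordered and boundary sets are honoured", {
  f <- tiny_volume(seed = 9)
  g <- filter_response_features(f$vol, f$mask, "Gabor")
  expect_gte(g["Gabor Mean Z"], g["Gabor Min Z"])
  expect_lte(g["Gabor Mean Z"], g["Gabor Max Z"])
  # boundary statistics come only from boundary voxels: verify against a
  # masking oracle computed from the same pooled response
  crop <- dceradiomics:::prepare_filter_crop(f$vol, f$mask)
  kernels <- list()
  for (th in c(0, 45, 90, 135) * pi / 180)
    for (fr in c(0.1, 0.3))
      kernels[[length(kernels) + 1]] <- dceradiomics:::gabor_kernel(fr, th)
  bank <- dceradiomics:::conv2d_bank(crop$stack,
    unlist(lapply(kernels, function(k) list(k$re, k$im)), recursive = FALSE))
  acc <- array(0, dim(crop$stack))
  for (i in seq_along(kernels)) acc <- acc + sqrt(bank[[2*i-1]]^2 + bank[[2*i]]^2)
  acc <- acc / length(kernels)
  expect_equal(unname(g["Gabor Mean Z Boundary"]), mean(acc[crop$shell]))
  expect_equal(unname(g["Gabor Max Z NoBoundary"]),
               max(acc[crop$mask & !crop$shell]))
})

test_that("DWF approximation sums grow with decomposition level", {
  f <- tiny_volume(seed = 3)
  d <- filter_response_features(f$vol, f$mask, "DWF")
  expect_lt(d["DWF Z L"], d["DWF Z LL"])
  expect_lt(d["DWF Z LL"], d["DWF Z LLL"])
})

make_edge_phantom <- function(height = 100, radius = 8, dims = c(31, 31, 3)) {
  ctr <- (dims[1:2] + 1) / 2
  arr <- array(0, dims); m <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    d <- sqrt(outer((seq_len(dims[1]) - ctr[1])^2,
                    (seq_len(dims[2]) - ctr[2])^2, `+`))
    arr[, , k] <- ifelse(d <= radius, height, 0)
    m[, , k] <- d <= radius
  }
  list(vol = image_volume(arr), mask = m)
}

test_that("sigmoid amplitude recovers a known step-edge height", {
  p <- make_edge_phantom(height = 100)
  f <- sigmoid_boundary_features(p$vol, p$mask)
  expect_equal(unname(f["Sigmoid Amplitude Mean"]), 100, tolerance = 0.1)
  expect_lt(f["Sigmoid Amplitude Std"] / 100, 0.1)
  # doubling the edge height doubles the amplitude
  p2 <- make_edge_phantom(height = 200)
  f2 <- sigmoid_boundary_features(p2$vol, p2$mask)
  expect_equal(unname(f2["Sigmoid Amplitude Mean"]),
               2 * unname(f["Sigmoid Amplitude Mean"]), tolerance = 0.02)
})

test_that("sigmoid amplitude vanishes on a constant image", {
  v <- image_volume(array(55, c(21, 21, 2)))
  m <- array(FALSE, c(21, 21, 2)); m[6:15, 6:15, ] <- TRUE
  f <- sigmoid_boundary_features(v, m)
  expect_lt(abs(f["Sigmoid Amplitude Mean"]), 1e-6)
})

test_that("edge frequency is zero on a constant VOI", {
  v <- image_volume(array(55, c(12, 12, 2)))
  m <- array(FALSE, c(12, 12, 2)); m[3:10, 3:10, ] <- TRUE
  f <- misc_texture_features(v, m)
  expect_equal(unname(f["Edge Frequency"]), 0)
})

test_that("box-counting dimension of a line is close to 1", {
  px <- matrix(FALSE, 32, 32); px[16, ] <- TRUE
  expect_equal(unname(dceradiomics:::box_counting_dimension(px)), 1,
               tolerance = 0.15)
})

test_that("spatial correlation is lower for a checkerboard than a smooth VOI", {
  dims <- c(16, 16, 2)
  m <- array(FALSE, dims); m[3:14, 3:14, ] <- TRUE
  chk <- array(0, dims)
  for (k in 1:2) chk[, , k] <- outer(1:16, 1:16, function(r, c) ((r + c) %% 2) * 50)
  f_chk <- misc_texture_features(image_volume(chk), m)
  f_cst <- misc_texture_features(image_volume(array(50, dims)), m)
  expect_lt(f_chk["Spatial Correlation"], f_cst["Spatial Correlation"])
  expect_equal(unname(f_cst["Spatial Correlation"]), 4)  # smooth limit
})
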