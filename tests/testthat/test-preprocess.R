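test_that("histogram equalization follows the explicit CDF oracle", {
  # two-level image: 8 pixels at 0, 8 at 1 -> CDF oracle gives levels 0 and 1
  px <- matrix(rep(c(0, 1), each = 8), 4, 4)
  eq <- equalize_histogram(px, 64)
  expect_equal(sort(unique(as.vector(eq))), c(0, 1))
  expect_equal(eq == 1, px == 1)

  # three-level image, hand-computed CDF mapping with 4 bins:
  # counts (8, 4, 0, 4)/16 -> cdf (.5, .75, .75, 1); rescaled: (0, .5, .5, 1)
  px3 <- matrix(c(rep(0, 8), rep(0.3, 4), rep(0.9, 4)), 4, 4)
  eq3 <- equalize_histogram(px3, 4)
  expect_equal(unique(eq3[px3 == 0]), 0)
  expect_equal(unique(eq3[px3 == 0.3]), 0.5)
  expect_equal(unique(eq3[px3 == 0.9]), 1)
})

test_that("equalization maps constants to themselves and preserves rank order", {
  cst <- matrix(0.4, 5, 5)
  expect_equal(equalize_histogram(cst), cst)

  for (s in 1:20) {
    px <- random_gray(s, 10, levels = 12)
    eq <- equalize_histogram(px, 16)
    expect_true(all(eq >= 0 & eq <= 1))
    # monotone: no pair of pixels swaps order
    o <- order(px)
    expect_true(all(diff(eq[o]) >= -1e-12))
  }
})

test_that("h-maxima transform matches its closed-form cases", {
  cst <- matrix(0.7, 6, 6)
  expect_equal(suppress_maxima(cst, 0.25), matrix(0.45, 6, 6))

  # interior plateau 0.9 on background 0.1, h = 0.3: plateau -> 0.6,
  # background untouched
  img <- matrix(0.1, 9, 9)
  img[4:6, 4:6] <- 0.9
  out <- suppress_maxima(img, 0.3)
  expect_equal(unique(out[img == 0.9]), 0.6)
  expect_equal(unique(out[img == 0.1]), 0.1)

  expect_error(suppress_maxima(img, 0), "in \\(0, 1\\)")
  expect_error(suppress_maxima(img, 1.2), "in \\(0, 1\\)")
})

test_that("h-maxima equals the geodesic-dilation fixpoint oracle", {
  for (s in 1:100) {
    nr <- sample(8:16, 1)
    img <- random_gray(s, nr)
    for (conn in c(4L, 8L)) {
      expect_equal(suppress_maxima(img, 0.2, conn),
                   oracle_hmax(img, 0.2, conn),
                   info = sprintf("seed %d conn %d", s, conn))
    }
  }
})

test_that("h-minima is the exact dual of h-maxima", {
  cst <- matrix(0.3, 5, 5)
  expect_equal(suppress_minima(cst, 0.2), matrix(0.5, 5, 5))

  for (s in 1:25) {
    img <- random_gray(s, 9)
    expect_equal(suppress_minima(img, 0.2),
                 1 - suppress_maxima(1 - img, 0.2))
    expect_equal(suppress_minima(img, 0.2), 1 - oracle_hmax(1 - img, 0.2))
    expect_true(all(suppress_minima(img, 0.2) >= img - 1e-12))
    expect_true(all(suppress_maxima(img, 0.2) <= img + 1e-12))
  }
})

test_that("regional maxima mark exactly the plateaus with no brighter neighbor", {
  expect_true(all(regional_maxima(matrix(0.5, 4, 7))))

  img <- matrix(0.1, 12, 12)
  img[2:4, 2:4] <- 0.9      # plateau A
  img[8:10, 8:10] <- 0.5    # plateau B, separate, still a regional max
  rm1 <- regional_maxima(img)
  expect_true(all(rm1[img == 0.9]))
  expect_true(all(rm1[img == 0.5]))
  expect_false(any(rm1[img == 0.1]))

  for (s in 1:100) {
    img <- random_gray(s + 500, sample(8:16, 1))
    for (conn in c(4L, 8L)) {
      expect_identical(regional_maxima(img, conn),
                       oracle_regional_maxima(img, conn),
                       info = sprintf("seed %d conn %d", s, conn))
    }
  }
})

test_that("the suppression depth dispatches on mean brightness", {
  cfg <- preprocess_config()
  expect_equal(select_h(matrix(0, 4, 4), cfg), cfg$h_dark)
  expect_equal(select_h(matrix(1, 4, 4), cfg), cfg$h_bright)

  # default T2 phantom equalizes to a predominantly dark slice
  ph <- generate_phantom(phantom_spec(seed = 1, sequence = "T2"))
  eq <- equalize_histogram(ph$image)
  expect_lt(mean(eq$pixels), cfg$brightness_split)
  expect_equal(select_h(eq, cfg), cfg$h_dark)
})

test_that("binarize composes the stages and never returns an empty mask", {
  # all-zero image: constant chain ends in an all-ones regional maximum
  z <- gray_image(matrix(0, 8, 8))
  expect_true(all(binarize(z)))

  # composition contract: binarize == regional_maxima . suppress . equalize
  ph <- small_phantom(5)
  cfg <- preprocess_config()
  eq <- equalize_histogram(ph$image$pixels, cfg$n_bins)
  h <- select_h(eq, cfg)
  staged <- regional_maxima(suppress_maxima(eq, h, cfg$connectivity),
                            cfg$connectivity)
  got <- binarize(ph$image, cfg)
  expect_identical(got, staged)
  # the tumor plateau is part of the ROI mask
  expect_true(all(got[ph$gold]))
  expect_gt(sum(got), 0)

  for (s in 1:5) {
    img <- gray_image(random_gray(s, 10))
    expect_gt(sum(binarize(img)), 0)
  }
})
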