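test_that("middle-line scans find the raw support edges", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(scan_edges(full), list(top = 1L, bottom = 10L,
                                      left = 1L, right = 10L))

  m <- matrix(FALSE, 11, 11)
  m[3:9, 3:9] <- TRUE
  expect_equal(scan_edges(m), list(top = 3L, bottom = 9L,
                                   left = 3L, right = 9L))

  # ring mask: scans agree with an exhaustive first/last index search
  ph <- small_phantom(2)
  ring <- binarize(ph$image)
  got <- scan_edges(ring)
  mid_r <- floor(nrow(ring) / 2) + 1
  mid_c <- floor(ncol(ring) / 2) + 1
  expect_equal(got$left, min(which(ring[mid_r, ])))
  expect_equal(got$right, max(which(ring[mid_r, ])))
  expect_equal(got$top, min(which(ring[, mid_c])))
  expect_equal(got$bottom, max(which(ring[, mid_c])))
})

test_that("empty middle lines fall back to nearby lines or fail", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 5:15] <- TRUE
  m[11, ] <- FALSE   # knock out the exact middle row
  expect_warning(e <- scan_edges(m), "middle row empty")
  expect_equal(e[c("left", "right")], list(left = 5L, right = 15L))

  expect_error(suppressWarnings(scan_edges(matrix(FALSE, 20, 20))),
               "edge detection failed")
})

test_that("edge displacement applies offsets, neck correction and clamping", {
  raw <- list(top = 1L, bottom = 100L, left = 1L, right = 100L)
  zero <- edge_offsets(0, 0, 0, 0, 0)
  e0 <- displace_edges(raw, zero, "axial", c(100L, 100L))
  expect_equal(unclass(e0)[c("top", "bottom", "left", "right")],
               list(top = 1L, bottom = 100L, left = 1L, right = 100L))

  off <- edge_offsets(0, 0, 0, d_bottom = 0.05, neck_extra = 0.10)
  expect_equal(displace_edges(raw, off, "coronal", c(100L, 100L))$bottom, 85L)
  expect_equal(displace_edges(raw, off, "sagittal", c(100L, 100L))$bottom, 85L)
  expect_equal(displace_edges(raw, off, "axial", c(100L, 100L))$bottom, 95L)

  cross <- edge_offsets(0.4, 0.4, 0.4, 0.4, 0)
  expect_error(displace_edges(list(top = 40L, bottom = 60L, left = 40L,
                                   right = 60L), cross, "axial",
                              c(100L, 100L)),
               "degenerate")
})

test_that("component tables report correct areas and bounding boxes", {
  m <- matrix(FALSE, 10, 12)
  m[2:4, 2:3] <- TRUE          # area 6, bbox (2,2,4,3)
  m[7:8, 5:9] <- TRUE          # area 10, bbox (7,5,8,9)
  m[10, 12] <- TRUE            # area 1
  ct <- label_components(m, 4)
  expect_equal(sort(ct$areas), c(1L, 6L, 10L))
  expect_equal(max(ct$labels), 3L)
  for (l in seq_along(ct$areas)) {
    px <- which(ct$labels == l, arr.ind = TRUE)
    expect_equal(ct$areas[l], nrow(px))
    expect_equal(unname(ct$bboxes[l, ]),
                 c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2])))
  }
  # labeling itself agrees with the naive flood oracle (up to relabeling)
  for (s in 1:20) {
    m <- random_blobs(s, 14)
    for (conn in c(4L, 8L)) {
      a <- label_components(m, conn)$labels
      b <- oracle_label(m, conn)
      expect_equal(a > 0, b > 0)
      expect_equal(max(a), max(b), info = sprintf("seed %d conn %d", s, conn))
    }
  }
})

test_that("components with any bbox corner outside the rectangle are removed", {
  edges <- structure(list(top = 3L, bottom = 12L, left = 3L, right = 12L),
                     class = "brain_edges")
  m <- matrix(FALSE, 14, 14)
  m[5:7, 5:7] <- TRUE           # fully interior
  expect_identical(remove_external_components(m, edges), m)

  m2 <- m
  m2[1:2, 6:9] <- TRUE          # touches the border outside the rectangle
  expect_identical(remove_external_components(m2, edges), m)

  # straddling: one bbox corner a single pixel outside -> whole component out
  m3 <- matrix(FALSE, 14, 14)
  m3[10:13, 6:8] <- TRUE        # max_row 13 > bottom 12
  expect_identical(remove_external_components(m3, edges),
                   matrix(FALSE, 14, 14))

  for (s in 1:100) {
    m <- random_blobs(s + 100, 16, p = 0.3)
    expect_identical(remove_external_components(m, edges, 4),
                     oracle_remove_external(m, edges, 4),
                     info = paste("seed", s))
  }
})

test_that("the MDC stage strips the skull and keeps interior structure whole", {
  ph <- small_phantom(4)
  roi <- binarize(ph$image)
  res <- mdc_segment(roi, "axial")

  expect_true(all(res$mask[roi == FALSE] == FALSE))   # subset of input
  skull <- ph$image$pixels == 0.85
  expect_equal(sum(res$mask & skull), 0)              # annulus removed
  expect_true(all(res$mask[ph$gold]))                 # tumor survives

  # all-or-nothing per component
  ct <- label_components(roi, 4)
  for (l in seq_along(ct$areas)) {
    kept <- res$mask[ct$labels == l]
    expect_true(all(kept) || !any(kept))
  }

  # all-ones mask with zero offsets is its own single interior component
  ones <- matrix(TRUE, 12, 12)
  r <- mdc_segment(ones, "axial", edge_offsets(0, 0, 0, 0, 0))
  expect_identical(r$mask, ones)

  # content strictly outside the rectangle vanishes
  m <- matrix(FALSE, 30, 30)
  m[14:16, 14:16] <- TRUE       # center content defines the raw edges
  m[1, 1] <- TRUE               # far corner blob
  res2 <- mdc_segment(m, "axial", edge_offsets(0, 0, 0, 0, 0))
  expect_false(res2$mask[1, 1])
  expect_true(all(res2$mask[14:16, 14:16]))
})
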