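test_that("structuring elements match their definitions", {
  box3 <- make_structuring_element("box", 3)
  expect_identical(box3$pattern, matrix(1L, 3, 3))
  disc1 <- make_structuring_element("disc", 1)
  expect_identical(disc1$pattern, matrix(1L, 1, 1))
  disc5 <- make_structuring_element("disc", 5)
  # pixels within Euclidean radius 2.5 of the centre
  expect_identical(colSums(disc5$pattern), c(3, 5, 5, 5, 3))
  expect_identical(disc5$pattern[3, 3], 1L)
  expect_error(make_structuring_element("disc", 4), "odd")
  expect_error(make_structuring_element("box", 0), "odd")
})

test_that("otsu threshold separates well-separated classes and matches the exhaustive oracle", {
  set.seed(3)
  v <- array(sample(c(10, 200), 48 * 48 * 4, TRUE), c(48, 48, 4))
  b <- otsu_threshold(image_stack(v, 0.03))
  expect_true(all(b$voxels == (v > 100)))

  # bimodal 8-bit fixture: threshold equals the brute-force arg-max over
  # all 256 candidate thresholds
  v2 <- array(round(c(rnorm(4000, 60, 12), rnorm(3000, 180, 20))), c(70, 100, 1))
  v2[v2 < 0] <- 0; v2[v2 > 255] <- 255
  b2 <- otsu_threshold(image_stack(v2, 0.03))
  expect_equal(attr(b2, "threshold"), oracle_otsu(as.vector(v2), 0:255))

  expect_error(otsu_threshold(image_stack(array(7, c(4, 4, 4)), 1)),
               "constant")
})

test_that("dilate/erode equal the naive sliding-window oracle", {
  set.seed(4)
  ses <- list(make_structuring_element("box", 3),
              make_structuring_element("disc", 5),
              make_structuring_element("disc", 3))
  for (se in ses) {
    for (rep in 1:3) {
      m <- matrix(rbinom(32 * 32, 1, 0.35), 32, 32)
      expect_identical(dilate(m, se, 1), oracle_morph(m, se$pattern, "dilate"))
      expect_identical(erode(m, se, 1), oracle_morph(m, se$pattern, "erode"))
    }
  }
  # iterated: disc-5, n = 2 equals the oracle applied twice
  m <- matrix(rbinom(32 * 32, 1, 0.35), 32, 32)
  se5 <- make_structuring_element("disc", 5)
  expect_identical(dilate(m, se5, 2),
                   oracle_morph_iter(m, se5$pattern, 2, "dilate"))
  expect_identical(erode(m, se5, 2),
                   oracle_morph_iter(m, se5$pattern, 2, "erode"))
})

test_that("dilation and erosion obey monotonicity, identity and duality", {
  set.seed(5)
  se <- make_structuring_element("disc", 5)
  for (rep in 1:5) {
    m <- matrix(rbinom(24 * 24, 1, 0.4), 24, 24)
    expect_identical(dilate(m, se, 0), {mm <- m; storage.mode(mm) <- "integer"; mm})
    expect_true(all(dilate(m, se, 1) >= m))
    expect_true(all(erode(m, se, 1) <= m))
    # complement duality, exact including borders
    expect_identical(erode(m, se, 2), 1L - dilate(1L - m, se, 2))
  }
  # single pixel under box-3 becomes a 3x3 block
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  d <- dilate(m, make_structuring_element("box", 3), 1)
  expect_identical(sum(d), 9L)
  expect_true(all(d[4:6, 4:6] == 1L))
  # nothing to grow
  expect_identical(sum(dilate(matrix(0L, 8, 8), se, 3)), 0L)
  # erosion pads with foreground: an all-white slice stays white
  expect_true(all(erode(matrix(1L, 8, 8), se, 3) == 1L))
})

test_that("split_bone of a solid disc yields no voids and all-cortical", {
  s <- fixture_disc_stack()
  comp <- split_bone(s)
  expect_identical(sum(comp$voids$voxels), 0L)
  expect_identical(sum(comp$interior$voxels), 0L)
  expect_identical(sum(comp$cancellous$voxels), 0L)
  expect_identical(comp$cortical$voxels, comp$mask$voxels)
})

test_that("split_bone of a hollow annulus recovers voids and cortex exactly", {
  fx <- fixture_annulus_stack()
  comp <- split_bone(fx$stack)
  # hand algebra on the rasterized annulus: the closing fills the hole,
  # voids are the hole, cortex is the ring, no cancellous remains
  expect_identical(comp$mask$voxels, fx$outer$voxels)
  expect_identical(comp$voids$voxels, fx$hole$voxels)
  expect_identical(comp$cortical$voxels, fx$stack$voxels)
  expect_identical(sum(comp$cancellous$voxels), 0L)
})

test_that("split_bone recovers interior specks as cancellous", {
  fx <- fixture_speck_stack()
  for (n_iter in list(c(5, 5), c(6, 6))) {
    comp <- split_bone(fx$stack, n_iter = n_iter)
    expect_gte(dice(comp$cancellous, fx$truth), 0.95)
  }
})

test_that("compartments partition the mask exactly on varied fixtures", {
  fixtures <- list(fixture_disc_stack(), fixture_annulus_stack()$stack,
                   fixture_speck_stack()$stack)
  for (s in fixtures) {
    comp <- split_bone(s)
    part <- comp$voids$voxels + comp$cortical$voxels +
      comp$cancellous$voxels
    expect_true(all(part == comp$mask$voxels))
    expect_true(all(comp$voids$voxels * comp$cortical$voxels == 0))
    expect_true(all(comp$voids$voxels * comp$cancellous$voxels == 0))
    expect_true(all(comp$cortical$voxels * comp$cancellous$voxels == 0))
    expect_identical(comp$interior$voxels,
                     comp$voids$voxels + comp$cancellous$voxels)
    expect_true(all(comp$mask$voxels >= s$voxels))
  }
})

test_that("the closing step is idempotent", {
  se <- make_structuring_element("disc", 5)
  closing <- function(v, n) erode(dilate(v, se, n), se, n)
  for (s in list(fixture_annulus_stack()$stack,
                 fixture_speck_stack()$stack)) {
    once <- closing(s$voxels, 5)
    expect_identical(closing(once, 5), once)
  }
})

test_that("split_bone rejects empty input", {
  empty <- image_stack(array(0L, c(8, 8, 2)), 1, is_binary = TRUE)
  expect_error(split_bone(empty), "nothing to split")
})

test_that("largest_component_filter keeps the dominant blob", {
  v <- array(0L, c(20, 20, 4))
  v[2:6, 2:6, 1:4] <- 1L          # 100 voxels
  v[15, 15, 1:3] <- 1L            # 3 voxels
  s <- image_stack(v, 1, is_binary = TRUE)
  out <- largest_component_filter(s)
  expect_identical(sum(out$voxels), 100L)
  expect_true(all(out$voxels[2:6, 2:6, ] == 1L))
  # single blob: identity
  v2 <- array(0L, c(10, 10, 2)); v2[3:5, 3:5, ] <- 1L
  s2 <- image_stack(v2, 1, is_binary = TRUE)
  expect_identical(largest_component_filter(s2)$voxels, v2)
  # empty stays empty
  e <- image_stack(array(0L, c(5, 5, 2)), 1, is_binary = TRUE)
  expect_identical(sum(largest_component_filter(e)$voxels), 0L)
})
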