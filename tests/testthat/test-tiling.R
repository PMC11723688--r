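test_that("half-overlap mining yields the grid-arithmetic patch count", {
  set.seed(20)
  roi <- list(image = array(runif(512 * 512 * 3), c(512, 512, 3)),
              mask = matrix(1L, 512, 512))
  got <- mine_training_patches(roi, tile = 256, stride = 128)
  expect_length(got, 9)   # (1 + (512-256)/128)^2
  origins <- t(vapply(got, `[[`, c(0, 0), "origin"))
  expect_equal(sort(unique(origins[, 1])), c(0, 128, 256))
})

test_that("patches without tumor surface are dropped by the keep rule", {
  roi <- list(image = array(0.5, c(512, 512, 3)), mask = matrix(0L, 512, 512))
  expect_length(mine_training_patches(roi, tile = 256, stride = 128), 0)
})

test_that("mined patches equal an exhaustive window scan of the mask", {
  set.seed(21)
  mask <- matrix(0L, 96, 96)
  mask[sample(96 * 96, 40)] <- 1L
  roi <- list(image = array(runif(96 * 96 * 3), c(96, 96, 3)), mask = mask)
  got <- mine_training_patches(roi, tile = 32, stride = 16)
  kept <- t(vapply(got, `[[`, c(0, 0), "origin"))
  want <- NULL
  for (oy in seq(0, 64, 16)) for (ox in seq(0, 64, 16)) {
    if (any(mask[oy + 1:32, ox + 1:32] == 1L)) want <- rbind(want, c(oy, ox))
  }
  expect_equal(unname(kept[order(kept[, 1], kept[, 2]), , drop = FALSE]),
               unname(want[order(want[, 1], want[, 2]), , drop = FALSE]))
  # mining is deterministic
  again <- mine_training_patches(roi, tile = 32, stride = 16)
  expect_identical(got, again)
})

test_that("mining rejects regions smaller than one tile", {
  roi <- list(image = array(0.5, c(20, 20, 3)), mask = matrix(1L, 20, 20))
  expect_error(mine_training_patches(roi, tile = 32), "smaller than one")
})

test_that("a 1024 region patchifies into 16 non-overlapping 256 tiles", {
  set.seed(22)
  region <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  pp <- patchify(region, tile = 256)
  expect_length(pp$tiles, 16)
  expect_equal(pp$grid$pad, c(0L, 0L))
  o <- pp$grid$origins
  expect_equal(nrow(unique(o)), 16)          # no duplicated origins
  expect_equal(sort(unique(o[, 1])), c(0L, 256L, 512L, 768L))
  back <- unpatchify(pp$grid, pp$tiles)
  expect_identical(back, region)             # bit-exact round trip
})

test_that("one-tile regions and non-divisible regions round-trip exactly", {
  set.seed(23)
  one <- array(runif(256 * 256 * 3), c(256, 256, 3))
  pp <- patchify(one, tile = 256)
  expect_length(pp$tiles, 1)
  expect_identical(pp$tiles[[1]], one)

  odd <- array(runif(300 * 300 * 3), c(300, 300, 3))
  pp <- patchify(odd, tile = 256)
  expect_length(pp$tiles, 4)
  expect_equal(pp$grid$padded_size, c(512L, 512L))
  expect_identical(unpatchify(pp$grid, pp$tiles), odd)

  gray <- matrix(runif(70 * 45), 70, 45)
  pg <- patchify(gray, tile = 32)
  expect_identical(unpatchify(pg$grid, pg$tiles), gray)
})

test_that("overlapping unpatchify averages then thresholds per pixel", {
  set.seed(24)
  grid <- tile_grid(c(48, 48), tile = 32, stride = 16)
  tiles <- lapply(seq_len(nrow(grid$origins)),
                  function(i) matrix(runif(32 * 32), 32, 32))
  got <- unpatchify(grid, tiles)
  acc <- matrix(0, 48, 48); wt <- matrix(0, 48, 48)
  for (i in seq_len(nrow(grid$origins))) {
    ri <- grid$origins[i, 1] + 1:32
    ci <- grid$origins[i, 2] + 1:32
    acc[ri, ci] <- acc[ri, ci] + tiles[[i]]
    wt[ri, ci] <- wt[ri, ci] + 1
  }
  expect_identical(got, (acc / wt >= 0.5) * 1L)
  const <- unpatchify(grid, lapply(tiles, function(t) t * 0 + 0.7))
  expect_true(all(const == 1L))
})

test_that("tiling input validation rejects malformed requests", {
  expect_error(patchify(array(0, c(0, 4, 3))), "empty")
  expect_error(tile_grid(c(100, 100), tile = 32, stride = 40), "stride")
  grid <- tile_grid(c(64, 64), tile = 32)
  expect_error(unpatchify(grid, list(matrix(0, 32, 32))), "one per grid origin")
})

test_that("overlay tints positives only and respects alpha", {
  set.seed(25)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  mask <- random_mask(20, 20)
  expect_identical(overlay(img, mask, alpha = 0), img)
  full <- overlay(img, matrix(1L, 20, 20), alpha = 1)
  expect_true(all(full[, , 1] == 0) && all(full[, , 3] == 1))
  mid <- overlay(img, mask, alpha = 0.4)
  neg <- mask == 0
  for (ch in 1:3) {
    expect_identical(mid[, , ch][neg], img[, , ch][neg])
  }
  expect_error(overlay(img, matrix(0L, 10, 10)), "do not match")
})
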