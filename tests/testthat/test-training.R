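test_that("augmentation applies identical flips to image and mask", {
  set.seed(40)
  patch <- list(image = array(runif(8 * 8 * 3), c(8, 8, 3)),
                mask = random_mask(8, 8))
  expect_identical(augment(patch, flip_prob = 0), patch)

  both <- augment(patch, flip_prob = 1)   # both flips = 180 degree rotation
  expect_identical(both$mask, patch$mask[8:1, 8:1])
  expect_identical(both$image, patch$image[8:1, 8:1, , drop = FALSE])

  for (i in 1:10) {
    a <- augment(patch, flip_prob = 0.5)
    expect_equal(sum(a$mask), sum(patch$mask))   # flips permute pixels
    # the image/mask pairing never desynchronizes: the multiset of image
    # values under the mask is untouched because both moved together
    expect_equal(sort(a$image[, , 1][a$mask == 1]),
                 sort(patch$image[, , 1][patch$mask == 1]))
  }
})

test_that("best-epoch selection is the argmax with earliest-epoch ties", {
  expect_equal(select_best(data.frame(val_dice = c(0.5, 0.9, 0.7))), 2)
  expect_equal(select_best(data.frame(val_dice = c(0.9, 0.9))), 1)
  expect_equal(select_best(data.frame(val_dice = c(0.1, 0.2, 0.3))), 3)
  expect_error(select_best(data.frame(val_dice = numeric())), "empty")
})

test_that("training is reproducible given the seed and logs sane losses", {
  sets <- tiny_corpus_sets()
  tr <- sets$train[1:8]
  va <- sets$val[1:4]
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 7)
  f1 <- unet_train(unet("vanilla", tiny_net_config(), seed = 3), tr, va, cfg)
  f2 <- unet_train(unet("vanilla", tiny_net_config(), seed = 3), tr, va, cfg)
  expect_identical(f1$log$train_loss[1], f2$log$train_loss[1])
  expect_identical(f1$log, f2$log)
  # soft Dice loss of a near-uniform untrained net is below its ceiling
  expect_lt(f1$log$train_loss[1], 1)
  expect_gt(f1$log$train_loss[1], 0)
})

test_that("an overfit network memorizes a single patch almost perfectly", {
  sets <- tiny_corpus_sets()
  one <- sets$train[which.max(vapply(sets$train,
                                     function(p) sum(p$mask), 0))]
  cfg <- train_config(epochs = 40, batch_size = 1, seed = 5, flip_prob = 0,
                      early_stop_dice = 0.995)
  net <- unet("vanilla", tiny_net_config(), seed = 4)
  fit <- unet_train(net, one, one, cfg)
  pred <- predict_batch(best_network(fit), one[[1]]$image, type = "mask")
  expect_gt(dice(pred, one[[1]]$mask), 0.99)
})

test_that("the best checkpoint reproduces its logged validation Dice", {
  sets <- tiny_corpus_sets()
  tr <- sets$train[1:10]
  va <- sets$val[1:6]
  fit <- unet_train(unet("vanilla", tiny_net_config(), seed = 3), tr, va,
                    train_config(epochs = 3, batch_size = 4, seed = 7))
  ev <- histoseg:::evaluate_patches(best_network(fit), va)
  expect_equal(ev$accuracy_percent / 100, fit$log$val_dice[fit$best_epoch],
               tolerance = 1e-6)
  expect_equal(select_best(fit), fit$best_epoch)

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  ev2 <- histoseg:::evaluate_patches(best_network(back), va)
  expect_equal(ev2$accuracy_percent, ev$accuracy_percent, tolerance = 1e-9)
})

test_that("training rejects empty datasets and mismatched patch shapes", {
  sets <- tiny_corpus_sets()
  net <- unet("vanilla", tiny_net_config())
  expect_error(unet_train(net, list(), sets$val, train_config(epochs = 1)),
               "empty training set")
  expect_error(unet_train(net, sets$train, list(), train_config(epochs = 1)),
               "empty validation set")
  bad <- list(list(image = array(0.5, c(8, 8, 3)), mask = matrix(0L, 8, 8)))
  expect_error(unet_train(net, bad, bad, train_config(epochs = 1)),
               "does not match")
})

test_that("a one-epoch run selects epoch one", {
  sets <- tiny_corpus_sets()
  fit <- unet_train(unet("vanilla", tiny_net_config(), seed = 3),
                    sets$train[1:4], sets$val[1:2],
                    train_config(epochs = 1, batch_size = 4, seed = 1))
  expect_equal(fit$best_epoch, 1)
  expect_equal(nrow(fit$log), 1)
})
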