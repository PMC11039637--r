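cfg64 <- preprocess_config(target_height = 64, target_width = 64)

test_that("bilinear resize: identity, constants, and mask fraction", {
  img <- generate_lesion(lesion_spec(64, 64, 0.25, seed = 1))
  expect_identical(resize_bilinear(img, cfg64), img)
  const <- structure(list(pixels = array(137, c(64, 64, 3)), mask = NULL,
                          label = NULL), class = "lesion_image")
  small <- resize_bilinear(const, preprocess_config(32, 32))
  expect_equal(dim(small$pixels), c(32, 32, 3))
  expect_true(all(abs(small$pixels - 137) < 1e-9))
  down <- resize_bilinear(img, preprocess_config(32, 32))
  expect_equal(dim(down$mask), c(32L, 32L))
  expect_lt(abs(mean(down$mask) - mean(img$mask)), 0.05)
  expect_true(all(down$mask %in% 0:1))
  expect_error(preprocess_config(target_height = 0), "target_height")
})

test_that("colour conversions: HSV definitions and round trips", {
  red <- structure(list(pixels = array(rep(c(255, 0, 0), each = 4),
                                       c(2, 2, 3)),
                        mask = NULL, label = NULL), class = "lesion_image")
  hsv <- convert_color_space(red, "HSV")
  expect_equal(hsv$pixels[1, 1, 1], 0)        # hue 0
  expect_equal(hsv$pixels[1, 1, 2], 255)      # saturation max
  gray_px <- structure(list(pixels = array(123, c(2, 2, 3)), mask = NULL,
                            label = NULL), class = "lesion_image")
  expect_equal(convert_color_space(gray_px, "HSV")$pixels[1, 1, 2], 0)

  img <- generate_lesion(lesion_spec(32, 32, 0.2, seed = 3))
  rt_hsv <- convert_color_space(convert_color_space(img, "HSV"), "RGB")
  expect_lte(max(abs(rt_hsv$pixels - img$pixels)), 1)
  rt_lab <- convert_color_space(convert_color_space(img, "LAB"), "RGB")
  expect_lte(max(abs(rt_lab$pixels - img$pixels)), 2)
  expect_error(convert_color_space(img, "XYZ"), "supported")
  g <- convert_color_space(img, "GRAY")
  expect_true(is.matrix(g$pixels))
})

test_that("CLAHE: constant images unchanged, low contrast enhanced, mask kept", {
  const <- structure(list(pixels = array(90, c(64, 64, 3)),
                          mask = exact_mask(4096, 819, 64), label = NULL),
                     class = "lesion_image")
  out <- equalize_adaptive(const, cfg64)
  expect_equal(out$pixels, const$pixels)
  expect_identical(out$mask, const$mask)

  img <- generate_lesion(lesion_spec(64, 64, 0.2, seed = 5))
  # squash contrast into a narrow band
  low <- img; low$pixels <- 120 + (img$pixels - mean(img$pixels)) * 0.15
  enhanced <- equalize_adaptive(low, cfg64)
  expect_gte(sd(enhanced$pixels), sd(low$pixels))
  expect_identical(enhanced$mask, low$mask)
  expect_true(all(enhanced$pixels >= 0 & enhanced$pixels <= 255))
})

test_that("adaptive median restores impulse noise and passes clean pixels", {
  noisy <- generate_lesion(lesion_spec(64, 64, 0.2, impulse_noise_prob = 0.05,
                                       seed = 9))
  clean <- generate_lesion(lesion_spec(64, 64, 0.2, seed = 9))
  filtered <- filter_adaptive_median(noisy, cfg64)
  corrupted <- which(abs(noisy$pixels - clean$pixels) > 1)
  restored <- mean(abs(filtered$pixels[corrupted] -
                         clean$pixels[corrupted]) <= 10)
  expect_gte(restored, 0.9)
  expect_identical(filter_adaptive_median(clean, cfg64)$pixels, clean$pixels)

  # a single bright impulse in a flat field is removed, all else unchanged
  flat <- array(100, c(32, 32, 3)); flat[16, 16, ] <- 255
  fixed <- filter_adaptive_median(flat, cfg64)
  expect_equal(fixed$pixels[16, 16, 1], 100)
  impulse_idx <- 16 + 15 * 32 + (0:2) * 1024
  expect_equal(fixed$pixels[-impulse_idx], flat[-impulse_idx])
  bad <- cfg64; bad$median_max_window <- 4L
  expect_error(filter_adaptive_median(clean, bad), "median_max_window")
})

test_that("adaptive local filter: identity at zero noise, mean at full ratio, MSE drop", {
  img <- generate_lesion(lesion_spec(64, 64, 0.2, seed = 4))
  cfg0 <- cfg64; cfg0$local_noise_variance <- 0
  expect_equal(filter_adaptive_local(img, cfg0)$pixels, img$pixels)

  # huge assumed noise variance: ratio clips to 1 -> local mean image
  cfgM <- cfg64; cfgM$local_noise_variance <- 1e9
  mean_img <- filter_adaptive_local(img, cfgM)$pixels
  st <- lesionforge:::box_stats(img$pixels[, , 1], cfgM$local_window)
  expect_equal(mean_img[, , 1], clip(st$mean, 0, 255), tolerance = 1e-8)

  speckled <- generate_lesion(lesion_spec(64, 64, 0.2, speckle_variance = 0.02,
                                          seed = 4))
  filtered <- filter_adaptive_local(speckled, cfg64)
  expect_lt(mean((filtered$pixels - img$pixels)^2),
            mean((speckled$pixels - img$pixels)^2))
})

test_that("hair removal: near-no-op without hairs, MSE drop with them, mask kept", {
  for (s in c(1, 8, 14)) {
    img <- generate_lesion(lesion_spec(64, 64, 0.2, seed = s))
    out <- remove_hairs(img, cfg64)
    expect_lt(mean(abs(out$pixels - img$pixels) > 1), 0.01)
    hairy <- generate_lesion(lesion_spec(64, 64, 0.2, hair_count = 5, seed = s))
    cleaned <- remove_hairs(hairy, cfg64)
    expect_lt(mean((cleaned$pixels - img$pixels)^2),
              mean((hairy$pixels - img$pixels)^2))
    expect_identical(cleaned$mask, hairy$mask)
  }
})

test_that("pipeline preserves range/shape and is near-idempotent when clean", {
  img <- generate_lesion(lesion_spec(64, 64, 0.2, seed = 2))
  once <- preprocess(img, cfg64)
  expect_equal(dim(once$pixels), dim(img$pixels))
  expect_true(all(once$pixels >= 0 & once$pixels <= 255))
  expect_identical(once$mask, img$mask)
  twice <- preprocess(once, cfg64)
  expect_lte(mean(abs(twice$pixels - once$pixels)), 3)
})
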