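test_that("default hyperparameter layout enumerates 22 genes", {
  lay <- default_layout()
  expect_equal(nrow(lay), 22)
  expect_equal(sum(lay$field == "kernel_count"), 8)
  expect_equal(sum(lay$field == "kernel_size"), 8)
  expect_equal(sum(lay$field == "pool_size"), 4)
  expect_equal(sum(lay$field == "drop_rate"), 2)
  space <- fcedn_search_space(lay)
  expect_true(all(space$lower < space$upper))
})

test_that("encode/decode round trip is the identity on valid specs", {
  lay <- default_layout(); space <- fcedn_search_space(lay)
  set.seed(10)
  for (i in 1:20) {
    v <- runif(22, space$lower, space$upper)
    spec <- decode_network(v, space, lay)
    expect_identical(decode_network(encode_network(spec, lay), space, lay), spec)
  }
})

test_that("decode rounds integer genes and clips out-of-range values", {
  lay <- default_layout(); space <- fcedn_search_space(lay)
  v <- encode_network(default_fcedn_spec(), lay)
  ks_gene <- which(lay$field == "kernel_size")[1]
  v[ks_gene] <- 3.4
  expect_equal(encode_network(decode_network(v, space, lay), lay)[ks_gene], 3)
  kc_gene <- which(lay$field == "kernel_count")[1]
  v[kc_gene] <- 250
  expect_equal(encode_network(decode_network(v, space, lay), lay)[kc_gene], 200)
  expect_error(decode_network(v[1:10], space, lay),
               class = "lesionforge_structural_error")
})

test_that("any random in-bounds vector decodes to a valid spec", {
  lay <- default_layout(); space <- fcedn_search_space(lay)
  set.seed(20)
  for (i in 1:200) {
    v <- runif(22, space$lower, space$upper)
    expect_no_error(decode_network(v, space, lay))
  }
})

test_that("built network maps input grid to an equal-size probability map", {
  spec <- default_fcedn_spec(32, 32, kernel_count = 20)
  model <- build_network(spec, seed = 1)
  img <- generate_lesion(lesion_spec(32, 32, 0.2, seed = 1))
  p <- lesionforge:::predict_prob(model, img)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))
  # zero image also yields finite probabilities
  zero <- structure(list(pixels = array(0, c(32, 32, 3)), mask = NULL,
                         label = NULL), class = "lesion_image")
  expect_true(all(is.finite(lesionforge:::predict_prob(model, zero))))
})

test_that("indivisible input dimensions are rejected with the pooling product", {
  spec <- default_fcedn_spec(32, 32)
  spec$input_height <- 33L
  expect_error(build_network(spec), "divisible")
})

test_that("parameter count is a deterministic function of the spec", {
  m1 <- build_network(default_fcedn_spec(32, 32, 24), seed = 1)
  m2 <- build_network(default_fcedn_spec(32, 32, 24), seed = 99)
  n1 <- lesionforge:::engine_count_params(m1$engine)
  expect_identical(n1, lesionforge:::engine_count_params(m2$engine))
  # regression value for the light default at 24 kernels:
  # conv stack (3->24 + 7x 24->24 3x3) + 1x1 output head
  expect_equal(n1, (3 * 9 * 24 + 24) + 7 * (24 * 9 * 24 + 24) + (24 + 1))
})

test_that("training drops the loss, is seeded, and epochs=0 is a no-op", {
  data <- tiny_seg_data(n = 8, size = 32)
  model <- build_network(default_fcedn_spec(32, 32, 20), seed = 1)
  same <- train_network(model, data, train_config(epochs = 0))
  expect_identical(same$engine, model$engine)
  expect_length(same$history, 0)

  cfg <- train_config(epochs = 5, batch_size = 4, seed = 2)
  t1 <- train_network(model, data, cfg)
  expect_length(t1$history, 5)
  expect_lt(tail(t1$history, 1), t1$history[1])
  t2 <- train_network(model, data, cfg)
  expect_identical(t1$history, t2$history)

  nomask <- data
  nomask[[1]]$mask <- NULL
  expect_error(train_network(model, nomask, cfg), "mask")
  small <- tiny_seg_data(n = 2, size = 16)
  expect_error(train_network(model, small, cfg), "match the model input")
})

test_that("predicted masks obey the threshold edge rules", {
  data <- tiny_seg_data(n = 6, size = 32)
  model <- fcedn(data, spec = default_fcedn_spec(32, 32, 20),
                 cfg = train_config(epochs = 4, batch_size = 4, seed = 3))
  img <- data[[1]]
  expect_true(all(predict_mask(model, img, threshold = 0) == 1))
  p <- lesionforge:::predict_prob(model, img)
  expect_equal(predict_mask(model, img, threshold = 1), (p >= 1) * 1L)
  # a trained model beats the all-background prediction on its own data
  j_model <- jaccard(predict_mask(model, img), img$mask)
  j_zero <- jaccard(img$mask * 0L, img$mask)
  expect_gt(j_model, j_zero)
})

test_that("training loss trend is monotone up to 20% violations", {
  data <- tiny_seg_data(n = 10, size = 32)
  model <- fcedn(data, spec = default_fcedn_spec(32, 32, 20),
                 cfg = train_config(epochs = 10, batch_size = 4, seed = 7))
  h <- model$history
  violations <- mean(diff(h) > 0)
  expect_lte(violations, 0.2)
})

test_that("checkpoints are self-describing and reload to identical predictions", {
  data <- tiny_seg_data(n = 4, size = 32)
  model <- fcedn(data, spec = default_fcedn_spec(32, 32, 20),
                 cfg = train_config(epochs = 2, batch_size = 4, seed = 1))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fcedn(model, path)
  back <- read_fcedn(path)
  expect_equal(back$spec, model$spec)
  expect_equal(lesionforge:::predict_prob(back, data[[1]]),
               lesionforge:::predict_prob(model, data[[1]]), tolerance = 1e-10)
})
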