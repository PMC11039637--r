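test_that("adaptive CNN softmax outputs are proper and deterministic", {
  cfg <- tiny_cnn_cfg()
  model <- build_adaptive_cnn(cfg)
  img <- generate_lesion(lesion_spec(32, 32, 0.25, seed = 1))
  p <- predict_softmax(model, img)
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  model2 <- build_adaptive_cnn(cfg)   # same seed in cfg
  expect_identical(predict_softmax(model2, img), p)
  expect_error(adaptive_cnn_config(input_size = 30,
                                   conv_blocks = list(c(4, 3), c(8, 3))),
               "pooling depth")
})

test_that("adaptive CNN learns two separable synthetic classes", {
  classes <- tiny_classes(c(2, 3), n = 14)
  imgs <- c(classes[[1]], classes[[2]])
  labels <- rep(1:2, each = 14)
  model <- build_adaptive_cnn(tiny_cnn_cfg())
  model <- train_adaptive_cnn(model, imgs, labels,
                              train_config(epochs = 8, batch_size = 4, seed = 2))
  pred <- vapply(imgs, function(im) which.max(predict_softmax(model, im)),
                 integer(1))
  expect_gte(mean(pred == labels), 0.9)
})

test_that("copy_and_branch preserves old logits and the source model", {
  classes <- tiny_classes(c(2, 3), n = 8)
  model <- build_adaptive_cnn(tiny_cnn_cfg())
  model <- train_adaptive_cnn(model, c(classes[[1]], classes[[2]]),
                              rep(1:2, each = 8),
                              train_config(epochs = 3, batch_size = 4, seed = 2))
  src_weights <- model$engine$layers
  grown <- copy_and_branch(model, 1, seed = 9)
  expect_equal(grown$cfg$n_outputs, 3)
  expect_identical(model$engine$layers, src_weights)   # source untouched
  probe <- generate_lesion(lesion_spec(32, 32, 0.25, class_id = 0, seed = 77))
  x <- lesionforge:::cnn_input(probe, 32)
  old_logits <- lesionforge:::engine_forward(model$engine, x)$out
  new_logits <- lesionforge:::engine_forward(grown$engine, x)$out
  expect_equal(new_logits[1:2], old_logits)
  expect_error(copy_and_branch(model, 0), "n_new_outputs")
})

test_that("warm-started training reaches the accuracy threshold no slower", {
  # paired seeded comparison: epochs until 95% training accuracy on an
  # enlarged class set, warm (copy-and-branch) vs from-scratch
  epochs_to_thresh <- function(model, imgs, labs, seed, thr = 0.95, cap = 12) {
    for (ep in 1:cap) {
      model <- train_adaptive_cnn(model, imgs, labs,
                                  train_config(epochs = 1, batch_size = 4,
                                               seed = seed + ep))
      pred <- vapply(imgs, function(im) which.max(predict_softmax(model, im)),
                     integer(1))
      if (mean(pred == labs) >= thr) return(ep)
    }
    cap + 1
  }
  e_warm <- e_cold <- integer(0)
  for (s in 1:10) {
    classes <- tiny_classes(c(2, 3, 0), n = 8, seed = 30 + s)
    base <- build_adaptive_cnn(tiny_cnn_cfg())
    base <- train_adaptive_cnn(base, c(classes[[1]], classes[[2]]),
                               rep(1:2, each = 8),
                               train_config(epochs = 12, batch_size = 4,
                                            seed = s))
    imgs3 <- c(classes[[1]], classes[[2]], classes[[3]])
    lab3 <- rep(1:3, each = 8)
    e_warm[s] <- epochs_to_thresh(copy_and_branch(base, 1, seed = s),
                                  imgs3, lab3, s)
    cfg3 <- tiny_cnn_cfg(); cfg3$n_outputs <- 3L; cfg3$seed <- as.integer(s)
    e_cold[s] <- epochs_to_thresh(build_adaptive_cnn(cfg3), imgs3, lab3, s)
  }
  expect_gte(sum(e_warm <= e_cold), 6)   # majority of paired runs
  expect_gte(mean(e_cold - e_warm), 0)   # no disadvantage on average
})

test_that("a fresh root grows one leaf per class and classifies separably", {
  classes <- tiny_classes(c(2, 3), n = 12)
  tree <- tree_cnn(classes, tiny_cnn_cfg(), tiny_cls_train(),
                   growth_policy(seed = 3))
  expect_equal(tree_classes(tree), c(2L, 3L))
  expect_length(tree$root$children, 2)
  expect_mapequal(as.list(tree$root$labels_transform),
                  list(`2` = 1L, `3` = 2L))
  held <- tiny_classes(c(2, 3), n = 6, seed = 99)
  acc <- mean(c(predict(tree, held[["2"]]) == 2,
                predict(tree, held[["3"]]) == 3))
  expect_gte(acc, 0.85)
})

test_that("softmax affinity rows sum to 1 and identify a twin class", {
  classes <- tiny_classes(c(2, 3), n = 12)
  tree <- tree_cnn(classes, tiny_cnn_cfg(), tiny_cls_train(),
                   growth_policy(seed = 3))
  # class 8 shares class 2's palette entry (8 %% 6 == 2): a visual twin
  twins <- tiny_classes(8, n = 10, seed = 123)
  aff <- softmax_affinity(tree$root, twins, growth_policy(sample_fraction = 1))
  expect_equal(unname(rowSums(aff)), rep(1, nrow(aff)), tolerance = 1e-6)
  twin_child <- tree$root$labels_transform[["2"]]
  expect_equal(unname(which.max(aff[1, ])), twin_child)
  expect_error(softmax_affinity(tree$root, list(`9` = list()), growth_policy()),
               "at least one image")
})

test_that("growing keeps the leaf-class bijection and conserves classes", {
  classes <- tiny_classes(c(2, 3), n = 12)
  tree <- tree_cnn(classes, tiny_cnn_cfg(), tiny_cls_train(),
                   growth_policy(seed = 3))
  tree2 <- grow_tree(tree, tiny_classes(0, n = 12))
  expect_equal(tree_classes(tree2), c(0L, 2L, 3L))
  paths <- tree_paths(tree2)
  expect_length(paths, 3)
  leaves <- vapply(paths, function(p) tail(p, 1), character(1))
  expect_equal(anyDuplicated(leaves), 0)   # no two classes share a leaf
  expect_error(grow_tree(tree2, tiny_classes(0, n = 4)), "already present")
})

test_that("incremental growth leaves unaffected branch weights bit-identical", {
  classes <- tiny_classes(c(2, 3), n = 12)
  tree <- tree_cnn(classes, tiny_cnn_cfg(), tiny_cls_train(),
                   growth_policy(seed = 3))
  # force two grow operations and compare untouched nodes across them
  tree2 <- grow_tree(tree, tiny_classes(0, n = 12))
  paths2 <- tree_paths(tree2)
  tree3 <- grow_tree(tree2, tiny_classes(1, n = 12))
  touched <- tree_paths(tree3)[["1"]]
  for (cls in names(paths2)) {
    p_old <- paths2[[cls]]
    # nodes of tree2 not on the new class's path must be bit-identical
    untouched_ids <- setdiff(p_old[-1], touched)  # root always retrains
    for (id in untouched_ids) {
      n_old <- find_node(tree2$root, id)
      n_new <- find_node(tree3$root, id)
      if (!n_old$is_leaf) {
        expect_identical(n_new$classifier$engine$layers,
                         n_old$classifier$engine$layers)
      }
    }
  }
  expect_equal(tree_classes(tree3), c(0L, 1L, 2L, 3L))
})

test_that("misrouting at the root is final: descent never recovers", {
  classes <- tiny_classes(c(2, 3), n = 12)
  tree <- tree_cnn(classes, tiny_cnn_cfg(), tiny_cls_train(),
                   growth_policy(seed = 3))
  tree <- grow_tree(tree, tiny_classes(0, n = 12))
  for (im in c(tiny_classes(2, n = 3, seed = 500)[[1]])) {
    res <- classify(tree, im, return_path = TRUE)
    # the leaf reached always lies beneath the child chosen at the root
    first_child_local <- tree$root$labels_transform[[as.character(res$label)]]
    chosen <- which.max(predict_softmax(tree$root$classifier,
                                        im)[seq_along(tree$root$children)])
    expect_equal(first_child_local, chosen)
  }
  # single-leaf subtree always returns its class
  leaf_only <- tree$root$children[[which(vapply(tree$root$children,
                                                function(ch) ch$is_leaf,
                                                logical(1)))[1]]]
  stub <- structure(list(root = leaf_only, cnn_cfg = tree$cnn_cfg,
                         train_cfg = tree$train_cfg, policy = tree$policy),
                    class = "tree_cnn")
  expect_equal(classify(stub, classes[[1]][[1]]), leaf_only$leaf_class)
})
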