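# Adaptive CNN classifier and the Tree-CNN incremental learner.
#
# A Tree-CNN is a hierarchy of classifier nodes: the root CNN routes an
# image to one of its children, branch nodes route further, and each
# leaf is bound to exactly one global class.  New classes are placed by
# average softmax affinity computed on a small seeded sample: a class
# that resembles an existing child is routed under it (a leaf child is
# expanded into a branch), otherwise it becomes a new child.  Every node
# keeps a LabelsTransform lookup table from global class labels to its
# local output indices; only nodes on the path of a new class are
# retrained, so the rest of the tree is left bit-identical.  Training
# images are retained at the leaves so affected nodes can be retrained
# on all classes below them.

#' Configuration of the adaptive CNN node classifier
#'
#' @param input_size square input size in pixels; must be divisible by
#'   `2^length(conv_blocks)` (each block ends in a 2x2 max-pool).
#' @param conv_blocks list of `c(kernel_count, kernel_size)` pairs, one
#'   per convolution block.
#' @param use_batchnorm apply per-channel batch normalisation after each
#'   convolution.
#' @param drop_rates dropout rates applied after flattening (one dropout
#'   layer per entry).
#' @param dense_units width of the hidden dense layer.
#' @param n_outputs number of output classes (>= 2).
#' @param seed weight-initialisation seed.
#' @return an `adaptive_cnn_config`.
#' @export
adaptive_cnn_config <- function(input_size = 32L,
                                conv_blocks = list(c(8, 3), c(16, 3)),
                                use_batchnorm = TRUE, drop_rates = 0.25,
                                dense_units = 32L, n_outputs = 2L,
                                seed = 1L) {
  lf_check(is_count(input_size, 4), "input_size", "must be an integer >= 4")
  lf_check(is.list(conv_blocks) && length(conv_blocks) >= 1, "conv_blocks",
           "must contain at least one block")
  lf_check(is_count(n_outputs, 2), "n_outputs", "must be >= 2")
  lf_check(all(drop_rates >= 0 & drop_rates < 1), "drop_rates",
           "must be proportions in [0, 1)")
  lf_check(is_count(dense_units), "dense_units", "must be a positive integer")
  depth <- length(conv_blocks)
  if (input_size %% (2^depth) != 0) {
    lf_stop(sprintf(
      "input_size %d incompatible with pooling depth %d (needs divisibility by %d)",
      input_size, depth, 2^depth
    ))
  }
  structure(
    list(input_size = as.integer(input_size), conv_blocks = conv_blocks,
         use_batchnorm = isTRUE(use_batchnorm), drop_rates = drop_rates,
         dense_units = as.integer(dense_units),
         n_outputs = as.integer(n_outputs), seed = as.integer(seed)),
    class = "adaptive_cnn_config"
  )
}

#' Build an adaptive CNN classifier
#'
#' Stacks convolution(+relu)(+batchnorm) + max-pool blocks, a flatten
#' layer, dropout, a hidden dense layer and a softmax output over
#' `n_outputs` classes.
#'
#' @param cfg an [adaptive_cnn_config()].
#' @return an untrained `adaptive_cnn` model.
#' @export
build_adaptive_cnn <- function(cfg) {
  lf_check(inherits(cfg, "adaptive_cnn_config"), "cfg",
           "must be an adaptive_cnn_config")
  layers <- list()
  for (b in cfg$conv_blocks) {
    layers <- c(layers, list(
      layer_conv(b[1], b[2], activation = "relu", batchnorm = cfg$use_batchnorm),
      layer_maxpool(2L)
    ))
  }
  layers <- c(layers, list(layer_flatten()))
  for (r in cfg$drop_rates) layers <- c(layers, list(layer_dropout(r)))
  layers <- c(layers, list(
    layer_dense(cfg$dense_units, activation = "relu"),
    layer_dense(cfg$n_outputs, activation = "none")
  ))
  eng <- engine_model(layers, input_dim = c(cfg$input_size, cfg$input_size, 3),
                      loss = "softmax")
  eng <- engine_init(eng, seed = cfg$seed)
  structure(
    list(engine = eng, cfg = cfg, history = numeric(0), trained = FALSE),
    class = "adaptive_cnn"
  )
}

#' @export
print.adaptive_cnn <- function(x, ...) {
  cat(sprintf(
    "adaptive_cnn: %dx%d input, %d conv blocks, %d outputs, %s (%s parameters)\n",
    x$cfg$input_size, x$cfg$input_size, length(x$cfg$conv_blocks),
    x$cfg$n_outputs, if (x$trained) "trained" else "untrained",
    format(engine_count_params(x$engine), big.mark = ",")
  ))
  invisible(x)
}

cnn_input <- function(image, size) {
  im <- as_image(image)
  px <- im$pixels
  if (is.matrix(px)) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[1] != size || dim(px)[2] != size) {
    im <- resize_bilinear(im, preprocess_config(target_height = size,
                                                target_width = size))
    px <- im$pixels
  }
  px / 127.5 - 1
}

#' Train an adaptive CNN on labelled images
#'
#' @param model an `adaptive_cnn`.
#' @param images list of `lesion_image`s (or pixel arrays).
#' @param labels integer vector of local output indices (1-based).
#' @param cfg a [train_config()].
#' @return the trained model with `$history` of per-epoch mean loss.
#' @export
train_adaptive_cnn <- function(model, images, labels,
                               cfg = train_config(epochs = 10L)) {
  lf_check(length(images) == length(labels), "labels",
           "must match images in length")
  lf_check(all(labels >= 1 & labels <= model$cfg$n_outputs), "labels",
           "must be local output indices within 1..n_outputs")
  inputs <- lapply(images, cnn_input, size = model$cfg$input_size)
  fit <- engine_train_loop(
    model$engine, inputs, as.list(as.integer(labels)),
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    lr = cfg$learning_rate, seed = cfg$seed,
    loss_fn = function(out, target) {
      lo <- loss_cross_entropy(out, target)
      list(loss = lo$loss, d_out = lo$dlogits)
    }
  )
  model$engine <- fit$model
  model$history <- c(model$history, fit$history)
  model$trained <- TRUE
  model
}

#' Softmax probabilities of an adaptive CNN
#'
#' @param model a trained (or untrained) `adaptive_cnn`.
#' @param image a `lesion_image` or pixel array.
#' @return probability vector over the node's local outputs (sums to 1).
#' @export
predict_softmax <- function(model, image) {
  x <- cnn_input(image, model$cfg$input_size)
  softmax_vec(engine_forward(model$engine, x, train = FALSE)$out)
}

#' Copy a classifier and branch new output units
#'
#' Creates a new classifier whose shared layers copy the source weights
#' while `n_new_outputs` randomly initialised output units are appended;
#' the source model is left unmodified and the logits of the old classes
#' are identical before any retraining.
#'
#' @param model a trained `adaptive_cnn`.
#' @param n_new_outputs number of output units to append (>= 1).
#' @param seed seed for the new units' initialisation.
#' @return a new `adaptive_cnn` with `n_outputs + n_new_outputs` outputs.
#' @export
copy_and_branch <- function(model, n_new_outputs, seed = 1L) {
  lf_check(is_count(n_new_outputs), "n_new_outputs", "must be >= 1")
  out <- model
  out$cfg$n_outputs <- model$cfg$n_outputs + as.integer(n_new_outputs)
  i_last <- length(out$engine$layers)
  old <- out$engine$layers[[i_last]]
  fan_in <- nrow(old$W)
  new_w <- with_seed(seed, matrix(
    rnorm(fan_in * n_new_outputs, sd = sqrt(2 / fan_in)), fan_in, n_new_outputs
  ))
  out$engine$layers[[i_last]]$W <- cbind(old$W, new_w)
  out$engine$layers[[i_last]]$b <- c(old$b, rep(0, n_new_outputs))
  out$engine$layers[[i_last]]$units <- out$cfg$n_outputs
  out$engine$output_dim <- out$cfg$n_outputs
  out$trained <- FALSE
  out
}

#' Growth policy for the Tree-CNN
#'
#' @param max_children_per_node cap on a node's children.
#' @param sample_fraction fraction of each new class's images used to
#'   compute softmax affinities (the "small sample"; default 0.10).
#' @param merge_enabled when several children pass the affinity
#'   criterion, route into the one with the higher average softmax
#'   (ties broken by seeded random choice).
#' @param affinity_threshold average softmax above which a new class is
#'   routed into an existing child; `NULL` uses the scale-aware default
#'   `2 / (n_children + 1)`.
#' @param max_depth maximum tree depth (root = depth 1; default 2 gives
#'   the two-level root + branch layout).
#' @param seed seed for sampling and tie-breaking.
#' @return a `growth_policy`.
#' @export
growth_policy <- function(max_children_per_node = 10L, sample_fraction = 0.10,
                          merge_enabled = TRUE, affinity_threshold = NULL,
                          max_depth = 2L, seed = 1L) {
  lf_check(is_scalar_num(sample_fraction) && sample_fraction > 0 &&
             sample_fraction <= 1,
           "sample_fraction", "must lie in (0, 1]")
  lf_check(is_count(max_children_per_node, 2), "max_children_per_node",
           "must be >= 2")
  lf_check(is_count(max_depth, 1), "max_depth", "must be >= 1")
  structure(
    list(max_children_per_node = as.integer(max_children_per_node),
         sample_fraction = sample_fraction,
         merge_enabled = isTRUE(merge_enabled),
         affinity_threshold = affinity_threshold,
         max_depth = as.integer(max_depth), seed = as.integer(seed)),
    class = "growth_policy"
  )
}

new_tree_node <- function(node_id, is_leaf = FALSE, leaf_class = NULL) {
  structure(
    list(node_id = node_id, classifier = NULL, children = list(),
         labels_transform = integer(0), is_leaf = is_leaf,
         leaf_class = leaf_class, samples = list()),
    class = "tree_node"
  )
}

#' @export
print.tree_node <- function(x, indent = 0, ...) {
  pad <- strrep("  ", indent)
  if (x$is_leaf) {
    cat(sprintf("%sleaf %s (class %d, %d stored images)\n", pad, x$node_id,
                x$leaf_class, length(x$samples)))
  } else {
    cat(sprintf("%snode %s (%d children)\n", pad, x$node_id, length(x$children)))
    for (ch in x$children) print(ch, indent = indent + 1)
  }
  invisible(x)
}

# all global classes reachable beneath a node
node_classes <- function(node) {
  if (node$is_leaf) return(node$leaf_class)
  sort(unlist(lapply(node$children, node_classes)))
}

# training set of a node: every stored image below child c, local label c
node_training_set <- function(node) {
  images <- list(); labels <- integer(0)
  collect <- function(n) {
    if (n$is_leaf) return(n$samples)
    unlist(lapply(n$children, collect), recursive = FALSE)
  }
  for (ci in seq_along(node$children)) {
    imgs <- collect(node$children[[ci]])
    images <- c(images, imgs)
    labels <- c(labels, rep(ci, length(imgs)))
  }
  list(images = images, labels = labels)
}

# retrain a node's classifier on all classes beneath it.  If the node
# already has a trained classifier with fewer outputs, warm-start by
# copy-and-branch; otherwise build fresh.
retrain_node <- function(node, cnn_cfg, train_cfg) {
  ts <- node_training_set(node)
  n_out <- max(2L, length(node$children))
  if (!is.null(node$classifier) && node$classifier$trained &&
      node$classifier$cfg$n_outputs < n_out) {
    model <- copy_and_branch(node$classifier,
                             n_out - node$classifier$cfg$n_outputs,
                             seed = train_cfg$seed)
  } else if (!is.null(node$classifier) &&
             node$classifier$cfg$n_outputs == n_out &&
             node$classifier$trained) {
    model <- node$classifier
  } else {
    cfg <- cnn_cfg
    cfg$n_outputs <- n_out
    model <- build_adaptive_cnn(cfg)
  }
  node$classifier <- train_adaptive_cnn(model, ts$images, ts$labels, train_cfg)
  node$labels_transform <- stats::setNames(
    unlist(lapply(seq_along(node$children), function(ci) {
      cls <- node_classes(node$children[[ci]])
      stats::setNames(rep(ci, length(cls)), as.character(cls))
    })),
    unlist(lapply(node$children, function(ch) as.character(node_classes(ch))))
  )
  node
}

#' Average softmax affinity of new classes to a node's children
#'
#' For each new class, a seeded `sample_fraction` sample of its images
#' is pushed through the node's classifier; entry (m, c) is the mean
#' softmax probability of child c over class m's sample.  Rows sum to 1.
#'
#' @param node a non-leaf `tree_node` with a trained classifier.
#' @param samples_by_class named list: class label -> list of images.
#' @param policy a [growth_policy()].
#' @return matrix (new classes x children) of average softmax values.
#' @export
softmax_affinity <- function(node, samples_by_class, policy = growth_policy()) {
  lf_check(!is.null(node$classifier) && node$classifier$trained, "node",
           "must have a trained classifier")
  lf_check(length(samples_by_class) >= 1 &&
             all(vapply(samples_by_class, length, 1L) >= 1),
           "samples_by_class", "every class needs at least one image")
  aff <- t(vapply(seq_along(samples_by_class), function(m) {
    imgs <- samples_by_class[[m]]
    n_take <- max(1L, ceiling(policy$sample_fraction * length(imgs)))
    take <- with_seed(derive_seed(policy$seed, m),
                      sample(length(imgs), n_take))
    rowMeans(vapply(imgs[take], function(im) predict_softmax(node$classifier, im),
                    numeric(node$classifier$cfg$n_outputs)))
  }, numeric(node$classifier$cfg$n_outputs)))
  rownames(aff) <- names(samples_by_class)
  aff
}

#' Fit a Tree-CNN on an initial set of classes
#'
#' Builds a fresh root whose children are one leaf per class and trains
#' the root classifier to separate them.
#'
#' @param classes named list: global class label (coercible to integer)
#'   -> list of `lesion_image`s.
#' @param cnn_cfg an [adaptive_cnn_config()] template for node
#'   classifiers (its `n_outputs` is overridden per node).
#' @param train_cfg a [train_config()] for node training.
#' @param policy a [growth_policy()].
#' @return a `tree_cnn` model.
#' @export
tree_cnn <- function(classes, cnn_cfg = adaptive_cnn_config(),
                     train_cfg = train_config(epochs = 10L),
                     policy = growth_policy()) {
  lf_check(length(classes) >= 2, "classes", "need at least two classes")
  root <- new_tree_node("root")
  tree <- structure(
    list(root = root, cnn_cfg = cnn_cfg, train_cfg = train_cfg,
         policy = policy),
    class = "tree_cnn"
  )
  grow_tree(tree, classes)
}

#' Grow a Tree-CNN with new classes
#'
#' Places each new class by softmax affinity: a class whose best average
#' softmax exceeds the add-to-child criterion is routed into that child
#' (a leaf child becomes a branch node over the old and new class; a
#' branch child absorbs the class as a new leaf); otherwise the class
#' becomes a new child of the root.  When several children pass the
#' criterion and merging is enabled, the child with the higher average
#' softmax wins (ties broken by seeded random choice).  Only nodes on an
#' affected path are retrained; every other node is left untouched.
#'
#' @param tree a `tree_cnn`.
#' @param new_classes named list: class label -> list of images.
#' @param policy optional [growth_policy()] override.
#' @return the grown `tree_cnn`.
#' @export
grow_tree <- function(tree, new_classes, policy = NULL) {
  lf_check(inherits(tree, "tree_cnn"), "tree", "must be a tree_cnn")
  policy <- policy %||% tree$policy
  lf_check(!is.null(names(new_classes)) && all(nzchar(names(new_classes))),
           "new_classes", "must be a named list (class label -> images)")
  existing <- node_classes(tree$root)
  for (lab in names(new_classes)) {
    if (as.integer(lab) %in% existing) {
      lf_stop(sprintf("class %s is already present in the tree", lab))
    }
  }
  tree$root <- grow_node(tree$root, new_classes, policy, tree$cnn_cfg,
                         tree$train_cfg, depth = 1L)
  tree
}

grow_node <- function(node, new_classes, policy, cnn_cfg, train_cfg, depth) {
  fresh <- is.null(node$classifier)
  placements <- list()
  if (fresh || length(node$children) == 0) {
    for (lab in names(new_classes)) placements[[lab]] <- 0L  # new leaf
  } else {
    aff <- softmax_affinity(node, new_classes, policy)
    for (m in seq_along(new_classes)) {
      lab <- names(new_classes)[m]
      thr <- policy$affinity_threshold %||% (2 / (length(node$children) + 1))
      cand <- which(aff[m, ] >= thr)
      if (length(cand) == 0 || length(node$children) >= policy$max_children_per_node) {
        placements[[lab]] <- 0L
      } else if (length(cand) == 1 || !policy$merge_enabled) {
        placements[[lab]] <- cand[which.max(aff[m, cand])]
      } else {
        # merge rule: the lower-average-softmax candidate yields to the
        # higher; exact ties are broken by a seeded random choice
        best_val <- max(aff[m, cand])
        top <- cand[aff[m, cand] == best_val]
        placements[[lab]] <- if (length(top) == 1) top else
          with_seed(derive_seed(policy$seed, 7919L + m), sample(top, 1))
      }
    }
  }
  for (lab in names(placements)) {
    target <- placements[[lab]]
    images <- new_classes[[lab]]
    if (target == 0L) {
      leaf <- new_tree_node(paste0(node$node_id, "/", lab), is_leaf = TRUE,
                            leaf_class = as.integer(lab))
      leaf$samples <- images
      node$children <- c(node$children, list(leaf))
    } else {
      child <- node$children[[target]]
      if (child$is_leaf) {
        # expand the leaf into a branch over the old and the new class
        if (depth + 1L > policy$max_depth) {
          # depth cap reached: the class becomes a new root-level child
          leaf <- new_tree_node(paste0(node$node_id, "/", lab),
                                is_leaf = TRUE, leaf_class = as.integer(lab))
          leaf$samples <- images
          node$children <- c(node$children, list(leaf))
        } else {
          branch <- new_tree_node(paste0(node$node_id, "/b", target))
          new_leaf <- new_tree_node(paste0(branch$node_id, "/", lab),
                                    is_leaf = TRUE,
                                    leaf_class = as.integer(lab))
          new_leaf$samples <- images
          branch$children <- list(child, new_leaf)
          branch <- retrain_node(branch, cnn_cfg, train_cfg)
          node$children[[target]] <- branch
        }
      } else {
        sub <- stats::setNames(list(images), lab)
        node$children[[target]] <- grow_node(child, sub, policy, cnn_cfg,
                                             train_cfg, depth + 1L)
      }
    }
  }
  # the (root) node is retrained on all data beneath it
  retrain_node(node, cnn_cfg, train_cfg)
}

#' Classify an image with a Tree-CNN
#'
#' Root-to-leaf descent: at every non-leaf node the child with the
#' highest softmax probability is taken; the reached leaf's class is
#' returned.
#'
#' @param tree a trained `tree_cnn`.
#' @param image a `lesion_image` or pixel array.
#' @param return_path also return the node ids visited.
#' @return the predicted global class label (integer), or a list with
#'   `label` and `path` when `return_path = TRUE`.
#' @export
classify <- function(tree, image, return_path = FALSE) {
  node <- tree$root
  path <- character(0)
  while (!node$is_leaf) {
    if (is.null(node$classifier) || !node$classifier$trained) {
      lf_stop(sprintf("node %s has no trained classifier", node$node_id),
              class = "lesionforge_state_error")
    }
    path <- c(path, node$node_id)
    probs <- predict_softmax(node$classifier, image)
    node <- node$children[[which.max(probs[seq_along(node$children)])]]
  }
  path <- c(path, node$node_id)
  if (return_path) list(label = node$leaf_class, path = path)
  else node$leaf_class
}

#' @rdname classify
#' @param object a `tree_cnn`.
#' @param newdata a `lesion_image` or list of them.
#' @param ... ignored.
#' @export
predict.tree_cnn <- function(object, newdata, ...) {
  single <- inherits(newdata, "lesion_image")
  items <- if (single) list(newdata) else newdata
  out <- vapply(items, function(im) classify(object, im), integer(1))
  if (single) out[[1]] else out
}

#' @export
print.tree_cnn <- function(x, ...) {
  cat(sprintf("tree_cnn over classes {%s}\n",
              paste(node_classes(x$root), collapse = ", ")))
  print(x$root)
  invisible(x)
}

#' Leaf classes of a Tree-CNN (bijection check helper)
#'
#' @param tree a `tree_cnn`.
#' @return sorted integer vector of the classes bound to leaves.
#' @export
tree_classes <- function(tree) node_classes(tree$root)

#' Compose labels_transform tables along the path to each leaf
#'
#' For every class, walks the tree guided by the per-node lookup tables
#' and returns the node ids on the path; used to verify lookup-table
#' invertibility (each class reaches exactly one leaf and that leaf
#' carries the class).
#'
#' @param tree a `tree_cnn`.
#' @return named list: class label -> character vector of node ids.
#' @export
tree_paths <- function(tree) {
  out <- list()
  for (cls in node_classes(tree$root)) {
    node <- tree$root
    path <- character(0)
    while (!node$is_leaf) {
      path <- c(path, node$node_id)
      local <- node$labels_transform[[as.character(cls)]]
      if (is.null(local) || is.na(local)) {
        lf_stop(sprintf("labels_transform at %s lacks class %d",
                        node$node_id, cls))
      }
      node <- node$children[[local]]
    }
    if (node$leaf_class != cls) {
      lf_stop(sprintf("lookup tables route class %d to leaf of class %d",
                      cls, node$leaf_class))
    }
    out[[as.character(cls)]] <- c(path, node$node_id)
  }
  out
}
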