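# FCEDN: fully convolutional encoder-decoder segmentation networks
# described by a flat hyperparameter vector.
#
# The default architecture follows the published composition: an encoder
# of 4 convolution(+relu) layers, 2 max-pooling layers and a dropout
# layer, mirrored by 4 transposed convolutions, 2 unpooling layers and a
# decoder dropout, closed by a 1x1 sigmoid output layer so the output
# grid always equals the input grid.  Its 22 tunable fields (8 kernel
# counts, 8 kernel sizes, 4 pool sizes, 2 drop rates) form the
# hyperparameter vector searched by `spasa()`.

GENE_BOUNDS <- list(
  kernel_count = c(20, 200),
  kernel_size = c(3, 5),
  pool_size = c(2, 3),
  drop_rate = c(0.2, 0.4)
)

#' Default FCEDN hyperparameter vector layout
#'
#' Enumerates the tunable (layer, field) pairs of the default
#' architecture in network order: for the encoder, kernel count and
#' kernel size of each of the 4 convolutions, the 2 pool sizes and the
#' encoder drop rate; then the mirrored decoder fields.  Length 22.
#'
#' @return a `vector_layout` data.frame with columns `gene`, `role`,
#'   `layer` (index within role), `field`, `lower`, `upper`, `integer`.
#' @examples
#' nrow(default_layout())  # 22
#' @export
default_layout <- function() {
  half <- function(conv_role, pool_role) {
    rows <- list(
      c(conv_role, 1, "kernel_count"), c(conv_role, 1, "kernel_size"),
      c(pool_role, 1, "pool_size"),
      c(conv_role, 2, "kernel_count"), c(conv_role, 2, "kernel_size"),
      c(pool_role, 2, "pool_size"),
      c(conv_role, 3, "kernel_count"), c(conv_role, 3, "kernel_size"),
      c(conv_role, 4, "kernel_count"), c(conv_role, 4, "kernel_size"),
      c("dropout", if (conv_role == "conv") 1 else 2, "drop_rate")
    )
    do.call(rbind, lapply(rows, function(r) {
      data.frame(role = r[1], layer = as.integer(r[2]), field = r[3])
    }))
  }
  tab <- rbind(half("conv", "max_pool"), half("transposed_conv", "unpool"))
  b <- t(vapply(tab$field, function(f) GENE_BOUNDS[[f]], numeric(2)))
  layout <- data.frame(
    gene = seq_len(nrow(tab)), tab,
    lower = b[, 1], upper = b[, 2],
    integer = tab$field != "drop_rate"
  )
  rownames(layout) <- NULL
  class(layout) <- c("vector_layout", "data.frame")
  layout
}

#' Search space derived from a vector layout
#'
#' @param layout a [default_layout()]-style layout.
#' @return a `search_space` data.frame with per-gene `lower`, `upper`
#'   and `integer` columns.
#' @export
fcedn_search_space <- function(layout = default_layout()) {
  lf_check(all(layout$lower < layout$upper), "layout",
           "every gene needs lower < upper")
  space <- layout[, c("gene", "lower", "upper", "integer")]
  class(space) <- c("search_space", "data.frame")
  space
}

#' Construct and validate a network specification
#'
#' @param encoder,decoder ordered lists of layer descriptors, each a
#'   list with `kind` (`"conv"`, `"transposed_conv"`, `"max_pool"`,
#'   `"unpool"`, `"dropout"`) and its tunable fields.
#' @param input_height,input_width,input_channels input raster geometry.
#' @return a validated `network_spec`.
#' @export
network_spec <- function(encoder, decoder, input_height = 64L,
                         input_width = 64L, input_channels = 3L) {
  spec <- structure(
    list(encoder = encoder, decoder = decoder,
         input_height = as.integer(input_height),
         input_width = as.integer(input_width),
         input_channels = as.integer(input_channels)),
    class = "network_spec"
  )
  validate_network_spec(spec)
  spec
}

spec_layers <- function(spec) c(spec$encoder, spec$decoder)

count_kind <- function(spec, kind) {
  sum(vapply(spec_layers(spec), function(l) l$kind == kind, logical(1)))
}

validate_network_spec <- function(spec) {
  n_conv <- count_kind(spec, "conv")
  n_tconv <- count_kind(spec, "transposed_conv")
  n_pool <- count_kind(spec, "max_pool")
  n_unpool <- count_kind(spec, "unpool")
  lf_check(n_conv == n_tconv, "spec",
           "number of conv layers must equal number of transposed_conv layers")
  lf_check(n_pool == n_unpool, "spec",
           "number of max_pool layers must equal number of unpool layers")
  for (n in c(n_conv, n_tconv, n_pool, n_unpool)) {
    lf_check(n >= 2 && n <= 10, "spec", "layer counts must lie in [2, 10]")
  }
  for (i in seq_along(spec_layers(spec))) {
    l <- spec_layers(spec)[[i]]
    if (l$kind %in% c("conv", "transposed_conv")) {
      lf_check(l$kernel_size >= 3 && l$kernel_size <= 5,
               sprintf("layer %d kernel_size", i), "must lie in [3, 5]")
      lf_check(l$kernel_count >= 20 && l$kernel_count <= 200,
               sprintf("layer %d kernel_count", i), "must lie in [20, 200]")
    } else if (l$kind %in% c("max_pool", "unpool")) {
      lf_check(l$pool_size >= 2 && l$pool_size <= 3,
               sprintf("layer %d pool_size", i), "must lie in [2, 3]")
    } else if (l$kind == "dropout") {
      lf_check(l$drop_rate >= 0.2 && l$drop_rate <= 0.4,
               sprintf("layer %d drop_rate", i), "must lie in [0.2, 0.4]")
    }
  }
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  fmt <- function(l) {
    switch(l$kind,
      conv = sprintf("conv(%dx%d, %d)", l$kernel_size, l$kernel_size, l$kernel_count),
      transposed_conv = sprintf("tconv(%dx%d, %d)", l$kernel_size, l$kernel_size,
                                l$kernel_count),
      max_pool = sprintf("pool(%d)", l$pool_size),
      unpool = sprintf("unpool(%d)", l$pool_size),
      dropout = sprintf("dropout(%.2f)", l$drop_rate)
    )
  }
  cat(sprintf("network_spec (%dx%dx%d input)\n", x$input_height,
              x$input_width, x$input_channels))
  cat(" encoder:", paste(vapply(x$encoder, fmt, character(1)), collapse = " -> "), "\n")
  cat(" decoder:", paste(vapply(x$decoder, fmt, character(1)), collapse = " -> "),
      "-> conv(1x1, 1) + sigmoid\n")
  invisible(x)
}

# gene value of a spec layer field, and the reverse assignment
spec_field <- function(spec, role, layer_idx, field) {
  layers <- spec_layers(spec)
  hits <- which(vapply(layers, function(l) l$kind == role, logical(1)))
  layers[[hits[layer_idx]]][[field]]
}

#' Encode a network specification as a hyperparameter vector
#'
#' @param spec a [network_spec()] matching the layout's composition.
#' @param layout a [default_layout()]-style layout.
#' @return numeric vector of length `nrow(layout)`.
#' @export
encode_network <- function(spec, layout = default_layout()) {
  for (role in unique(layout$role)) {
    need <- max(layout$layer[layout$role == role])
    have <- count_kind(spec, role)
    if (have < need) {
      lf_stop(sprintf(
        "spec has %d `%s` layers but the layout requires %d (layer index %d)",
        have, role, need, need
      ), class = "lesionforge_structural_error")
    }
  }
  vapply(seq_len(nrow(layout)), function(i) {
    spec_field(spec, layout$role[i], layout$layer[i], layout$field[i])
  }, numeric(1))
}

#' Decode a hyperparameter vector into a network specification
#'
#' Integer genes are rounded to the nearest integer, then all genes are
#' clipped to their bounds; the resulting specification always satisfies
#' the architecture invariants.
#'
#' @param vector numeric gene vector.
#' @param space a [fcedn_search_space()].
#' @param layout the matching [default_layout()].
#' @param input_height,input_width,input_channels input geometry of the
#'   decoded specification.
#' @return a `network_spec`.
#' @export
decode_network <- function(vector, space = fcedn_search_space(layout),
                           layout = default_layout(), input_height = 64L,
                           input_width = 64L, input_channels = 3L) {
  if (length(vector) != nrow(layout)) {
    lf_stop(sprintf("vector length %d does not match layout length %d",
                    length(vector), nrow(layout)),
            class = "lesionforge_structural_error")
  }
  v <- repair_genes(vector, space)
  make_layer <- function(role, idx) {
    sel <- layout$role == role & layout$layer == idx
    fields <- as.list(v[which(sel)])
    names(fields) <- layout$field[sel]
    c(list(kind = role), fields)
  }
  build_half <- function(conv_role, pool_role, drop_idx) {
    list(
      make_layer(conv_role, 1), make_layer(pool_role, 1),
      make_layer(conv_role, 2), make_layer(pool_role, 2),
      make_layer(conv_role, 3), make_layer(conv_role, 4),
      make_layer("dropout", drop_idx)
    )
  }
  network_spec(
    encoder = build_half("conv", "max_pool", 1),
    decoder = build_half("transposed_conv", "unpool", 2),
    input_height = input_height, input_width = input_width,
    input_channels = input_channels
  )
}

# round integer genes, clip everything to bounds
repair_genes <- function(vector, space) {
  v <- as.numeric(vector)
  v[space$integer] <- round(v[space$integer])
  clip(v, space$lower, space$upper)
}

#' Build a trainable FCEDN from a network specification
#'
#' Encoder convolutions use relu activations; spatial reduction happens
#' through the max-pool layers, and the decoder's unpooling layers
#' (nearest-neighbour upsampling by the stored pool size) restore the
#' input grid, so the 1x1 sigmoid output layer has exactly the input's
#' spatial dimensions.
#'
#' @param spec a [network_spec()] (or a gene vector, decoded with the
#'   default layout).
#' @param seed seed for weight initialisation.
#' @param eps smoothing constant of the Jaccard training loss.
#' @return an untrained `fcedn` model object.
#' @export
build_network <- function(spec, seed = 1L, eps = 1) {
  if (is.numeric(spec)) spec <- decode_network(spec)
  validate_network_spec(spec)
  pool_prod <- prod(vapply(
    Filter(function(l) l$kind == "max_pool", spec_layers(spec)),
    function(l) l$pool_size, numeric(1)
  ))
  unpool_prod <- prod(vapply(
    Filter(function(l) l$kind == "unpool", spec_layers(spec)),
    function(l) l$pool_size, numeric(1)
  ))
  if (spec$input_height %% pool_prod != 0 || spec$input_width %% pool_prod != 0) {
    lf_stop(sprintf(
      "input %dx%d must be divisible by the pooling product %d",
      spec$input_height, spec$input_width, pool_prod
    ))
  }
  if (pool_prod != unpool_prod) {
    lf_stop(sprintf(
      "pooling product %d and unpooling product %d must match for the output grid to equal the input grid",
      pool_prod, unpool_prod
    ))
  }
  to_engine <- function(l) {
    switch(l$kind,
      conv = layer_conv(l$kernel_count, l$kernel_size),
      transposed_conv = layer_conv(l$kernel_count, l$kernel_size),
      max_pool = layer_maxpool(l$pool_size),
      unpool = layer_upsample(l$pool_size),
      dropout = layer_dropout(l$drop_rate)
    )
  }
  layers <- c(
    lapply(spec$encoder, to_engine),
    lapply(spec$decoder, to_engine),
    list(layer_conv(1, 1, activation = "sigmoid"))
  )
  eng <- engine_model(layers,
    input_dim = c(spec$input_height, spec$input_width, spec$input_channels),
    loss = "jaccard", eps = eps
  )
  eng <- engine_init(eng, seed = seed)
  stopifnot(identical(
    as.integer(eng$output_dim),
    as.integer(c(spec$input_height, spec$input_width, 1))
  ))
  structure(
    list(spec = spec, engine = eng, history = numeric(0), trained = FALSE,
         eps = eps, seed = as.integer(seed)),
    class = "fcedn"
  )
}

#' Training configuration for the built-in networks
#'
#' @param epochs training epochs (0 allowed: no-op).
#' @param batch_size images per Adam step.
#' @param learning_rate Adam step size.
#' @param seed RNG seed controlling shuffling and dropout.
#' @param max_images cap on the number of training images actually used
#'   (the first `max_images` after a seeded shuffle); `Inf` uses all.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 15L, batch_size = 8L, learning_rate = 1e-3,
                         seed = 1L, max_images = Inf) {
  lf_check(is_count(epochs, 0), "epochs", "must be a nonnegative integer")
  lf_check(is_count(batch_size), "batch_size", "must be a positive integer")
  lf_check(is_scalar_num(learning_rate) && learning_rate > 0,
           "learning_rate", "must be positive")
  lf_check(
    (is_scalar_num(max_images) && max_images >= 1) || is.infinite(max_images),
    "max_images", "must be >= 1"
  )
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed),
         max_images = max_images),
    class = "train_config"
  )
}

# network input: intensities scaled to roughly [-1, 1]
fcedn_input <- function(image) {
  px <- as_image(image)$pixels
  if (is.matrix(px)) px <- array(px, c(dim(px), 1))
  px / 127.5 - 1
}

check_seg_data <- function(model, data) {
  for (i in seq_along(data)) {
    im <- data[[i]]
    lf_check(!is.null(im$mask), sprintf("data[[%d]]$mask", i),
             "training images must carry ground-truth masks")
    ok <- identical(
      as.integer(dim(im$mask)),
      as.integer(c(model$spec$input_height, model$spec$input_width))
    )
    lf_check(ok, sprintf("data[[%d]]", i), sprintf(
      "image size must match the model input (%dx%d)",
      model$spec$input_height, model$spec$input_width
    ))
  }
}

#' Train an FCEDN on masked images
#'
#' Stochastic (Adam) minimisation of `1 - smoothed Jaccard` between the
#' predicted probability map and the ground-truth mask.  Fully seeded:
#' identical data, config and seed give identical histories.
#'
#' @param model an `fcedn` from [build_network()].
#' @param data list of `lesion_image`s with masks, sized like the model
#'   input.
#' @param cfg a [train_config()].
#' @return the trained `fcedn`, with `$history` holding per-epoch mean
#'   training loss (`cfg$epochs` entries).
#' @export
train_network <- function(model, data, cfg = train_config()) {
  lf_check(inherits(model, "fcedn"), "model", "must be an fcedn")
  check_seg_data(model, data)
  if (is.finite(cfg$max_images) && length(data) > cfg$max_images) {
    keep <- with_seed(derive_seed(cfg$seed, 999L),
                      sample(length(data), cfg$max_images))
    data <- data[keep]
  }
  inputs <- lapply(data, fcedn_input)
  masks <- lapply(data, function(im) im$mask)
  eps <- model$eps
  fit <- engine_train_loop(
    model$engine, inputs, masks,
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    lr = cfg$learning_rate, seed = cfg$seed,
    loss_fn = function(out, mask) {
      lo <- loss_soft_jaccard(out, mask, eps)
      list(loss = lo$loss, d_out = lo$dprobs)
    }
  )
  model$engine <- fit$model
  model$history <- c(model$history, fit$history)
  model$trained <- TRUE
  model
}

#' Fit an FCEDN segmentation model
#'
#' Convenience wrapper: decode/validate the architecture, build the
#' network and train it in one call.
#'
#' @param data list of `lesion_image`s with masks.
#' @param spec a `network_spec`, a 22-gene hyperparameter vector, or
#'   `NULL` for the default architecture (all kernel counts 24, kernel
#'   sizes 3, pools 2, drop rates 0.25 -- a light default for CPU use).
#' @param cfg a [train_config()].
#' @param eps smoothing constant of the Jaccard loss.
#' @return a trained `fcedn` model.
#' @export
fcedn <- function(data, spec = NULL, cfg = train_config(), eps = 1) {
  if (is.null(spec)) {
    h <- dim(data[[1]]$pixels)[1]; w <- dim(data[[1]]$pixels)[2]
    spec <- default_fcedn_spec(h, w)
  }
  model <- build_network(spec, seed = cfg$seed, eps = eps)
  train_network(model, data, cfg)
}

#' Default light-weight FCEDN specification
#'
#' @param input_height,input_width input geometry.
#' @param kernel_count kernel count used for every convolution.
#' @return a `network_spec`.
#' @export
default_fcedn_spec <- function(input_height = 64L, input_width = 64L,
                               kernel_count = 24L) {
  layout <- default_layout()
  genes <- ifelse(layout$field == "kernel_count", kernel_count,
           ifelse(layout$field == "kernel_size", 3,
           ifelse(layout$field == "pool_size", 2, 0.25)))
  decode_network(genes, input_height = input_height, input_width = input_width)
}

#' Predict a binary lesion mask
#'
#' @param model a trained `fcedn`.
#' @param image a `lesion_image` (or pixel array) matching the model size.
#' @param threshold probability cut; pixels with probability `>=`
#'   threshold are foreground (so `threshold = 1` keeps exact-1 pixels).
#' @return an HxW 0/1 mask matrix.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- predict_prob(model, image)
  (p >= threshold) * 1L
}

predict_prob <- function(model, image) {
  x <- fcedn_input(image)
  ok <- identical(
    as.integer(dim(x)[1:2]),
    as.integer(c(model$spec$input_height, model$spec$input_width))
  )
  lf_check(ok, "image", sprintf("size must match the model input (%dx%d)",
                                model$spec$input_height, model$spec$input_width))
  out <- engine_forward(model$engine, x, train = FALSE)$out
  matrix(out, dim(out)[1], dim(out)[2])
}

#' @rdname predict_mask
#' @param object a trained `fcedn`.
#' @param newdata a `lesion_image` or list of them.
#' @param type `"mask"` for binary masks, `"prob"` for probability maps.
#' @param ... ignored.
#' @export
predict.fcedn <- function(object, newdata, type = c("mask", "prob"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "lesion_image") || !is.list(newdata)
  items <- if (single) list(newdata) else newdata
  out <- lapply(items, function(im) {
    if (type == "mask") predict_mask(object, im, threshold)
    else predict_prob(object, im)
  })
  if (single) out[[1]] else out
}

#' @export
print.fcedn <- function(x, ...) {
  cat(sprintf("fcedn model (%s, %s parameters)\n",
              if (x$trained) "trained" else "untrained",
              format(engine_count_params(x$engine), big.mark = ",")))
  print(x$spec)
  if (length(x$history)) {
    cat(sprintf(" final training loss: %.4f over %d epochs\n",
                tail(x$history, 1), length(x$history)))
  }
  invisible(x)
}

#' @export
summary.fcedn <- function(object, ...) {
  cat("Fully convolutional encoder-decoder segmentation model\n")
  print(object)
  cat(sprintf(" Jaccard-loss smoothing eps: %g\n", object$eps))
  invisible(object)
}

#' @export
coef.fcedn <- function(object, ...) {
  encode_network(object$spec)
}

#' Serialise / restore an FCEDN checkpoint
#'
#' The checkpoint is a single self-describing JSON file: the network
#' specification as metadata plus all weights.
#'
#' @param model a `fcedn`.
#' @param path output file.
#' @export
write_fcedn <- function(model, path) {
  payload <- list(
    spec = model$spec, eps = model$eps, seed = model$seed,
    history = model$history, trained = model$trained,
    weights = lapply(model$engine$layers, function(ly) {
      if (is.null(ly$W)) NULL else {
        # flatten column-major so the reader can rebuild with matrix()
        list(W = as.vector(ly$W), b = ly$b, dims = dim(ly$W))
      }
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_fcedn
#' @export
read_fcedn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  sp <- payload$spec
  spec <- network_spec(sp$encoder, sp$decoder, sp$input_height,
                       sp$input_width, sp$input_channels)
  model <- build_network(spec, seed = payload$seed, eps = payload$eps)
  for (i in seq_along(model$engine$layers)) {
    wi <- payload$weights[[i]]
    if (!is.null(wi) && !is.null(wi$W)) {
      dims <- as.integer(unlist(wi$dims))
      model$engine$layers[[i]]$W <- matrix(as.numeric(unlist(wi$W)),
                                           dims[1], dims[2])
      model$engine$layers[[i]]$b <- as.numeric(unlist(wi$b))
    }
  }
  model$history <- as.numeric(unlist(payload$history))
  model$trained <- isTRUE(payload$trained)
  model
}
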