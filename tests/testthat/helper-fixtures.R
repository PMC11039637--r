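# Shared fixture builders; everything is generated in code, seeded.

# tiny masked dataset for segmentation tests
tiny_seg_data <- function(n = 6, size = 32, fraction = 0.2, seed = 3) {
  generate_dataset(n, lesion_spec(size, size, fraction), seed = seed)
}

# per-class image lists for classifier tests (classes differ in colour)
tiny_classes <- function(class_ids, n = 10, size = 32, seed = 50) {
  out <- lapply(class_ids, function(cid) {
    generate_dataset(n, lesion_spec(size, size, 0.25, class_id = cid),
                     seed = seed + cid)
  })
  names(out) <- as.character(class_ids)
  out
}

# small classifier/training settings reused across tree tests
tiny_cnn_cfg <- function(size = 32) {
  adaptive_cnn_config(input_size = size, conv_blocks = list(c(6, 3), c(12, 3)),
                      dense_units = 24)
}

tiny_cls_train <- function(seed = 5) {
  train_config(epochs = 8, batch_size = 4, seed = seed)
}

# brute-force per-pixel confusion counting (independent oracle)
oracle_confusion <- function(pred, truth) {
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# brute-force smoothed Jaccard via explicit pixel-set counting
oracle_jaccard <- function(pred, truth, eps = 0) {
  inter <- 0L; np <- 0L; nt <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) inter <- inter + 1L
    if (pred[i] == 1) np <- np + 1L
    if (truth[i] == 1) nt <- nt + 1L
  }
  (eps + inter) / (eps + np + nt - inter)
}

# a mask with an exact foreground count (deterministic layout)
exact_mask <- function(n_pixels, n_fg, nrow = NULL) {
  m <- c(rep(1L, n_fg), rep(0L, n_pixels - n_fg))
  if (is.null(nrow)) nrow <- floor(sqrt(n_pixels))
  matrix(m, nrow = nrow)
}

# slow reference convolution (same zero padding, stride 1)
reference_conv <- function(x, w_mat, b, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  f_out <- length(b)
  pad <- (k - 1) / 2
  out <- array(0, c(H, W, f_out))
  for (f in seq_len(f_out)) {
    wf <- array(w_mat[, f], c(k, k, C))
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- b[f]
        for (c in seq_len(C)) {
          for (ky in seq_len(k)) {
            for (kx in seq_len(k)) {
              ii <- i + ky - 1 - pad; jj <- j + kx - 1 - pad
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
                acc <- acc + x[ii, jj, c] * wf[ky, kx, c]
              }
            }
          }
        }
        out[i, j, f] <- acc
      }
    }
  }
  out
}

# locate a node by id in a tree (recursive)
find_node <- function(node, id) {
  if (node$node_id == id) return(node)
  for (ch in node$children) {
    r <- find_node(ch, id)
    if (!is.null(r)) return(r)
  }
  NULL
}
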