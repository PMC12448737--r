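#' Declarative AttCNN architecture specification
#'
#' Describes the attention-based 1-D convolutional classifier. The canonical
#' baseline wiring is: `conv(1->32, k=3, same, ReLU)` ->
#' `conv(32->64, k=3, same, ReLU)` -> global average pooling of the conv-2
#' map to a channel vector -> a dense layer mapping that vector to one score
#' per position, softmax-normalized into attention weights -> position-wise
#' reweighting of the conv-2 feature map by those weights -> flatten ->
#' `dense(128, ReLU)` -> dropout 0.5 -> `dense(1, sigmoid)`. With "same"
#' padding and stride 1 the position count stays at `input_length`
#' throughout, so the flattened representation has `input_length * 64`
#' entries; at `input_length = 1000` this wiring has exactly 8 263 593
#' trainable parameters.
#'
#' An extended variant adds a symmetric attention block after conv-1 (used
#' only to define the ablation family, see [make_ablation()]); `head = "gap"`
#' replaces the flattened attention-weighted map by the pooled channel
#' vector, which together with no attention blocks yields a plain CNN
#' comparator.
#'
#' @param input_length Number of genes p (positions of the 1-D input, one
#'   channel).
#' @param conv_filters Integer pair, filters of the two conv layers
#'   (default `c(32, 64)`).
#' @param kernel_size Odd kernel width (default 3).
#' @param attention_blocks Character subset of
#'   `c("after_conv1", "after_conv2")`; default `"after_conv2"`.
#' @param dense_units Width of the penultimate dense layer; 0 removes it
#'   (flatten -> dropout -> output).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.5).
#' @param head `"flatten"` (default) or `"gap"`.
#' @return An object of class `attcnn_spec`.
#' @export
attcnn_spec <- function(input_length,
                        conv_filters = c(32L, 64L),
                        kernel_size = 3L,
                        attention_blocks = "after_conv2",
                        dense_units = 128L,
                        dropout_rate = 0.5,
                        head = c("flatten", "gap")) {
  head <- match.arg(head)
  stopifnot(length(conv_filters) == 2L, all(conv_filters >= 1L),
            kernel_size %% 2L == 1L, kernel_size >= 1L,
            dense_units >= 0L, dropout_rate >= 0, dropout_rate < 1,
            all(attention_blocks %in% c("after_conv1", "after_conv2")))
  if (input_length < kernel_size) stop("input_length < kernel_size")
  if (head == "gap" && length(attention_blocks) > 0L &&
      "after_conv2" %in% attention_blocks) {
    stop("head = 'gap' discards positions; incompatible with after_conv2 attention")
  }
  structure(list(input_length = as.integer(input_length),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 attention_blocks = sort(unique(attention_blocks)),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 head = head),
            class = "attcnn_spec")
}

#' @export
print.attcnn_spec <- function(x, ...) {
  tbl <- build_attcnn(x)
  cat(sprintf("AttCNN spec: input length %d, filters (%d, %d), attention: %s\n",
              x$input_length, x$conv_filters[1L], x$conv_filters[2L],
              if (length(x$attention_blocks)) paste(x$attention_blocks, collapse = "+")
              else "none"))
  print(tbl, row.names = FALSE)
  cat(sprintf("total trainable parameters: %s\n",
              format(sum(tbl$params), big.mark = " ")))
  invisible(x)
}

#' Layer table and exact trainable-parameter accounting
#'
#' Expands an [attcnn_spec()] into its layer sequence with output shapes and
#' per-layer trainable-parameter counts, computable from the spec alone.
#'
#' @param spec An `attcnn_spec`.
#' @return `data.frame` with columns `layer`, `output_shape`, `params`.
#' @export
build_attcnn <- function(spec) {
  stopifnot(inherits(spec, "attcnn_spec"))
  p <- spec$input_length
  k <- spec$kernel_size
  f1 <- spec$conv_filters[1L]
  f2 <- spec$conv_filters[2L]
  att1 <- "after_conv1" %in% spec$attention_blocks
  att2 <- "after_conv2" %in% spec$attention_blocks
  rows <- list(
    list("conv1", sprintf("(%d, %d)", p, f1), k * 1L * f1 + f1)
  )
  if (att1) {
    rows <- c(rows, list(
      list("attention1_gap", sprintf("(%d)", f1), 0L),
      list("attention1_dense", sprintf("(%d)", p), f1 * p + p),
      list("attention1_reweight", sprintf("(%d, %d)", p, f1), 0L)
    ))
  }
  rows <- c(rows, list(
    list("conv2", sprintf("(%d, %d)", p, f2), k * f1 * f2 + f2)
  ))
  if (att2) {
    rows <- c(rows, list(
      list("attention2_gap", sprintf("(%d)", f2), 0L),
      list("attention2_dense", sprintf("(%d)", p), f2 * p + p),
      list("attention2_reweight", sprintf("(%d, %d)", p, f2), 0L)
    ))
  }
  if (spec$head == "flatten") {
    feat_dim <- p * f2
    rows <- c(rows, list(list("flatten", sprintf("(%d)", feat_dim), 0L)))
  } else {
    feat_dim <- f2
    rows <- c(rows, list(list("global_average_pool", sprintf("(%d)", feat_dim), 0L)))
  }
  if (spec$dense_units > 0L) {
    rows <- c(rows, list(
      list("dense", sprintf("(%d)", spec$dense_units),
           feat_dim * spec$dense_units + spec$dense_units)
    ))
    out_in <- spec$dense_units
  } else {
    out_in <- feat_dim
  }
  rows <- c(rows, list(
    list("dropout", sprintf("(%d)", out_in), 0L),
    list("output", "(1)", out_in + 1L)
  ))
  data.frame(layer = vapply(rows, `[[`, character(1), 1L),
             output_shape = vapply(rows, `[[`, character(1), 2L),
             params = vapply(rows, function(r) as.integer(r[[3L]]), integer(1)),
             stringsAsFactors = FALSE)
}

#' Total trainable parameters of a spec
#'
#' @param spec An `attcnn_spec`.
#' @return Integer parameter count.
#' @export
attcnn_n_params <- function(spec) sum(build_attcnn(spec)$params)

#' Ablation variants of the AttCNN
#'
#' Structural ablations of the classifier:
#' * `WFAL` — drop the post-conv-1 attention block (requires it in `base`);
#' * `WSAL` — drop the post-conv-2 attention block (requires it in `base`);
#' * `RBAL` — drop all attention blocks (the flattened conv-2 map feeds the
#'   head unweighted); idempotent;
#' * `RFCL` — remove the penultimate dense layer (flatten -> dropout ->
#'   output);
#' * `baseline` — reset to the canonical single-attention wiring.
#'
#' `WFAL`/`WSAL`/`RBAL` are meant to be applied to the two-attention
#' extended spec (`attention_blocks = c("after_conv1", "after_conv2")`), so
#' that each single-attention ablation differs from its parent by exactly
#' one attention block's parameters.
#'
#' @param variant One of `"WFAL"`, `"WSAL"`, `"RBAL"`, `"RFCL"`,
#'   `"baseline"`.
#' @param base An `attcnn_spec` to transform.
#' @return A transformed `attcnn_spec`.
#' @export
make_ablation <- function(variant, base) {
  stopifnot(inherits(base, "attcnn_spec"))
  variant <- match.arg(variant, c("WFAL", "WSAL", "RBAL", "RFCL", "baseline"))
  spec <- base
  if (variant == "WFAL") {
    if (!"after_conv1" %in% base$attention_blocks) {
      stop("WFAL requires a post-conv-1 attention block in the base spec")
    }
    spec$attention_blocks <- setdiff(base$attention_blocks, "after_conv1")
  } else if (variant == "WSAL") {
    if (!"after_conv2" %in% base$attention_blocks) {
      stop("WSAL requires a post-conv-2 attention block in the base spec")
    }
    spec$attention_blocks <- setdiff(base$attention_blocks, "after_conv2")
  } else if (variant == "RBAL") {
    spec$attention_blocks <- character(0)
  } else if (variant == "RFCL") {
    spec$dense_units <- 0L
  } else {
    spec$attention_blocks <- "after_conv2"
    spec$dense_units <- 128L
  }
  spec
}

#' Softmax attention weights
#'
#' Normalizes a vector of attention scores into a probability vector via the
#' softmax, computed with max-subtraction so that extreme scores do not
#' overflow.
#'
#' @param scores Finite numeric vector.
#' @return Probability vector (positive, sums to 1).
#' @export
attention_weights <- function(scores) {
  if (!all(is.finite(scores))) stop("non-finite attention scores")
  e <- exp(scores - max(scores))
  e / sum(e)
}

# row-wise softmax for score matrices (internal fast path)
row_softmax <- function(u) {
  e <- exp(u - apply(u, 1L, max))
  e / rowSums(e)
}

#' Position-wise attention reweighting of a feature map
#'
#' Scales each position (row) of a positions x channels feature map by its
#' attention weight: `out[i, c] = alpha[i] * features[i, c]`. Summing the
#' output over positions reproduces the attention context vector
#' \eqn{c = \sum_i \alpha_i h_i}; keeping positions (rather than summing
#' immediately) preserves the per-position resolution that the flattened
#' dense layer consumes.
#'
#' @param features Numeric matrix, positions x channels.
#' @param alpha Weight vector, one entry per position.
#' @return Matrix of the same shape.
#' @export
context_reweight <- function(features, alpha) {
  features <- as.matrix(features)
  if (length(alpha) != nrow(features)) stop("alpha/position shape mismatch")
  features * as.numeric(alpha)
}

#' Global average pooling of a feature map
#'
#' Channel-wise mean over positions: `g[c] = mean(features[, c])`.
#'
#' @param features Numeric matrix, positions x channels (>= 1 position).
#' @return Channel vector.
#' @export
global_average_pool <- function(features) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 1L)
  colMeans(features)
}

#' Write the layer table as TSV
#'
#' Emits `layer<TAB>output_shape<TAB>params`.
#'
#' @param spec An `attcnn_spec`.
#' @param path Output path.
#' @export
write_attcnn_summary <- function(spec, path) {
  utils::write.table(build_attcnn(spec), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
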