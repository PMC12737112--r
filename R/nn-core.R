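# Seeded neural-network core: per-timestep dense stacks on top of an
# optional bidirectional LSTM, trained with minibatch Adam.  Parameter
# initialization, batch shuffling, early stopping and checkpointing live in
# R; the batched forward/backward/update kernels live in src/nn.cpp and
# operate on a flat parameter vector.  Batch inputs are 3-d arrays
# [n, T, d].  Gradients are verified against central finite differences in
# the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# LSTM parameter block for one direction; gate order (i, f, g, o), the
# forget-gate bias initialized to 1 (standard practice for short sequences).
lstm_init <- function(d, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(W = glorot(d, 4 * h), U = glorot(h, 4 * h), b = b)
}

# Build a sequence network: optional BiLSTM (units per direction), dense
# ReLU widths, output width + activation.  All weights drawn reproducibly
# from `seed`.
nn_init <- function(d_in, bilstm, dense, d_out, out_act, seed) {
  set.seed(seed)
  p <- list(bilstm = NULL, dense = list(), out = NULL)
  d <- d_in
  if (bilstm > 0L) {
    p$bilstm <- list(fwd = lstm_init(d, bilstm), bwd = lstm_init(d, bilstm))
    d <- 2L * bilstm
  }
  for (w in dense) {
    p$dense[[length(p$dense) + 1L]] <- list(W = glorot(d, w), b = numeric(w))
    d <- w
  }
  if (length(p$dense) > 0L) names(p$dense) <- paste0("d", seq_along(p$dense))
  p$out <- list(W = glorot(d, d_out), b = numeric(d_out))
  attr(p, "arch") <- list(d_in = d_in, bilstm = bilstm, dense = dense,
                          d_out = d_out, out_act = out_act)
  p
}

nn_n_params <- function(p) {
  sum(vapply(param_leaves(p), length, integer(1)))
}

# x: array [n, T, d] -> list of T matrices [n, d]
split_steps <- function(x) {
  n <- dim(x)[1L]; Tn <- dim(x)[2L]; d <- dim(x)[3L]
  lapply(seq_len(Tn), function(t) {
    m <- x[, t, , drop = FALSE]
    dim(m) <- c(n, d)
    m
  })
}

cpp_arch <- function(p) {
  arch <- attr(p, "arch")
  list(d_in = as.integer(arch$d_in), bilstm = as.integer(arch$bilstm),
       dense = as.integer(arch$dense), d_out = as.integer(arch$d_out),
       out_act = arch$out_act)
}

# Flatten structured parameters to the canonical flat vector consumed by
# the C++ kernels (lstm fwd W/U/b, lstm bwd W/U/b, dense W/b, out W/b;
# matrices column-major), and back.
pack_params <- function(p) {
  unlist(param_leaves(p), use.names = FALSE)
}

unpack_params <- function(p, theta) {
  at <- 0L
  for (pt in param_paths(p)) {
    leaf <- p[[pt]]
    k <- length(leaf)
    v <- theta[(at + 1L):(at + k)]
    if (is.matrix(leaf)) dim(v) <- dim(leaf)
    p[[pt]] <- v
    at <- at + k
  }
  stopifnot(at == length(theta))
  p
}

# Forward pass; returns scores [n, T, d_out] and the flat [(T*n), d_out]
# timestep-major score matrix.
nn_forward <- function(p, x, theta = NULL) {
  arch <- attr(p, "arch")
  n <- dim(x)[1L]; Tn <- dim(x)[2L]
  if (is.null(theta)) theta <- pack_params(p)
  flat <- cpp_net_forward(theta, cpp_arch(p), split_steps(x))
  out <- array(0, c(n, Tn, arch$d_out))
  for (t in seq_len(Tn)) out[, t, ] <- flat[((t - 1L) * n + 1L):(t * n), ]
  list(scores = out, flat = flat)
}

# ---- masked losses -------------------------------------------------------

#' Masked categorical cross-entropy
#'
#' Mean negative log-likelihood of the true class over valid frames only.
#' Frames with `mask = 0` (label `other`, encoded as the all-zero target
#' vector) contribute nothing to the loss or its gradient; a fully masked
#' batch has loss 0 by convention.  Scores are clipped at `eps` before the
#' logarithm.
#'
#' @param targets Numeric array `[n, T, 6]` of one-hot targets (all-zero
#'   rows at masked frames).
#' @param scores Numeric array `[n, T, 6]`; each frame's scores sum to 1.
#' @param mask Binary matrix `[n, T]`.
#' @param eps Clipping constant for `log`; default `1e-7`.
#' @return Scalar loss.
#' @export
masked_categorical_crossentropy <- function(targets, scores, mask,
                                            eps = 1e-7) {
  stopifnot(all(dim(targets) == dim(scores)))
  m <- as.logical(mask)
  if (!any(m)) return(0)
  tf <- flatten_frames(targets); sf <- flatten_frames(scores)
  p <- rowSums(tf * sf)[m]
  -sum(log(pmax(p, eps))) / sum(m)
}

#' Masked mean squared error
#'
#' Mean of squared prediction errors over all (valid frame x 6 emotion
#' channel) entries; masked frames contribute nothing.  A fully masked
#' batch has loss 0 by convention.
#'
#' @param targets,scores Numeric arrays `[n, T, 6]`.
#' @param mask Binary matrix `[n, T]`.
#' @return Scalar loss.
#' @export
masked_mse <- function(targets, scores, mask) {
  stopifnot(all(dim(targets) == dim(scores)))
  m <- as.logical(mask)
  if (!any(m)) return(0)
  tf <- flatten_frames(targets); sf <- flatten_frames(scores)
  d <- (sf - tf)[m, , drop = FALSE]
  mean(d^2)
}

# [n, T, k] -> [(T*n), k] with the same timestep-major stacking as
# nn_forward()'s flat scores.
flatten_frames <- function(x) {
  n <- dim(x)[1L]; Tn <- dim(x)[2L]; k <- dim(x)[3L]
  out <- matrix(0, n * Tn, k)
  for (t in seq_len(Tn)) out[((t - 1L) * n + 1L):(t * n), ] <- x[, t, ]
  out
}

# mask [n, T] flattened timestep-major to match flatten_frames stacking
mask_vec <- function(mask) as.vector(mask)

masked_loss <- function(loss, targets, scores, mask) {
  if (loss == "cce") masked_categorical_crossentropy(targets, scores, mask)
  else masked_mse(targets, scores, mask)
}

# ---- Adam ----------------------------------------------------------------

param_leaves <- function(p) {
  # deterministic depth-first list of numeric leaves
  out <- list()
  walk <- function(x, path) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) {
      nms <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
      for (k in seq_along(x)) walk(x[[k]], c(path, nms[k]))
    } else out[[paste(path, collapse = ".")]] <<- x
    invisible(NULL)
  }
  walk(p[c("bilstm", "dense", "out")], character())
  out
}

# Index paths (character vectors usable with recursive `[[`) to every
# numeric leaf, precomputed once per training run.
param_paths <- function(p) {
  paths <- list()
  walk <- function(x, path) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) {
      nms <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
      for (k in seq_along(x)) walk(x[[k]], c(path, nms[k]))
    } else paths[[length(paths) + 1L]] <<- path
    invisible(NULL)
  }
  for (nm in c("bilstm", "dense", "out")) walk(p[[nm]], nm)
  paths
}
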