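# Small trainable convolutional embedding network. Strided 3x3 valid
# convolutions (im2col as matrix multiplication) with ReLU, global average
# pooling, a dense head and L2 normalization onto the unit hypersphere.
# Forward and backward passes are explicit base-R matrix algebra, which keeps
# the whole training loop reproducible and dependency-free at the small image
# sizes this package targets.

conv_out_size <- function(s) (s - 3L) %/% 2L + 1L

# im2col index table for a square s x s x C input: row p = output position
# (column-major), column (c-1)*9 + (kj-1)*3 + ki = kernel tap, value = flat
# index into the s*s*C input vector.
conv_indices <- function(s, C) {
  o <- conv_out_size(s)
  oi <- rep(seq_len(o), times = o)
  oj <- rep(seq_len(o), each = o)
  idx <- matrix(0L, nrow = o * o, ncol = C * 9L)
  for (c in seq_len(C)) for (kj in 1:3) for (ki in 1:3) {
    ii <- 2L * (oi - 1L) + ki
    jj <- 2L * (oj - 1L) + kj
    idx[, (c - 1L) * 9L + (kj - 1L) * 3L + ki] <-
      ii + (jj - 1L) * s + (c - 1L) * s * s
  }
  idx
}

#' Create an untrained convolutional embedding network
#'
#' @param input_size Square input side length (frames are resized to
#'   `input_size x input_size`); default 32.
#' @param channels Integer vector of output channels per strided conv block.
#' @param embed_dim Embedding dimension (128, the classifier contract).
#' @param seed Seed for the weight initialization.
#' @return An object of class `embed_net`.
#' @export
embed_net <- function(input_size = 32L, channels = c(16L, 32L),
                      embed_dim = 128L, seed = 1L) {
  input_size <- as.integer(input_size)
  if (input_size < 16L) stop_arg("input_size must be at least 16")
  sizes <- input_size
  for (i in seq_along(channels)) {
    nxt <- conv_out_size(sizes[length(sizes)])
    if (nxt < 1L) stop_arg("too many conv blocks for this input size")
    sizes <- c(sizes, nxt)
  }
  net <- withr::with_seed(derive_seed(seed, "init"), {
    in_ch <- c(3L, channels[-length(channels)])
    conv <- lapply(seq_along(channels), function(l) {
      ck <- in_ch[l] * 9L
      list(W = matrix(rnorm(ck * channels[l], 0, sqrt(2 / ck)), ck, channels[l]),
           b = numeric(channels[l]),
           idx = conv_indices(sizes[l], in_ch[l]),
           in_size = sizes[l], out_size = sizes[l + 1L],
           in_ch = in_ch[l], out_ch = channels[l])
    })
    last_ch <- channels[length(channels)]
    list(W = matrix(rnorm(embed_dim * last_ch, 0, sqrt(1 / last_ch)),
                    embed_dim, last_ch),
         b = numeric(embed_dim), conv = conv)
  })
  structure(list(input_size = input_size, channels = as.integer(channels),
                 embed_dim = as.integer(embed_dim),
                 conv = net$conv, dense = list(W = net$W, b = net$b),
                 trained = FALSE, history = list()),
            class = "embed_net")
}

# Forward pass. X: input_size x input_size x 3 x B array.
# Returns E (embed_dim x B) and, when requested, the caches for backprop.
net_forward <- function(net, X, want_cache = FALSE) {
  S <- net$input_size
  B <- dim(X)[4]
  Xf <- matrix(X, nrow = S * S * 3L, ncol = B)
  caches <- vector("list", length(net$conv))
  for (l in seq_along(net$conv)) {
    cv <- net$conv[[l]]
    P <- cv$out_size^2
    CK <- ncol(cv$idx)
    gathered <- Xf[as.vector(cv$idx), , drop = FALSE]         # (P*CK) x B
    Xcol <- matrix(aperm(array(gathered, c(P, CK, B)), c(1, 3, 2)),
                   nrow = P * B, ncol = CK)                    # (P*B) x CK
    Z <- Xcol %*% cv$W
    Z <- Z + matrix(cv$b, nrow(Z), cv$out_ch, byrow = TRUE)
    A <- pmax(Z, 0)
    if (want_cache) caches[[l]] <- list(Xcol = Xcol, mask = Z > 0, P = P, B = B)
    Xf <- matrix(aperm(array(A, c(P, B, cv$out_ch)), c(1, 3, 2)),
                 nrow = P * cv$out_ch, ncol = B)               # pixel-major per image
  }
  lastC <- net$conv[[length(net$conv)]]$out_ch
  P <- net$conv[[length(net$conv)]]$out_size^2
  H <- colMeans(array(Xf, c(P, lastC, B)), dims = 1)           # lastC x B
  if (!is.matrix(H)) H <- matrix(H, nrow = lastC, ncol = B)
  Z <- net$dense$W %*% H + net$dense$b
  nrm <- sqrt(colSums(Z^2))
  nrm[nrm < 1e-12] <- 1e-12
  E <- Z / rep(nrm, each = net$embed_dim)
  if (!want_cache) return(list(E = E))
  list(E = E, H = H, nrm = nrm, caches = caches, P = P, lastC = lastC)
}

# Backward pass: gradient of a scalar loss w.r.t. all parameters, given the
# loss gradient dE at the (normalized) embeddings.
net_backward <- function(net, fw, dE) {
  d <- net$embed_dim
  B <- ncol(dE)
  E <- fw$E
  s <- colSums(dE * E)
  dZ <- (dE - E * rep(s, each = d)) / rep(fw$nrm, each = d)
  gW <- dZ %*% t(fw$H)
  gb <- rowSums(dZ)
  dH <- t(net$dense$W) %*% dZ                                  # lastC x B
  P <- fw$P
  darr <- array(0, c(P, fw$lastC, B))
  darr[] <- rep(dH / P, each = P)
  dXf <- matrix(darr, nrow = P * fw$lastC, ncol = B)
  grads <- list(dense.W = gW, dense.b = gb)
  for (l in rev(seq_along(net$conv))) {
    cv <- net$conv[[l]]
    ca <- fw$caches[[l]]
    dA <- matrix(aperm(array(dXf, c(ca$P, cv$out_ch, B)), c(1, 3, 2)),
                 nrow = ca$P * B, ncol = cv$out_ch)
    dZl <- dA * ca$mask
    grads[[paste0("conv", l, ".W")]] <- t(ca$Xcol) %*% dZl
    grads[[paste0("conv", l, ".b")]] <- colSums(dZl)
    dXcol <- dZl %*% t(cv$W)                                   # (P*B) x CK
    arrc <- array(dXcol, c(ca$P, B, ncol(cv$idx)))
    dXf <- matrix(0, nrow = cv$in_size^2 * cv$in_ch, ncol = B)
    for (j in seq_len(ncol(cv$idx))) {
      rows <- cv$idx[, j]
      dXf[rows, ] <- dXf[rows, ] + arrc[, , j]
    }
  }
  grads
}

net_get_params <- function(net) {
  p <- list(dense.W = net$dense$W, dense.b = net$dense$b)
  for (l in seq_along(net$conv)) {
    p[[paste0("conv", l, ".W")]] <- net$conv[[l]]$W
    p[[paste0("conv", l, ".b")]] <- net$conv[[l]]$b
  }
  p
}

net_set_params <- function(net, p) {
  net$dense$W <- p$dense.W
  net$dense$b <- p$dense.b
  for (l in seq_along(net$conv)) {
    net$conv[[l]]$W <- p[[paste0("conv", l, ".W")]]
    net$conv[[l]]$b <- p[[paste0("conv", l, ".b")]]
  }
  net
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of images into the network's input array, resizing as needed.
stack_images <- function(net, images) {
  images <- as_image_list(images)
  S <- net$input_size
  X <- array(0, c(S, S, 3L, length(images)))
  for (i in seq_along(images)) X[, , , i] <- resize_image(images[[i]], c(S, S))
  X
}

#' Embed images into the 128-dimensional metric space
#'
#' Deterministic in inference mode for fixed weights; every returned vector is
#' L2-normalized to the unit hypersphere.
#'
#' @param net An `embed_net`.
#' @param images A single `H x W x 3` image, a list of images, or an
#'   `H x W x 3 x B` array. Images are resized to the network's input size.
#' @return For a single image, a numeric vector of length `embed_dim`;
#'   otherwise a `B x embed_dim` matrix (one embedding per row).
#' @export
embed <- function(net, images) {
  if (!inherits(net, "embed_net")) stop_arg("net must be an embed_net (state error)")
  single <- is_image(images)
  X <- stack_images(net, images)
  E <- net_forward(net, X)$E
  if (single) as.numeric(E[, 1L]) else t(E)
}

#' @export
print.embed_net <- function(x, ...) {
  cat(sprintf("<embed_net> input %dx%d, conv channels [%s], %d-d embedding, %s\n",
              x$input_size, x$input_size, paste(x$channels, collapse = ", "),
              x$embed_dim, if (x$trained) "trained" else "untrained"))
  invisible(x)
}
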