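# Staged curriculum training of the embedding network: per-stage triplet
# mining mode, Adam on mean triplet loss + global orthogonal regularization,
# epoch-level validation with patience-based early stopping and best-weights
# restoration.

#' Training configuration
#'
#' Defaults follow the reference recipe: triplet margin 0.2, Adam with
#' learning rate 0.001 and momentum parameters 0.9/0.999, early stopping when
#' the validation loss has not decreased for 5 epochs, at most 100 epochs per
#' stage, and a three-stage mining curriculum semi-hard, hard, hardest.
#' Batches are formed as `batch_identities` (P) identities times
#' `images_per_identity` (K) images so positives always exist.
#'
#' @param margin Triplet margin `alpha`.
#' @param gor_weight Weight of the global orthogonal regularization term.
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param patience Epochs without validation improvement before a stage stops.
#' @param max_epochs Epoch cap per stage.
#' @param stages Ordered character vector of mining modes.
#' @param batch_identities,images_per_identity Batch composition P and K.
#' @param val_fraction Fraction of the data held out for validation.
#' @param seed Seed for splits, batch sampling and initialization.
#' @param input_size Square image side the network trains on.
#' @param channels Conv block channels for a freshly created network.
#' @return A list of class `train_config`.
#' @export
train_config <- function(margin = 0.2, gor_weight = 1.0, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, patience = 5L,
                         max_epochs = 100L,
                         stages = c("semi_hard", "hard", "hardest"),
                         batch_identities = 4L, images_per_identity = 4L,
                         val_fraction = 0.2, seed = 1L,
                         input_size = 32L, channels = c(16L, 32L)) {
  if (margin <= 0) stop_arg("margin must be positive")
  if (val_fraction <= 0 || val_fraction >= 1) stop_arg("val_fraction must be in (0, 1)")
  if (length(stages) < 1L) stop_arg("stages must be non-empty")
  stages <- vapply(stages, function(s) match.arg(s, MINING_MODES), "")
  structure(list(margin = margin, gor_weight = gor_weight,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 patience = as.integer(patience), max_epochs = as.integer(max_epochs),
                 stages = unname(stages),
                 batch_identities = as.integer(batch_identities),
                 images_per_identity = as.integer(images_per_identity),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 input_size = as.integer(input_size),
                 channels = as.integer(channels)),
            class = "train_config")
}

#' Bundle images and identity labels into a training dataset
#'
#' @param images List of `H x W x 3` images.
#' @param labels Character vector of identity labels, one per image.
#' @return A list of class `reid_dataset`.
#' @export
reid_dataset <- function(images, labels) {
  images <- as_image_list(images)
  if (length(images) != length(labels)) stop_arg("images/labels length mismatch")
  structure(list(images = images, labels = as.character(labels)),
            class = "reid_dataset")
}

# Collect every frame of a session stream into a labeled dataset.
stream_to_dataset <- function(sessions) {
  images <- list(); labels <- character(0)
  for (s in sessions) {
    images <- c(images, s$frames)
    labels <- c(labels, rep(s$identity_id, length(s$frames)))
  }
  reid_dataset(images, labels)
}

# Patience rule shared by the stage loop: given the validation losses so far,
# report the best epoch and whether training should stop now (no strict
# improvement over the best for `patience` consecutive epochs).
early_stop_status <- function(val_losses, patience) {
  best <- which.min(val_losses)
  list(best_epoch = best, stop = (length(val_losses) - best) >= patience)
}

split_train_val <- function(dataset, val_fraction, seed) {
  idx <- stratified_split(dataset$labels, test_fraction = val_fraction, seed = seed)
  list(train = reid_dataset(dataset$images[idx$train], dataset$labels[idx$train]),
       val = reid_dataset(dataset$images[idx$test], dataset$labels[idx$test]))
}

# Loss over a full (small) set, used for validation: one mining pass.
set_loss <- function(net, X, labels, mode, config) {
  E <- net_forward(net, X)$E
  triplet_batch_loss(E, labels, mode, config$margin, config$gor_weight,
                     want_grad = FALSE)$loss
}

#' Train the embedding network for one curriculum stage
#'
#' Runs up to `max_epochs` epochs of Adam on the mean triplet loss over
#' triplets mined with `mode`, plus the weighted global orthogonal
#' regularizer. Batches are P identities x K images. The stage stops early
#' when the validation loss has not improved for `patience` consecutive
#' epochs, and the weights from the best-validation epoch are restored.
#'
#' @param net An `embed_net`.
#' @param dataset A `reid_dataset`, or a list with `$train` and `$val`
#'   datasets (an unsplit dataset is split internally per `val_fraction`).
#' @param mode Mining mode for this stage.
#' @param config A `train_config`.
#' @return `list(net =, history =)` where history is a data frame with one
#'   row per epoch (`epoch`, `train_loss`, `val_loss`).
#' @export
train_stage <- function(net, dataset, mode, config = train_config()) {
  mode <- match.arg(mode, MINING_MODES)
  if (config$max_epochs < 1L) return(list(net = net, history = NULL))
  if (inherits(dataset, "reid_dataset"))
    dataset <- split_train_val(dataset, config$val_fraction,
                               derive_seed(config$seed, "stage_split", mode))
  tr <- dataset$train
  if (length(unique(tr$labels)) < 2L)
    stop_arg("training error: dataset must contain at least 2 identities")

  Xtr <- stack_images(net, tr$images)
  Xval <- stack_images(net, dataset$val$images)
  by_id <- split(seq_along(tr$labels), tr$labels)
  P <- min(config$batch_identities, length(by_id))
  K <- config$images_per_identity
  steps <- max(1L, ceiling(length(tr$labels) / (P * K)))

  params <- net_get_params(net)
  state <- adam_init(params)
  best_params <- params
  vals <- numeric(0)
  trains <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    epoch_loss <- withr::with_seed(
      derive_seed(config$seed, "epoch", mode, epoch), {
        total <- 0
        for (s in seq_len(steps)) {
          ids <- sample(names(by_id), P)
          sel <- unlist(lapply(ids, function(id) {
            pool <- by_id[[id]]
            pool[sample.int(length(pool), K, replace = length(pool) < K)]
          }))
          net <- net_set_params(net, params)
          fw <- net_forward(net, Xtr[, , , sel, drop = FALSE], want_cache = TRUE)
          bl <- triplet_batch_loss(fw$E, tr$labels[sel], mode,
                                   config$margin, config$gor_weight)
          grads <- net_backward(net, fw, bl$dE)
          upd <- adam_step(params, grads, state, config$learning_rate,
                           config$beta1, config$beta2)
          params <- upd$params
          state <- upd$state
          total <- total + bl$loss
        }
        total / steps
      })
    net <- net_set_params(net, params)
    vals <- c(vals, set_loss(net, Xval, dataset$val$labels, mode, config))
    trains <- c(trains, epoch_loss)
    st <- early_stop_status(vals, config$patience)
    if (st$best_epoch == epoch) best_params <- params
    if (st$stop) break
  }
  net <- net_set_params(net, best_params)
  list(net = net,
       history = data.frame(epoch = seq_along(vals), train_loss = trains,
                            val_loss = vals))
}

#' Run the full three-stage mining curriculum
#'
#' Applies [train_stage()] once per mode in `config$stages` (by default
#' semi-hard, then hard, then hardest), threading the network through. The
#' dataset is split once into train/validation by stratified sampling at
#' `(1 - val_fraction):val_fraction`.
#'
#' @param net An `embed_net` (a fresh one is created from the config if `NULL`).
#' @param dataset A `reid_dataset`.
#' @param config A `train_config`.
#' @return The trained `embed_net`, with per-stage histories in `$history`.
#' @export
staged_train <- function(net = NULL, dataset, config = train_config()) {
  if (is.null(net))
    net <- embed_net(input_size = config$input_size, channels = config$channels,
                     seed = config$seed)
  split <- split_train_val(dataset, config$val_fraction,
                           derive_seed(config$seed, "split"))
  histories <- list()
  for (mode in config$stages) {
    res <- train_stage(net, split, mode, config)
    net <- res$net
    histories[[mode]] <- res$history
  }
  net$trained <- TRUE
  net$history <- histories
  net
}

#' Fine-tune a trained network on relabeled (drifted) data
#'
#' One hardest-mode stage at a tenfold-reduced learning rate, preserving the
#' embedding contract (unit-norm 128-d vectors). With `max_epochs = 0` the
#' network is returned unchanged.
#'
#' @param net A trained `embed_net`.
#' @param dataset A `reid_dataset` of relabeled images.
#' @param config A `train_config`; its learning rate is scaled by 0.1.
#' @return The updated `embed_net`.
#' @export
fine_tune <- function(net, dataset, config = train_config()) {
  if (!inherits(net, "embed_net")) stop_arg("net must be an embed_net")
  if (config$max_epochs < 1L) return(net)
  cfg <- config
  cfg$learning_rate <- config$learning_rate * 0.1
  res <- train_stage(net, dataset, "hardest", cfg)
  net <- res$net
  net$history <- c(net$history, list(fine_tune = res$history))
  net
}
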