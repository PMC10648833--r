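# End-to-end orchestration: simulate -> train -> adapt -> evaluate,
# including the frozen-vs-adaptive comparison under appearance drift, and a
# small command-line front end over the package's functions.

#' Identify a cat from a body-crop image
#'
#' The composition embed -> predict: the extractor maps the image to the
#' 128-d metric space and the classifier assigns an identity with per-class
#' scores.
#'
#' @param image `H x W x 3` image in `[0, 1]`.
#' @param extractor A trained `embed_net`.
#' @param classifier A `fitted_classifier`.
#' @return `list(identity =, scores =)` (scores named by class).
#' @export
identify <- function(image, extractor, classifier) {
  e <- embed(extractor, image)
  p <- predict_classifier(classifier, e)
  list(identity = p$identity[1L], scores = p$scores[1L, ])
}

#' Render a labeled training corpus from a population
#'
#' Renders `frames_per_identity` frames per cat at the given age, cycling
#' through the four color temperatures so the corpus is diversified 1:1:1:1
#' across lighting conditions.
#'
#' @param genotypes List of `cat_genotype`.
#' @param frames_per_identity Frames rendered per identity.
#' @param seed Seed for the per-frame noise.
#' @param size Frame size `(H, W)`.
#' @param noise_sd Pixel noise level.
#' @param age Age at which all frames are rendered.
#' @return A `reid_dataset`.
#' @export
render_training_set <- function(genotypes, frames_per_identity, seed,
                                size = c(32L, 32L), noise_sd = 0.02, age = 0) {
  images <- list(); labels <- character(0)
  for (g in genotypes) {
    for (k in seq_len(frames_per_identity)) {
      kelvin <- SUPPORTED_KELVINS[(k - 1L) %% 4L + 1L]
      img <- render_frame(g, age = age,
                          noise_seed = derive_seed(seed, "train", g$identity_id, k),
                          size = size, noise_sd = noise_sd)
      images[[length(images) + 1L]] <- apply_color_filter(img, kelvin)
      labels <- c(labels, g$identity_id)
    }
  }
  reid_dataset(images, labels)
}

session_frame_accuracy <- function(session, extractor, classifier) {
  pred <- predict_classifier(classifier, embed(extractor, session$frames))
  mean(pred$identity == session$identity_id)
}

#' Run a frozen-vs-adaptive drift experiment
#'
#' Trains the feature extractor and a classifier on tick-0 data, then replays
#' a drifting session stream. The adaptive arm relabels sessions (perfect
#' oracle by default), runs the selection/refit/fine-tune triggers and
#' registers or deregisters identities on population events; the frozen arm
#' never retrains. Both arms are scored each tick on held-out sessions
#' generated independently of the ingested ones.
#'
#' @param scenario A `drift_scenario`.
#' @param policy A `retrain_policy`.
#' @param config A `train_config`.
#' @param seed Master seed; every stochastic step derives from it.
#' @param n_identities Population size at tick 0.
#' @param frames_per_session,sessions_per_tick Ingest stream shape.
#' @param eval_sessions_per_tick Held-out sessions scored per tick.
#' @param train_frames_per_identity Tick-0 training frames per identity.
#' @param registration_frames Images captured by the user when a new cat is
#'   registered mid-stream.
#' @param size Frame size.
#' @param noise_sd Pixel noise level.
#' @param classifier_spec Classifier used by both arms (default: linear SVM).
#' @param relabel_error_rate Probability that the simulated user mislabels a
#'   session (0 = perfect relabeler).
#' @return A `drift_experiment`: per-tick accuracy series for both arms,
#'   per-session detail, the action journal, and a final evaluation report
#'   per arm.
#' @export
run_drift_experiment <- function(scenario, policy = retrain_policy(),
                                 config = train_config(), seed = 1L,
                                 n_identities = 5L,
                                 frames_per_session = 8L,
                                 sessions_per_tick = 15L,
                                 eval_sessions_per_tick = 10L,
                                 train_frames_per_identity = 24L,
                                 registration_frames = 10L,
                                 size = c(32L, 32L), noise_sd = 0.02,
                                 classifier_spec = NULL,
                                 relabel_error_rate = 0) {
  if (is.null(classifier_spec))
    classifier_spec <- catdrift::classifier_spec("svm", kernel = "linear")
  if (!inherits(scenario, "drift_scenario")) stop_arg("scenario must be a drift_scenario")
  if (n_identities < 2L) stop_arg("need at least 2 identities at tick 0")

  population <- generate_population(n_identities, derive_seed(seed, "pop"))
  train_ds <- render_training_set(population, train_frames_per_identity,
                                  derive_seed(seed, "train0"), size, noise_sd)
  cfg <- config
  cfg$seed <- derive_seed(seed, "traincfg")
  net <- staged_train(NULL, train_ds, cfg)

  E0 <- embed(net, train_ds$images)
  frozen_net <- net
  frozen_clf <- fit_classifier(classifier_spec, E0, train_ds$labels)

  store <- embedding_store(capacity = policy$N)
  by_id <- split(seq_along(train_ds$labels), train_ds$labels)
  for (id in names(by_id))
    store <- register_identity(store, id, train_ds$images[by_id[[id]]], net, tick = 0L)
  adaptive_clf <- refit_classifier(store, classifier_spec)

  ingest <- generate_stream(population, scenario, frames_per_session,
                            sessions_per_tick, seed = derive_seed(seed, "ingest"),
                            size = size, noise_sd = noise_sd, genotype_seed = seed)
  eval_stream <- generate_stream(population, scenario, frames_per_session,
                                 eval_sessions_per_tick,
                                 seed = derive_seed(seed, "eval"),
                                 size = size, noise_sd = noise_sd,
                                 genotype_seed = seed)
  genotypes <- attr(ingest, "genotypes")

  ticks <- 0:(scenario$duration - 1L)
  acc <- data.frame(tick = ticks, adaptive = NA_real_, frozen = NA_real_)
  details <- list()
  actions <- list()
  last_eval <- NULL
  for (t in ticks) {
    for (ev in scenario$population_events) {
      if (ev$tick != t) next
      if (ev$action == "add") {
        reg <- lapply(seq_len(registration_frames), function(k)
          render_frame(genotypes[[ev$identity_id]], age = t * scenario$morph_rate,
                       noise_seed = derive_seed(seed, "reg", ev$identity_id, k),
                       size = size, noise_sd = noise_sd))
        store <- register_identity(store, ev$identity_id, reg, net, tick = t)
      } else {
        store <- deregister_identity(store, ev$identity_id)
      }
      adaptive_clf <- refit_classifier(store, classifier_spec)
      actions <- c(actions, list(list(tick = t, type = paste0("population_", ev$action),
                                      identity = ev$identity_id)))
    }

    evals <- Filter(function(s) s$tick == t, eval_stream)
    if (length(evals) > 0L) {
      arow <- vapply(evals, session_frame_accuracy, 0, net, adaptive_clf)
      frow <- vapply(evals, session_frame_accuracy, 0, frozen_net, frozen_clf)
      acc$adaptive[acc$tick == t] <- mean(arow)
      acc$frozen[acc$tick == t] <- mean(frow)
      details[[length(details) + 1L]] <- data.frame(
        tick = t,
        session_id = vapply(evals, `[[`, "", "session_id"),
        identity_id = vapply(evals, `[[`, "", "identity_id"),
        adaptive = arow, frozen = frow)
      last_eval <- evals
    }

    for (s in Filter(function(x) x$tick == t, ingest)) {
      label <- s$identity_id
      if (relabel_error_rate > 0) {
        label <- withr::with_seed(derive_seed(seed, "relabel", s$session_id), {
          if (runif(1) < relabel_error_rate) {
            others <- setdiff(store_identities(store), s$identity_id)
            if (length(others) > 0L) sample(others, 1L) else s$identity_id
          } else s$identity_id
        })
      }
      if (!(label %in% store_identities(store))) next
      store <- ingest_labeled_session(store, s, label, net)
    }
    ad <- maybe_adapt(store, policy, classifier_spec, net)
    store <- ad$store
    if (!is.null(ad$classifier)) adaptive_clf <- ad$classifier
    for (a in ad$actions) {
      actions <- c(actions, list(c(list(tick = t), a)))
      if (a$type == "fine_tune") {
        net <- fine_tune(net, store_to_dataset(store), cfg)
        store <- reembed_store(store, net)
        adaptive_clf <- refit_classifier(store, classifier_spec)
      }
    }
  }

  reports <- list()
  if (!is.null(last_eval)) {
    ds <- stream_to_dataset(last_eval)
    if (length(unique(ds$labels)) >= 2L) {
      reports$adaptive <- full_report(adaptive_clf, embed(net, ds$images), ds$labels)
      reports$frozen <- full_report(frozen_clf, embed(frozen_net, ds$images), ds$labels)
    }
  }
  structure(list(accuracy = acc, details = do.call(rbind, details),
                 actions = actions, reports = reports,
                 journal = store$journal, store = store,
                 extractor = net, adaptive_classifier = adaptive_clf,
                 frozen_classifier = frozen_clf),
            class = "drift_experiment")
}

#' @export
print.drift_experiment <- function(x, ...) {
  cat("<drift_experiment>\n")
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}
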