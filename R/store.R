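# Adaptive embedding memory: per-identity bounded record sets, session-level
# relabeled ingestion, mean-vector prioritized selection (keep the N vectors
# closest to the class mean, discard the rest), registration/deregistration,
# and trigger logic for classifier refits and extractor fine-tuning.

#' Retraining policy
#'
#' The four triggers and capacities governing adaptation: images are
#' collected over a period `period` (T); once an identity has gathered `M`
#' new images its embedding set is re-selected; at most `N` embeddings are
#' retained per identity; once every registered identity has accumulated `C`
#' litter-box images since the last fine-tune, a feature-extractor fine-tune
#' is requested.
#'
#' @param period Collection period T in ticks.
#' @param M Per-identity new-image count triggering selection.
#' @param N Per-identity embedding capacity.
#' @param C Per-identity accumulated-image count triggering fine-tuning.
#' @return A `retrain_policy`.
#' @export
retrain_policy <- function(period = 1L, M = 20L, N = 200L, C = 500L) {
  vals <- c(period = period, M = M, N = N, C = C)
  if (any(vals < 1)) stop_arg("all policy values must be positive")
  structure(lapply(as.list(vals), as.integer), class = "retrain_policy")
}

empty_bucket <- function(dim = 128L) {
  list(vectors = matrix(numeric(0), 0L, dim),
       meta = data.frame(session_id = character(0), tick = integer(0),
                         origin = character(0), stringsAsFactors = FALSE),
       images = list())
}

#' Create an empty adaptive embedding store
#'
#' @param capacity Default per-identity capacity N.
#' @param dim Embedding dimension.
#' @return An `embedding_store`.
#' @export
embedding_store <- function(capacity = 200L, dim = 128L) {
  if (capacity < 1L) stop_arg("capacity must be at least 1")
  structure(list(capacity = as.integer(capacity), dim = as.integer(dim),
                 records = list(), staged = list(),
                 litter_count = integer(0), journal = character(0)),
            class = "embedding_store")
}

journal_add <- function(store, ...) {
  store$journal <- c(store$journal, paste0(...))
  store
}

#' Identities currently registered in a store
#' @param store An `embedding_store`.
#' @return Character vector of identity ids.
#' @export
store_identities <- function(store) names(store$records)

#' Per-identity bounded record counts
#' @param store An `embedding_store`.
#' @param staged Count staged (not yet selected) records instead.
#' @return Named integer vector.
#' @export
store_counts <- function(store, staged = FALSE) {
  src <- if (staged) store$staged else store$records
  vapply(src, function(b) nrow(b$vectors), 0L)
}

add_records <- function(bucket, vectors, session_id, tick, origin, images) {
  bucket$vectors <- rbind(bucket$vectors, vectors)
  bucket$meta <- rbind(bucket$meta,
                       data.frame(session_id = rep(session_id, nrow(vectors)),
                                  tick = rep(as.integer(tick), nrow(vectors)),
                                  origin = rep(origin, nrow(vectors)),
                                  stringsAsFactors = FALSE))
  bucket$images <- c(bucket$images, images)
  bucket
}

#' Register a new identity from user-supplied images
#'
#' All images are embedded and stored as bounded records with origin
#' `"registration"`; the identity becomes predictable after the next
#' classifier refit. If more images are supplied than the store's capacity,
#' the mean-vector selection rule trims them so the capacity bound holds
#' from the start.
#'
#' @param store An `embedding_store`.
#' @param identity_id New identity token (must not already exist).
#' @param images Non-empty list of images.
#' @param extractor An `embed_net`.
#' @param tick Registration time.
#' @return The updated store.
#' @export
register_identity <- function(store, identity_id, images, extractor, tick = 0L) {
  if (identity_id %in% names(store$records))
    stop_arg("registration error: identity ", identity_id, " already registered")
  images <- as_image_list(images)
  if (length(images) == 0L) stop_arg("need at least one registration image")
  E <- embed(extractor, images)
  if (nrow(E) > store$capacity) {
    # the capacity bound holds from the first moment: keep the registration
    # images closest to their own mean
    idx <- attr(select_embeddings(NULL, E, store$capacity), "indices")
    E <- E[idx, , drop = FALSE]
    images <- images[idx]
  }
  bucket <- add_records(empty_bucket(store$dim), E, "registration", tick,
                        "registration", images)
  store$records[[identity_id]] <- bucket
  store$staged[[identity_id]] <- empty_bucket(store$dim)
  store$litter_count[identity_id] <- 0L
  journal_add(store, "register ", identity_id, " n=", length(images),
              " tick=", tick)
}

#' Deregister an identity, deleting all its embedding vectors
#'
#' @param store An `embedding_store`.
#' @param identity_id Registered identity token.
#' @return The updated store; other identities are untouched.
#' @export
deregister_identity <- function(store, identity_id) {
  if (!(identity_id %in% names(store$records)))
    stop_arg("unknown identity ", identity_id)
  store$records[[identity_id]] <- NULL
  store$staged[[identity_id]] <- NULL
  store$litter_count <- store$litter_count[names(store$litter_count) != identity_id]
  journal_add(store, "deregister ", identity_id)
}

#' Ingest a user-relabeled session
#'
#' Every frame of the session is embedded and staged as a new litter-box
#' record under the corrected identity (session-atomic labeling: one label
#' for all frames). Staged records enter the bounded store only at the next
#' selection event.
#'
#' @param store An `embedding_store`.
#' @param session A `session_record`.
#' @param corrected_identity The user-confirmed identity (must be registered).
#' @param extractor An `embed_net`.
#' @return The updated store.
#' @export
ingest_labeled_session <- function(store, session, corrected_identity, extractor) {
  if (!(corrected_identity %in% names(store$records)))
    stop_arg("unknown identity ", corrected_identity)
  E <- embed(extractor, session$frames)
  store$staged[[corrected_identity]] <- add_records(
    store$staged[[corrected_identity]], E, session$session_id, session$tick,
    "litterbox", session$frames)
  store$litter_count[corrected_identity] <-
    store$litter_count[corrected_identity] + length(session$frames)
  journal_add(store, "ingest ", session$session_id, " as ", corrected_identity,
              " n=", length(session$frames))
}

#' Mean-vector prioritized embedding selection
#'
#' Computes the arithmetic mean of the union of existing and incoming
#' vectors, then keeps the `min(N, union size)` vectors closest to that mean
#' (Euclidean distance; ties broken by earlier position in existing-then-
#' incoming order). The far-from-mean remainder — outliers — is discarded.
#'
#' @param existing Matrix of currently stored vectors (rows), possibly 0-row.
#' @param incoming Matrix of newly collected vectors (rows).
#' @param N Capacity.
#' @return The selected vectors in selection order, with the chosen union
#'   row indices attached as attribute `"indices"`.
#' @export
select_embeddings <- function(existing, incoming, N) {
  if (N < 1L) stop_arg("N must be at least 1")
  ex <- if (is.null(existing)) NULL else as_embedding_matrix(existing)
  inc <- if (is.null(incoming)) NULL else as_embedding_matrix(incoming)
  U <- rbind(ex, inc)
  if (is.null(U) || nrow(U) == 0L) stop_arg("empty union")
  mu <- colMeans(U)
  d <- sqrt(rowSums((U - matrix(mu, nrow(U), ncol(U), byrow = TRUE))^2))
  ord <- order(d, seq_len(nrow(U)))
  sel <- ord[seq_len(min(N, nrow(U)))]
  structure(U[sel, , drop = FALSE], indices = sel)
}

#' Run the adaptation triggers over a store
#'
#' For each identity whose staged records have reached `M`, re-selects its
#' bounded set as the `N` vectors closest to the mean of (bounded union
#' staged) and clears the stage. After any selection the classifier is refit
#' on all bounded records. If every registered identity has accumulated at
#' least `C` litter-box images since the last fine-tune, a `fine_tune`
#' action is emitted (and the counters reset); performing the fine-tune and
#' re-embedding is the caller's responsibility.
#'
#' @param store An `embedding_store`.
#' @param policy A `retrain_policy`.
#' @param classifier_spec A `classifier_spec` used for refits.
#' @param extractor An `embed_net` (kept for interface symmetry; selection
#'   operates on stored vectors).
#' @return `list(store =, actions =, classifier =)`; `classifier` is the
#'   refit `fitted_classifier` or `NULL` when no selection occurred.
#' @export
maybe_adapt <- function(store, policy, classifier_spec, extractor) {
  actions <- list()
  for (id in names(store$records)) {
    staged <- store$staged[[id]]
    if (nrow(staged$vectors) < policy$M) next
    bounded <- store$records[[id]]
    U <- rbind(bounded$vectors, staged$vectors)
    meta <- rbind(bounded$meta, staged$meta)
    images <- c(bounded$images, staged$images)
    sel <- select_embeddings(bounded$vectors, staged$vectors, policy$N)
    idx <- attr(sel, "indices")
    store$records[[id]] <- list(vectors = U[idx, , drop = FALSE],
                                meta = meta[idx, , drop = FALSE],
                                images = images[idx])
    store$staged[[id]] <- empty_bucket(store$dim)
    actions <- c(actions, list(list(type = "select", identity = id,
                                    kept = length(idx),
                                    discarded = nrow(U) - length(idx))))
    store <- journal_add(store, "select ", id, " kept=", length(idx),
                         " discarded=", nrow(U) - length(idx))
  }
  classifier <- NULL
  if (length(actions) > 0L) {
    classifier <- refit_classifier(store, classifier_spec)
    actions <- c(actions, list(list(type = "refit")))
    store <- journal_add(store, "refit classes=",
                         paste(store_identities(store), collapse = ","))
  }
  ids <- names(store$records)
  if (length(ids) > 0L && all(store$litter_count[ids] >= policy$C)) {
    actions <- c(actions, list(list(type = "fine_tune")))
    store$litter_count[ids] <- 0L
    store <- journal_add(store, "fine_tune requested")
  }
  list(store = store, actions = actions, classifier = classifier)
}

#' Refit a classifier on all bounded records of a store
#'
#' @param store An `embedding_store` with at least two identities.
#' @param spec A `classifier_spec`.
#' @return A `fitted_classifier`.
#' @export
refit_classifier <- function(store, spec) {
  ids <- store_identities(store)
  vecs <- do.call(rbind, lapply(ids, function(id) store$records[[id]]$vectors))
  labels <- rep(ids, vapply(ids, function(id) nrow(store$records[[id]]$vectors), 0L))
  fit_classifier(spec, vecs, labels)
}

#' Recompute every bounded record's vector with the current extractor
#'
#' Used after fine-tuning: counts and identities are unchanged, vectors are
#' re-extracted from each record's source image.
#'
#' @param store An `embedding_store`.
#' @param extractor An `embed_net`.
#' @return The updated store.
#' @export
reembed_store <- function(store, extractor) {
  for (id in names(store$records)) {
    bucket <- store$records[[id]]
    if (nrow(bucket$vectors) == 0L) next
    if (length(bucket$images) != nrow(bucket$vectors) ||
        any(vapply(bucket$images, is.null, TRUE)))
      stop_arg("state error: record without source image for ", id)
    store$records[[id]]$vectors <- embed(extractor, bucket$images)
  }
  journal_add(store, "reembed")
}

# Flatten bounded records into a dataset for fine-tuning.
store_to_dataset <- function(store) {
  ids <- store_identities(store)
  images <- list(); labels <- character(0)
  for (id in ids) {
    bucket <- store$records[[id]]
    images <- c(images, bucket$images)
    labels <- c(labels, rep(id, length(bucket$images)))
  }
  reid_dataset(images, labels)
}

#' Persist a store as a CSV index plus vector table and PNG images
#'
#' @param store An `embedding_store`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
save_store <- function(store, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list(); vecs <- list(); n <- 0L
  for (id in store_identities(store)) {
    bucket <- store$records[[id]]
    for (i in seq_len(nrow(bucket$vectors))) {
      n <- n + 1L
      img_path <- sprintf("images/rec_%05d.png", n)
      png::writePNG(bucket$images[[i]], file.path(dir, img_path))
      rows[[n]] <- data.frame(identity_id = id,
                              session_id = bucket$meta$session_id[i],
                              tick = bucket$meta$tick[i],
                              origin = bucket$meta$origin[i],
                              image = img_path, stringsAsFactors = FALSE)
      vecs[[n]] <- bucket$vectors[i, ]
    }
  }
  index <- if (n > 0L) do.call(rbind, rows) else
    data.frame(identity_id = character(0), session_id = character(0),
               tick = integer(0), origin = character(0), image = character(0))
  write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  V <- if (n > 0L) do.call(rbind, vecs) else matrix(numeric(0), 0L, store$dim)
  colnames(V) <- sprintf("v%03d", seq_len(store$dim))
  write.csv(V, file.path(dir, "vectors.csv"), row.names = FALSE)
  writeLines(store$journal, file.path(dir, "journal.log"))
  writeLines(as.character(store$capacity), file.path(dir, "capacity.txt"))
  invisible(dir)
}

#' Load a store persisted with [save_store()]
#'
#' @param dir Directory written by [save_store()].
#' @return An `embedding_store`.
#' @export
load_store <- function(dir) {
  index <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  V <- as.matrix(read.csv(file.path(dir, "vectors.csv")))
  capacity <- as.integer(readLines(file.path(dir, "capacity.txt"))[1])
  store <- embedding_store(capacity = capacity,
                           dim = if (ncol(V) > 0) ncol(V) else 128L)
  for (id in unique(index$identity_id)) {
    sel <- which(index$identity_id == id)
    imgs <- lapply(index$image[sel], function(p) {
      img <- png::readPNG(file.path(dir, p))
      img[, , 1:3, drop = FALSE]
    })
    store$records[[id]] <- list(
      vectors = V[sel, , drop = FALSE],
      meta = data.frame(session_id = index$session_id[sel],
                        tick = index$tick[sel], origin = index$origin[sel],
                        stringsAsFactors = FALSE),
      images = imgs)
    store$staged[[id]] <- empty_bucket(store$dim)
    store$litter_count[id] <- 0L
  }
  jp <- file.path(dir, "journal.log")
  if (file.exists(jp)) store$journal <- readLines(jp)
  store
}
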