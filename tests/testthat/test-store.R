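fresh_store <- function(net, ids = c("A", "B"), n_images = 3, size = 16,
                        capacity = 50) {
  store <- embedding_store(capacity = capacity)
  for (id in ids) {
    imgs <- lapply(seq_len(n_images), function(k)
      render_frame(spawn_genotype(id, 5), noise_seed = k, size = c(size, size)))
    store <- register_identity(store, id, imgs, net)
  }
  store
}

toy_session <- function(id, n, tick = 0, sid = paste0("sess_", id, "_", tick),
                        size = 16) {
  g <- spawn_genotype(id, 5)
  frames <- lapply(seq_len(n), function(k)
    render_frame(g, age = tick, noise_seed = 1000 + k, size = c(size, size)))
  catdrift:::new_session_record(sid, id, frames, tick, 6500)
}

test_that("registration and deregistration maintain exact record sets", {
  net <- embed_net(input_size = 16, seed = 4)
  store <- embedding_store(capacity = 10)
  imgs <- lapply(1:10, function(k)
    render_frame(spawn_genotype("A", 1), noise_seed = k, size = c(16, 16)))
  store <- register_identity(store, "A", imgs, net)
  expect_equal(unname(store_counts(store)["A"]), 10L)
  expect_error(register_identity(store, "A", imgs[1:2], net), "already registered")
  expect_error(register_identity(store, "B", list(), net), "at least one")

  store <- register_identity(store, "B", imgs[1:4], net)
  store2 <- deregister_identity(store, "A")
  expect_false("A" %in% store_identities(store2))
  expect_equal(unname(store_counts(store2)["B"]), 4L)
  expect_error(deregister_identity(store2, "A"), "unknown identity")

  # re-registering holds only the new records
  store3 <- register_identity(store2, "A", imgs[1:2], net)
  expect_equal(unname(store_counts(store3)["A"]), 2L)
})

test_that("session ingestion is atomic and additive", {
  net <- embed_net(input_size = 16, seed = 4)
  store <- fresh_store(net)
  store <- ingest_labeled_session(store, toy_session("B", 7, sid = "s1"), "A", net)
  expect_equal(unname(store_counts(store, staged = TRUE)["A"]), 7L)
  expect_equal(unname(store_counts(store, staged = TRUE)["B"]), 0L)
  expect_true(all(store$staged$A$meta$session_id == "s1"))

  store <- ingest_labeled_session(store, toy_session("A", 3, sid = "s2"), "A", net)
  store <- ingest_labeled_session(store, toy_session("A", 4, sid = "s3"), "A", net)
  expect_equal(unname(store_counts(store, staged = TRUE)["A"]), 14L)
  expect_error(ingest_labeled_session(store, toy_session("Z", 2), "Z", net),
               "unknown identity")
})

test_that("selection keeps the vectors nearest the mean (worked example)", {
  existing <- rbind(c(0, 0), c(0, 2))
  incoming <- rbind(c(0, 1), c(10, 0))
  sel <- select_embeddings(existing, incoming, 3)
  expect_equal(sel, rbind(c(0, 1), c(0, 0), c(0, 2)), ignore_attr = TRUE)
  expect_equal(attr(sel, "indices"), c(3L, 1L, 2L))

  # capacity slack returns the whole union
  all4 <- select_embeddings(existing, incoming, 10)
  expect_equal(nrow(all4), 4)

  # ties broken by input order
  four <- matrix(1, 4, 2)
  tied <- select_embeddings(four[1:2, ], four[3:4, ], 2)
  expect_equal(attr(tied, "indices"), c(1L, 2L))

  expect_error(select_embeddings(NULL, NULL, 3), "empty union")
  expect_error(select_embeddings(existing, incoming, 0), "at least 1")
})

test_that("selection matches the exhaustive oracle on random instances", {
  set.seed(13)
  for (rep in 1:60) {
    d <- sample(2:64, 1)
    ne <- sample(0:30, 1); ni <- sample(1:30, 1)
    ex <- if (ne > 0) matrix(rnorm(ne * d), ne, d) else NULL
    inc <- matrix(rnorm(ni * d), ni, d)
    N <- sample(1:40, 1)
    got <- select_embeddings(ex, inc, N)
    expect_equal(got, select_oracle(ex, inc, N), ignore_attr = TRUE)
  }
})

test_that("a far outlier is never selected when capacity fits the cluster", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:12, 1)
    cluster <- matrix(rnorm(k * 8, sd = 0.1), k, 8)
    diam <- max(dist(cluster))
    far <- colMeans(cluster) + rnorm(8)
    far <- colMeans(cluster) + (far - colMeans(cluster)) *
      (10 * max(diam, 0.5)) / sqrt(sum((far - colMeans(cluster))^2))
    sel <- select_embeddings(cluster, matrix(far, 1), k)
    expect_false((k + 1L) %in% attr(sel, "indices"))
  }
})

test_that("adaptation triggers respect M, N and the fine-tune condition", {
  net <- embed_net(input_size = 16, seed = 4)
  policy <- retrain_policy(M = 5, N = 4, C = 8)
  spec <- classifier_spec("knn", k = 3)
  store <- fresh_store(net)

  # below M: no selection
  store1 <- ingest_labeled_session(store, toy_session("A", 4), "A", net)
  r1 <- maybe_adapt(store1, policy, spec, net)
  expect_length(Filter(function(a) a$type == "select", r1$actions), 0)

  # at M with union > N: bounded count equals N exactly and classifier refits
  store2 <- ingest_labeled_session(store, toy_session("A", 5), "A", net)
  r2 <- maybe_adapt(store2, policy, spec, net)
  types <- vapply(r2$actions, `[[`, "", "type")
  expect_true("select" %in% types && "refit" %in% types)
  expect_equal(unname(store_counts(r2$store)["A"]), 4L)
  expect_equal(unname(store_counts(r2$store, staged = TRUE)["A"]), 0L)
  expect_s3_class(r2$classifier, "fitted_classifier")

  # fine-tune fires only when all identities reach C
  store3 <- ingest_labeled_session(store, toy_session("A", 9), "A", net)
  r3 <- maybe_adapt(store3, policy, spec, net)
  expect_false("fine_tune" %in% vapply(r3$actions, `[[`, "", "type"))
  store4 <- ingest_labeled_session(r3$store, toy_session("B", 8, sid = "sb"), "B", net)
  r4 <- maybe_adapt(store4, policy, spec, net)
  expect_equal(sum(vapply(r4$actions, `[[`, "", "type") == "fine_tune"), 1)
  expect_true(all(r4$store$litter_count == 0))
})

test_that("capacity and session atomicity hold under random ingest/adapt sequences", {
  net <- embed_net(input_size = 16, seed = 4)
  for (seed in 1:10) {
    set.seed(seed)
    policy <- retrain_policy(M = sample(2:6, 1), N = sample(2:8, 1), C = 50)
    store <- fresh_store(net, capacity = policy$N)
    sessions_seen <- list()
    for (step in 1:8) {
      id <- sample(c("A", "B"), 1)
      s <- toy_session(id, sample(1:6, 1), tick = step,
                       sid = sprintf("s%d_%d", seed, step))
      store <- ingest_labeled_session(store, s, id, net)
      sessions_seen[[s$session_id]] <- id
      if (runif(1) < 0.7) {
        r <- maybe_adapt(store, policy, classifier_spec("knn", k = 3), net)
        store <- r$store
        expect_true(all(store_counts(store) <= policy$N))
      }
      # all records of any session carry one identity
      for (id2 in store_identities(store)) {
        for (bucket in list(store$records[[id2]], store$staged[[id2]])) {
          sess <- setdiff(unique(bucket$meta$session_id), "registration")
          for (sid in sess) expect_equal(sessions_seen[[sid]], id2)
        }
      }
    }
  }
})

test_that("re-embedding preserves structure and tracks extractor weights", {
  net <- embed_net(input_size = 16, seed = 4)
  store <- fresh_store(net)
  before <- store$records$A$vectors
  same <- reembed_store(store, net)
  expect_equal(same$records$A$vectors, before, tolerance = 1e-6)
  expect_equal(store_counts(same), store_counts(store))

  other <- embed_net(input_size = 16, seed = 99)
  changed <- reembed_store(store, other)
  expect_gt(max(abs(changed$records$A$vectors - before)), 1e-4)
})

test_that("a store survives a save/load round trip", {
  net <- embed_net(input_size = 16, seed = 4)
  store <- fresh_store(net)
  dir <- withr::local_tempdir()
  save_store(store, dir)
  back <- load_store(dir)
  expect_equal(sort(store_identities(back)), c("A", "B"))
  expect_equal(unname(back$records$A$vectors), unname(store$records$A$vectors),
               tolerance = 1e-12)
  # images round-trip at PNG precision, so re-embedding still works
  re <- reembed_store(back, net)
  expect_equal(unname(re$records$A$vectors), unname(store$records$A$vectors),
               tolerance = 0.05)
})
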