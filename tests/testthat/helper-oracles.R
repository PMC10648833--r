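# Independent brute-force oracles used to cross-check the implementation.

# O(n^3) triplet mining straight from the definitions.
mine_oracle <- function(E, labels, mode, margin = 0.2) {
  n <- nrow(E)
  D2 <- as.matrix(dist(E))^2
  rows <- list()
  for (a in seq_len(n)) for (p in seq_len(n)) {
    if (p == a || labels[p] != labels[a]) next
    negs <- which(labels != labels[a])
    if (length(negs) == 0L) next
    if (mode == "hardest") {
      best <- negs[1]
      for (ng in negs) if (D2[a, ng] < D2[a, best]) best <- ng
      rows[[length(rows) + 1L]] <- c(a, p, best)
    } else {
      for (ng in negs) {
        keep <- if (mode == "semi_hard")
          D2[a, p] < D2[a, ng] && D2[a, ng] < D2[a, p] + margin
        else D2[a, ng] < D2[a, p]
        if (keep) rows[[length(rows) + 1L]] <- c(a, p, ng)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(0), ncol = 3)
  out
}

# Exhaustive sort-by-distance-to-mean selection.
select_oracle <- function(existing, incoming, N) {
  U <- rbind(existing, incoming)
  mu <- colMeans(U)
  d <- apply(U, 1, function(r) sqrt(sum((r - mu)^2)))
  keep <- order(d, seq_len(nrow(U)))[seq_len(min(N, nrow(U)))]
  U[keep, , drop = FALSE]
}

# Exhaustive KNN with majority vote, ties resolved by the nearest neighbour.
knn_oracle <- function(train, labels, query, k) {
  d2 <- apply(train, 1, function(r) sum((r - query)^2))
  ord <- order(d2, seq_along(d2))
  nb <- labels[ord[seq_len(k)]]
  tb <- table(nb)
  top <- names(tb)[tb == max(tb)]
  if (length(top) == 1L) top else labels[ord[1L]]
}

# Mann-Whitney pair-counting AUC.
auc_pairs <- function(scores, member) {
  sp <- scores[member]
  sn <- scores[!member]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

random_unit_rows <- function(n, d) {
  M <- matrix(rnorm(n * d), n, d)
  M / sqrt(rowSums(M^2))
}

# A tiny trained extractor, trained once per test run and memoized.
demo_env <- new.env(parent = emptyenv())
demo_world <- function() {
  if (is.null(demo_env$world)) {
    pop <- generate_population(5, seed = 101)
    train <- render_training_set(pop, 20, seed = 101)
    cfg <- train_config(seed = 101, max_epochs = 15)
    net <- staged_train(NULL, train, cfg)
    demo_env$world <- list(pop = pop, train = train, net = net, cfg = cfg)
  }
  demo_env$world
}
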