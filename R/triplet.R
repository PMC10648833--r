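# Triplet-loss metric learning primitives: hinge loss on squared Euclidean
# distances, global orthogonal regularization, and the three-mode triplet
# mining curriculum (semi-hard, hard, hardest).

MINING_MODES <- c("semi_hard", "hard", "hardest")

#' Triplet hinge loss on squared distances
#'
#' `max(0, d2_ap - d2_an + margin)`: the anchor-positive squared distance must
#' undercut the anchor-negative squared distance by at least the margin.
#'
#' @param d2_ap Nonnegative squared anchor-positive distance(s).
#' @param d2_an Nonnegative squared anchor-negative distance(s).
#' @param margin Margin `alpha` (default 0.2).
#' @return Nonnegative loss, vectorized over the inputs.
#' @export
triplet_loss <- function(d2_ap, d2_an, margin = 0.2) {
  if (any(d2_ap < 0) || any(d2_an < 0))
    stop_arg("squared distances must be nonnegative")
  pmax(0, d2_ap - d2_an + margin)
}

# Coerce embeddings given as a list of vectors or an n x d matrix (rows).
as_embedding_matrix <- function(embeddings) {
  if (is.list(embeddings)) {
    lens <- lengths(embeddings)
    if (length(unique(lens)) > 1L) stop_arg("embedding dimension mismatch")
    embeddings <- do.call(rbind, lapply(embeddings, as.numeric))
  }
  if (!is.matrix(embeddings)) embeddings <- matrix(embeddings, nrow = 1L)
  if (!all(is.finite(embeddings))) stop_arg("embeddings must be finite")
  embeddings
}

pairwise_sqdist <- function(E) {
  n2 <- rowSums(E^2)
  D2 <- outer(n2, n2, "+") - 2 * tcrossprod(E)
  D2[D2 < 0] <- 0
  D2
}

#' Global orthogonal regularization term
#'
#' Pushes embeddings of *different* identities toward the second-moment
#' statistics of uniformly spread unit vectors: with `dot_ij` the dot products
#' over all different-label pairs, `M1` their mean and `M2` their mean square,
#' the penalty is `M1^2 + max(0, M2 - 1/d)` where `d` is the embedding
#' dimension. It is 0 when no different-label pair exists.
#'
#' @param embeddings `n x d` matrix (rows are embeddings) or list of vectors.
#' @param labels Length-`n` label vector.
#' @return Nonnegative scalar.
#' @export
gor_term <- function(embeddings, labels) {
  E <- as_embedding_matrix(embeddings)
  n <- nrow(E)
  if (n < 1L) stop_arg("need at least one embedding")
  if (length(labels) != n) stop_arg("labels/embeddings length mismatch")
  diff <- outer(labels, labels, "!=")
  diff[lower.tri(diff, diag = TRUE)] <- FALSE
  if (!any(diff)) return(0)
  G <- tcrossprod(E)
  dots <- G[diff]
  m1 <- mean(dots)
  m2 <- mean(dots^2)
  m1^2 + max(0, m2 - 1 / ncol(E))
}

#' Mine triplets from a batch of embeddings
#'
#' With `D2` the squared Euclidean distance and `(a, p, n)` ranging over
#' anchors, same-label positives and different-label negatives:
#' * `semi_hard` keeps triplets with `D2(a,p) < D2(a,n) < D2(a,p) + margin`;
#' * `hard` keeps `D2(a,n) < D2(a,p)`;
#' * `hardest` keeps, for each `(a, p)`, only the negative minimizing
#'   `D2(a,n)` (ties broken by lowest index).
#'
#' Anchors with no positive are skipped. The semi-hard and hard sets are
#' disjoint by construction.
#'
#' @param embeddings `n x d` matrix or list of vectors.
#' @param labels Length-`n` labels.
#' @param mode One of `"semi_hard"`, `"hard"`, `"hardest"`.
#' @param margin Margin used by the semi-hard window.
#' @return Integer matrix with columns `anchor`, `positive`, `negative`
#'   (possibly zero rows).
#' @export
mine_triplets <- function(embeddings, labels, mode = "semi_hard", margin = 0.2) {
  mode <- match.arg(mode, MINING_MODES)
  E <- as_embedding_matrix(embeddings)
  n <- nrow(E)
  if (length(labels) != n) stop_arg("labels/embeddings length mismatch")
  out <- matrix(integer(0), ncol = 3L,
                dimnames = list(NULL, c("anchor", "positive", "negative")))
  if (n < 3L) return(out)
  D2 <- pairwise_sqdist(E)
  rows <- vector("list", n)
  for (a in seq_len(n)) {
    pos <- which(labels == labels[a])
    pos <- pos[pos != a]
    neg <- which(labels != labels[a])
    if (length(pos) == 0L || length(neg) == 0L) next
    triples <- lapply(pos, function(p) {
      dap <- D2[a, p]
      dan <- D2[a, neg]
      keep <- switch(mode,
        semi_hard = neg[dan > dap & dan < dap + margin],
        hard = neg[dan < dap],
        hardest = neg[which.min(dan)])
      if (length(keep) == 0L) NULL else cbind(a, p, keep)
    })
    rows[[a]] <- do.call(rbind, triples)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(out)
  colnames(res) <- c("anchor", "positive", "negative")
  res
}

# Batch loss and gradient w.r.t. the embeddings, used by the trainer:
# mean triplet hinge over the mined triplets of `mode`, plus
# gor_weight * gor_term. E is d x B (columns are embeddings).
triplet_batch_loss <- function(E, labels, mode, margin, gor_weight,
                               want_grad = TRUE) {
  B <- ncol(E)
  d <- nrow(E)
  Et <- t(E)
  trips <- mine_triplets(Et, labels, mode, margin)
  dE <- if (want_grad) matrix(0, d, B) else NULL
  tri_loss <- 0
  if (nrow(trips) > 0L) {
    a <- trips[, 1L]; p <- trips[, 2L]; ng <- trips[, 3L]
    d2ap <- colSums((E[, a, drop = FALSE] - E[, p, drop = FALSE])^2)
    d2an <- colSums((E[, a, drop = FALSE] - E[, ng, drop = FALSE])^2)
    h <- d2ap - d2an + margin
    act <- h > 0
    tri_loss <- mean(pmax(0, h))
    if (want_grad && any(act)) {
      Tn <- nrow(trips)
      for (i in which(act)) {
        ea <- E[, a[i]]; ep <- E[, p[i]]; en <- E[, ng[i]]
        dE[, a[i]] <- dE[, a[i]] + 2 * (en - ep) / Tn
        dE[, p[i]] <- dE[, p[i]] + 2 * (ep - ea) / Tn
        dE[, ng[i]] <- dE[, ng[i]] + 2 * (ea - en) / Tn
      }
    }
  }
  gor_loss <- 0
  if (gor_weight > 0) {
    A <- outer(labels, labels, "!=")
    if (any(A)) {
      np <- sum(A) / 2
      G <- crossprod(E)
      m1 <- sum(G[A]) / (2 * np)
      m2 <- sum(G[A]^2) / (2 * np)
      gor_loss <- m1^2 + max(0, m2 - 1 / d)
      if (want_grad) {
        Amat <- A * 1
        grad_rows <- 2 * m1 * (Amat %*% Et) / np
        if (m2 > 1 / d) grad_rows <- grad_rows + 2 * ((Amat * G) %*% Et) / np
        dE <- dE + gor_weight * t(grad_rows)
      }
    }
  }
  list(loss = tri_loss + gor_weight * gor_loss, dE = dE,
       n_triplets = nrow(trips))
}
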