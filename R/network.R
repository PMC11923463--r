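#' Build a binary entity-by-tweet incidence matrix
#'
#' Each retained entity becomes a row vector over tweets: cell (e, t) is 1
#' iff tweet t mentions entity e at least once (mention multiplicity is
#' collapsed here, not earlier, so trend counts keep multiplicity).
#' Entities with no mentions among `tweet_ids` are dropped (no all-zero
#' rows).
#'
#' @param mentions Mention data frame (see [extract_mentions()]).
#' @param entities Canonicals to include as rows (normally the output of
#'   [frequency_filter()]).
#' @param tweet_ids Ordered column universe; defaults to the distinct
#'   tweet ids in `mentions`, sorted.
#' @return A sparse `Matrix::ngCMatrix`-backed binary matrix with entity
#'   rownames and tweet-id colnames.
#' @export
build_incidence <- function(mentions, entities, tweet_ids = NULL) {
  if (is.null(tweet_ids)) tweet_ids <- sort(unique(mentions$tweet_id))
  sub <- mentions[mentions$canonical %in% entities &
                    mentions$tweet_id %in% tweet_ids, , drop = FALSE]
  i <- match(sub$canonical, entities)
  j <- match(sub$tweet_id, tweet_ids)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(entities), length(tweet_ids)),
                            dimnames = list(entities, tweet_ids))
  m@x[] <- 1  # collapse multiplicity to binary
  keep <- Matrix::rowSums(m) > 0
  m[keep, , drop = FALSE]
}

#' Cosine similarity between binary incidence rows
#'
#' For binary rows this is the shared-tweet overlap normalized by the
#' geometric mean of the support sizes:
#' `|T_i inter T_j| / sqrt(|T_i| |T_j|)`.
#'
#' @param m Incidence matrix (rows = entities).
#' @param m2 Optional second matrix with identical columns; similarities
#'   are then computed between rows of `m` and rows of `m2`.
#' @return Dense similarity matrix in `[0, 1]`.
#' @export
cosine_rows <- function(m, m2 = NULL) {
  if (any(Matrix::rowSums(m) == 0) || (!is.null(m2) && any(Matrix::rowSums(m2) == 0))) {
    stop("cosine_rows: zero row vector has undefined similarity", call. = FALSE)
  }
  if (is.null(m2)) {
    cross <- as.matrix(Matrix::tcrossprod(m))
    nrm <- sqrt(Matrix::rowSums(m))
    cross / outer(nrm, nrm)
  } else {
    if (ncol(m) != ncol(m2) || !identical(colnames(m), colnames(m2))) {
      stop("cosine_rows: column universes must match", call. = FALSE)
    }
    cross <- as.matrix(Matrix::tcrossprod(m, m2))
    cross / outer(sqrt(Matrix::rowSums(m)), sqrt(Matrix::rowSums(m2)))
  }
}

new_cooc_network <- function(nodes, edges, tau) {
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$name))
  nodes$degree <- as.integer(deg[nodes$name])
  structure(list(nodes = nodes, edges = edges, tau = tau), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (tau = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$tau))
  invisible(x)
}

#' Build a thresholded cosine co-occurrence network
#'
#' Undirected weighted graph over the incidence rows: an edge joins two
#' entities iff their cosine similarity strictly exceeds `tau`. Nodes left
#' with degree 0 after thresholding are pruned by default (mirroring the
#' node-count reductions such networks show after filtering).
#'
#' @param m Incidence matrix from [build_incidence()].
#' @param tau Similarity threshold in `[0, 1)`; strict inequality.
#' @param classes Optional named vector canonical -> class for node
#'   annotation.
#' @param drop_isolated Prune zero-degree nodes (default `TRUE`).
#' @return A `cooc_network`: `nodes` (name, class, degree), `edges`
#'   (from, to, weight), `tau`.
#' @export
build_network <- function(m, tau = 0.005, classes = NULL, drop_isolated = TRUE) {
  S <- cosine_rows(m)
  nm <- rownames(m)
  idx <- which(upper.tri(S) & S > tau, arr.ind = TRUE)
  edges <- data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]],
                      weight = S[idx], stringsAsFactors = FALSE)
  nodes <- data.frame(name = nm,
                      class = if (is.null(classes)) NA_character_ else
                        unname(classes[nm]),
                      stringsAsFactors = FALSE)
  net <- new_cooc_network(nodes, edges, tau)
  if (drop_isolated) {
    keep <- net$nodes$degree > 0L
    net$nodes <- net$nodes[keep, , drop = FALSE]
    rownames(net$nodes) <- NULL
  }
  net
}

#' Build a drug-symptom co-occurrence network
#'
#' Cross-class network over two incidence matrices sharing the same tweet
#' columns. By default only drug-symptom edges are emitted
#' (`within_class = FALSE`); set `within_class = TRUE` to also threshold
#' within-class similarities over the union row set.
#'
#' @param drug_m,symptom_m Incidence matrices with identical column
#'   ordering.
#' @param tau Threshold; default 0.05 for the cross-class mode.
#' @param within_class Also include drug-drug and symptom-symptom edges.
#' @param drop_isolated Prune zero-degree nodes.
#' @return A `cooc_network` with node classes `drug`/`symptom`.
#' @export
drug_symptom_network <- function(drug_m, symptom_m, tau = 0.05,
                                 within_class = FALSE, drop_isolated = TRUE) {
  if (ncol(drug_m) != ncol(symptom_m) ||
      !identical(colnames(drug_m), colnames(symptom_m))) {
    stop("drug_symptom_network: column orderings must be identical", call. = FALSE)
  }
  classes <- c(stats::setNames(rep("drug", nrow(drug_m)), rownames(drug_m)),
               stats::setNames(rep("symptom", nrow(symptom_m)), rownames(symptom_m)))
  if (within_class) {
    both <- rbind(drug_m, symptom_m)
    return(build_network(both, tau = tau, classes = classes,
                         drop_isolated = drop_isolated))
  }
  S <- cosine_rows(drug_m, symptom_m)
  idx <- which(S > tau, arr.ind = TRUE)
  edges <- data.frame(from = rownames(drug_m)[idx[, 1]],
                      to = rownames(symptom_m)[idx[, 2]],
                      weight = S[idx], stringsAsFactors = FALSE)
  nodes <- data.frame(name = names(classes), class = unname(classes),
                      stringsAsFactors = FALSE)
  net <- new_cooc_network(nodes, edges, tau)
  if (drop_isolated) {
    net$nodes <- net$nodes[net$nodes$degree > 0L, , drop = FALSE]
    rownames(net$nodes) <- NULL
  }
  net
}

edge_weight_matrix <- function(network) {
  nm <- network$nodes$name
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(network$edges)) {
    i <- match(network$edges$from, nm)
    j <- match(network$edges$to, nm)
    A[cbind(i, j)] <- network$edges$weight
    A[cbind(j, i)] <- network$edges$weight
  }
  A
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ Sigma_in,c / 2m - (Sigma_tot,c / 2m)^2 ]` where
#' `Sigma_in,c` is twice the intra-community edge weight, `Sigma_tot,c`
#' the total strength of community c, and `m` the total edge weight. An
#' empty edge set yields `Q = 0` with a warning.
#'
#' @param network A `cooc_network`.
#' @param membership Named vector (or vector aligned with
#'   `network$nodes$name`) of community ids.
#' @return Modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(network, membership) {
  nm <- network$nodes$name
  if (!is.null(names(membership))) membership <- membership[nm]
  if (length(membership) != length(nm) || anyNA(membership)) {
    stop("modularity_q: membership must cover every node", call. = FALSE)
  }
  e <- network$edges
  if (!nrow(e)) {
    warning("modularity_q: empty edge set; Q defined as 0")
    return(0)
  }
  m <- sum(e$weight)
  ci <- membership[match(e$from, nm)]
  cj <- membership[match(e$to, nm)]
  Sin <- tapply(2 * e$weight[ci == cj], factor(ci[ci == cj], levels = unique(membership)),
                sum, default = 0)
  strength <- stats::setNames(numeric(length(nm)), nm)
  for (k in seq_len(nrow(e))) {
    strength[e$from[k]] <- strength[e$from[k]] + e$weight[k]
    strength[e$to[k]] <- strength[e$to[k]] + e$weight[k]
  }
  Stot <- tapply(strength, factor(membership, levels = unique(membership)), sum,
                 default = 0)
  as.numeric(sum(Sin / (2 * m) - (Stot / (2 * m))^2))
}

#' Louvain community detection
#'
#' Fast-unfolding modularity maximization: repeated local moving of nodes
#' to the neighboring community with the largest positive modularity gain
#' (ties to the lowest community id), followed by graph aggregation, until
#' no gain remains. Nodes are visited in sorted name order; a `seed`
#' shuffles the visiting order reproducibly.
#'
#' @param network A non-empty `cooc_network`.
#' @param resolution Resolution parameter gamma (default 1 = classic Q).
#' @param seed Optional integer; if given, the per-pass visiting order is
#'   a seeded shuffle.
#' @return List with `membership` (named integer vector, consecutive ids)
#'   and `modularity` (Q of the returned partition at resolution 1).
#' @export
louvain <- function(network, resolution = 1.0, seed = NULL) {
  nm <- network$nodes$name
  if (!length(nm)) stop("louvain: empty network", call. = FALSE)
  A <- edge_weight_matrix(network)
  run <- function() {
    comm_of_orig <- seq_along(nm)            # original node -> community
    repeat {
      n <- nrow(A)
      memb <- seq_len(n)
      k <- rowSums(A)
      two_m <- sum(A)
      if (two_m == 0) break
      selfw <- diag(A)
      improved_any <- FALSE
      repeat {
        moved <- FALSE
        order_idx <- if (is.null(seed)) seq_len(n) else sample.int(n)
        for (i in order_idx) {
          ci <- memb[i]
          memb[i] <- 0L
          # weight from i to each community (excluding self-loop)
          w_i <- A[i, ]
          w_i[i] <- 0
          comm_w <- tapply(w_i[memb > 0], memb[memb > 0], sum)
          tot <- tapply(k[memb > 0], memb[memb > 0], sum)
          cand <- as.integer(names(comm_w))
          gain <- 2 * comm_w / two_m -
            resolution * 2 * k[i] * tot[as.character(cand)] / (two_m^2)
          # rejoining own (old) community has gain too; include old comm even
          # if no remaining neighbors link to it
          if (!(ci %in% cand)) {
            tot_ci <- sum(k[memb == ci])
            gain <- c(gain, stats::setNames(-resolution * 2 * k[i] * tot_ci / (two_m^2),
                                            as.character(ci)))
            cand <- c(cand, ci)
          }
          best <- cand[order(-gain, cand)][1L]
          if (gain[[as.character(best)]] <= gain[[as.character(ci)]] + 1e-15) {
            best <- ci
          }
          memb[i] <- best
          if (best != ci) moved <- TRUE
        }
        if (!moved) break
        improved_any <- TRUE
      }
      memb <- as.integer(factor(memb))
      if (!improved_any || length(unique(memb)) == n) break
      comm_of_orig <- memb[comm_of_orig]
      # aggregate
      nc <- max(memb)
      B <- matrix(0, nc, nc)
      for (a in seq_len(n)) {
        for (b in seq_len(n)) {
          B[memb[a], memb[b]] <- B[memb[a], memb[b]] + A[a, b]
        }
      }
      A <- B
    }
    comm_of_orig
  }
  memb <- if (is.null(seed)) run() else with_seed(seed, run())
  memb <- as.integer(factor(memb))
  names(memb) <- nm
  list(membership = memb, modularity = modularity_q(network, memb))
}

#' Annotate network nodes with ATC classes
#'
#' @param network A `cooc_network`.
#' @param atc_map Named vector canonical -> ATC level-1 letter; unmapped
#'   nodes are labeled `"unknown"`.
#' @return The network with an `atc` node column.
#' @export
annotate_atc <- function(network, atc_map) {
  a <- unname(atc_map[network$nodes$name])
  a[is.na(a)] <- "unknown"
  network$nodes$atc <- a
  network
}

#' Agreement between a partition and a reference labeling
#'
#' Adjusted Rand index and normalized mutual information, computed over
#' the nodes present in both labelings (e.g. nodes with a known ATC
#' class).
#'
#' @param partition Named vector node -> community.
#' @param reference Named vector node -> reference label; `"unknown"` and
#'   `NA` entries are excluded.
#' @return List with `ari` and `nmi`.
#' @export
partition_agreement <- function(partition, reference) {
  keep <- intersect(names(partition),
                    names(reference)[!is.na(reference) & reference != "unknown"])
  if (!length(keep)) stop("partition_agreement: no overlapping labeled nodes", call. = FALSE)
  list(ari = adjusted_rand_index(partition[keep], reference[keep]),
       nmi = normalized_mutual_info(partition[keep], reference[keep]))
}

#' Adjusted Rand index between two labelings
#' @param a,b Equal-length label vectors.
#' @return ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  as.numeric((sum_ij - expected) / (maxi - expected))
}

#' Normalized mutual information between two labelings
#' @param a,b Equal-length label vectors.
#' @return NMI in `[0, 1]` (arithmetic-mean normalization).
#' @export
normalized_mutual_info <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
  }
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  as.numeric(2 * mi / (ha + hb))
}

#' Top-k strongest neighbors of a node
#'
#' Descending by edge weight, ties broken by neighbor name; returns all
#' neighbors when fewer than k exist.
#'
#' @param network A `cooc_network`.
#' @param node Node name.
#' @param k How many neighbors (default 10).
#' @return Data frame `neighbor, weight`.
#' @export
top_neighbors <- function(network, node, k = 10L) {
  if (!node %in% network$nodes$name) stop("unknown node: ", node, call. = FALSE)
  e <- network$edges
  inc <- e$from == node | e$to == node
  nb <- ifelse(e$from[inc] == node, e$to[inc], e$from[inc])
  w <- e$weight[inc]
  ord <- order(-w, nb)
  utils::head(data.frame(neighbor = nb[ord], weight = w[ord],
                         stringsAsFactors = FALSE, row.names = NULL), k)
}
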