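# Independent oracles and small fixture builders. These deliberately take
# the dumb, brute-force route so they share no code path with the package.

toy_lexicon <- function() {
  lexicon(surface = c("hcq", "hydroxychloroquine", "ivermectin", "ivm",
                      "vitamin", "vitamin d", "zinc", "fever", "cough"),
          canonical = c("hydroxychloroquine", "hydroxychloroquine", "ivermectin",
                        "ivermectin", "vitamin", "vitamin d", "zinc", "fever", "cough"),
          class = c("drug", "drug", "drug", "drug", "drug", "drug", "drug",
                    "symptom", "symptom"),
          atc = c("P", "P", "P", "P", NA, "A", "A", NA, NA))
}

mini_corpus <- function(texts, start = as.POSIXct("2020-02-01 12:00:00", tz = "UTC")) {
  n <- length(texts)
  df <- data.frame(tweet_id = sprintf("t%03d", seq_len(n)),
                   user_id = sprintf("u%03d", seq_len(n)),
                   created_at = start + (seq_len(n) - 1) * 3600,
                   text = texts, stringsAsFactors = FALSE)
  class(df) <- c("tweet_corpus", "data.frame")
  df
}

# mention-scan oracle: every surface occurrence with word boundaries, then
# greedy longest-match-first, left-to-right overlap resolution
brute_force_matches <- function(text, lex) {
  cand <- list()
  low <- tolower(text)
  for (r in seq_len(nrow(lex))) {
    s <- tolower(lex$surface[r])
    from <- 1L
    repeat {
      i <- regexpr(s, substr(low, from, nchar(low)), fixed = TRUE)
      if (i == -1L) break
      st <- from + as.integer(i) - 1L           # 1-based
      en <- st + nchar(s) - 1L
      before <- if (st > 1L) substr(low, st - 1L, st - 1L) else ""
      after <- if (en < nchar(low)) substr(low, en + 1L, en + 1L) else ""
      wordish <- function(ch) grepl("[a-z0-9_]", ch)
      if ((before == "" || !wordish(before)) && (after == "" || !wordish(after))) {
        cand[[length(cand) + 1L]] <- data.frame(start = st - 1L, end = en,
                                                surface = substr(text, st, en),
                                                canonical = lex$canonical[r],
                                                class = lex$class[r],
                                                stringsAsFactors = FALSE)
      }
      from <- st + 1L
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), surface = character(),
                      canonical = character(), class = character()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  keep <- logical(nrow(cand))
  cursor <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= cursor) {
      keep[i] <- TRUE
      cursor <- cand$end[i]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# set-overlap cosine oracle over binary incidence rows
cosine_overlap_oracle <- function(m) {
  supports <- apply(as.matrix(m), 1, function(r) which(r > 0))
  if (is.matrix(supports)) supports <- lapply(seq_len(ncol(supports)), function(i) supports[, i])
  n <- nrow(m)
  S <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- length(intersect(supports[[i]], supports[[j]])) /
        sqrt(length(supports[[i]]) * length(supports[[j]]))
    }
  }
  S
}

# direct-definition modularity: (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)
modularity_oracle <- function(network, membership) {
  nm <- network$nodes$name
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in seq_len(nrow(network$edges))) {
    i <- network$edges$from[r]; j <- network$edges$to[r]
    A[i, j] <- A[i, j] + network$edges$weight[r]
    A[j, i] <- A[j, i] + network$edges$weight[r]
  }
  if (!is.null(names(membership))) membership <- membership[nm]
  k <- rowSums(A)
  two_m <- sum(A)
  if (two_m == 0) return(0)
  q <- 0
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (membership[i] == membership[j]) q <- q + A[i, j] - k[i] * k[j] / two_m
    }
  }
  unname(q / two_m)
}

# enumerate all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (k in seq_len(maxid + 1L)) rec(c(prefix, k), max(maxid, k))
  }
  rec(integer(), 0L)
  out
}

# explicit pair-counting adjusted Rand index
ari_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  num / den
}

make_net <- function(nodes, edges, tau = 0) {
  drugpulse:::new_cooc_network(nodes, edges, tau)
}

two_triangles <- function() {
  make_net(data.frame(name = letters[1:6], class = NA_character_),
           data.frame(from = c("a", "b", "a", "d", "e", "d"),
                      to = c("b", "c", "c", "e", "f", "f"), weight = 1))
}

random_incidence <- function(n_ent, n_tw, p = 0.15) {
  repeat {
    m <- Matrix::Matrix(stats::runif(n_ent * n_tw) < p, nrow = n_ent, sparse = TRUE) * 1
    if (all(Matrix::rowSums(m) > 0)) break
  }
  dimnames(m) <- list(sprintf("e%02d", seq_len(n_ent)), sprintf("t%03d", seq_len(n_tw)))
  m
}

# block-structured planted topics: topic k puts 90% of its mass uniformly
# on its own V/K-word block, 10% on the remainder -- the standard
# topic-recovery fixture, and the only way a V-word world is actually
# realized (Dirichlet(0.01)-sampled topics collapse to a handful of words)
planted_topics <- function(K = 3, V = 60, own_mass = 0.9) {
  block <- V %/% K
  phi <- matrix((1 - own_mass) / (V - block), K, V)
  for (k in seq_len(K)) phi[k, ((k - 1) * block + 1):(k * block)] <- own_mass / block
  phi
}

# match estimated to planted topics over all permutations (small K),
# returning the minimal mean total-variation distance and the permutation
match_topics_tv <- function(phi_est, phi_true) {
  K <- nrow(phi_true)
  perms <- rbind(seq_len(K))
  if (K > 1) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), , drop = FALSE]
  }
  best <- Inf; best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    tv <- mean(vapply(seq_len(K), function(k)
      0.5 * sum(abs(phi_est[p[k], ] - phi_true[k, ])), 0))
    if (tv < best) { best <- tv; best_p <- p }
  }
  list(tv = best, perm = best_p)
}
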