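test_that("incidence matrices are binary with no all-zero rows", {
  men <- data.frame(tweet_id = c("t1", "t1", "t2", "t3"),
                    canonical = c("a", "a", "a", "b"),
                    class = "drug", stringsAsFactors = FALSE)
  m <- build_incidence(men, c("a", "b", "ghost"), c("t1", "t2", "t3"))
  expect_equal(rownames(m), c("a", "b"))       # ghost row dropped
  expect_equal(as.numeric(m["a", ]), c(1, 1, 0)) # double mention collapsed
  expect_true(all(m@x == 1))

  # recount oracle: row sums equal distinct-tweet counts from a direct scan
  cfg <- generator_config(n_tweets = 1000, url_fraction = 0, seed = 3)
  sim <- generate_corpus(cfg)
  tm <- sim$truth$mentions
  ents <- sort(unique(tm$canonical))
  mm <- build_incidence(tm, ents, sim$corpus$tweet_id)
  scan <- vapply(rownames(mm), function(e)
    length(unique(tm$tweet_id[tm$canonical == e])), 0L)
  expect_equal(unname(Matrix::rowSums(mm)), unname(scan[rownames(mm)]))
})

test_that("cosine similarity equals the set-overlap closed form", {
  m <- Matrix::Matrix(rbind(c(1, 1, 1, 1, 0, 0), c(1, 1, 0, 0, 1, 0)),
                      sparse = TRUE)
  dimnames(m) <- list(c("u", "v"), paste0("t", 1:6))
  S <- cosine_rows(m)
  expect_equal(S["u", "u"], 1)
  expect_equal(S["u", "v"], 2 / sqrt(12), tolerance = 1e-12)  # 0.57735

  disjoint <- Matrix::Matrix(rbind(c(1, 0), c(0, 1)), sparse = TRUE,
                             dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(cosine_rows(disjoint)["a", "b"], 0)
  expect_error(cosine_rows(rbind(as.matrix(m), z = 0)), "zero row")
})

test_that("network thresholding is strict and brute-force verified", {
  # 5-entity toy incidence printed in full
  m <- Matrix::Matrix(rbind(
    a = c(1, 1, 1, 0, 0, 0, 0, 0),
    b = c(1, 1, 0, 1, 0, 0, 0, 0),
    c = c(0, 0, 1, 1, 1, 0, 0, 0),
    d = c(0, 0, 0, 0, 0, 1, 1, 0),
    e = c(0, 0, 0, 0, 0, 1, 1, 1)), sparse = TRUE)
  colnames(m) <- paste0("t", 1:8)
  tau <- 0.3
  net <- build_network(m, tau = tau, drop_isolated = FALSE)
  S <- cosine_overlap_oracle(m)
  want <- which(upper.tri(S) & S > tau, arr.ind = TRUE)
  expect_equal(nrow(net$edges), nrow(want))
  for (r in seq_len(nrow(want))) {
    i <- rownames(S)[want[r, 1]]; j <- rownames(S)[want[r, 2]]
    w <- net$edges$weight[(net$edges$from == i & net$edges$to == j) |
                            (net$edges$from == j & net$edges$to == i)]
    expect_equal(w, S[i, j], tolerance = 1e-12)
  }

  # tau = 0 where every pair shares a tweet -> complete graph
  full <- Matrix::Matrix(rbind(x = c(1, 1), y = c(1, 0), z = c(1, 1)), sparse = TRUE,
                         dimnames = list(c("x", "y", "z"), c("t1", "t2")))
  expect_equal(nrow(build_network(full, tau = 0)$edges), 3L)

  # strict inequality: at tau just below 1 only perfect co-occurrence
  # survives; at tau = 1 even weight-1 edges are excluded
  twin <- Matrix::Matrix(rbind(p = c(1, 1, 0), q = c(1, 1, 0), r = c(1, 0, 1)),
                         sparse = TRUE,
                         dimnames = list(c("p", "q", "r"), paste0("t", 1:3)))
  nearly <- build_network(twin, tau = 1 - 1e-9)
  expect_equal(nrow(nearly$edges), 1L)
  expect_equal(sort(c(nearly$edges$from, nearly$edges$to)), c("p", "q"))
  expect_equal(nrow(build_network(twin, tau = 1)$edges), 0L)

  # isolated-node pruning
  expect_false("r" %in% nearly$nodes$name)
  kept <- build_network(twin, tau = 1 - 1e-9, drop_isolated = FALSE)
  expect_true("r" %in% kept$nodes$name)
})

test_that("raising tau never adds nodes or edges (nestedness)", {
  set.seed(12)
  m <- random_incidence(12, 150)
  prev_edges <- NULL
  prev_nodes <- NULL
  for (tau in c(0, 0.005, 0.05, 0.5)) {
    net <- build_network(m, tau = tau)
    ekey <- paste(net$edges$from, net$edges$to)
    if (!is.null(prev_edges)) {
      expect_true(all(ekey %in% prev_edges))
      expect_true(all(net$nodes$name %in% prev_nodes))
    }
    prev_edges <- ekey
    prev_nodes <- net$nodes$name
  }
})

test_that("drug-symptom networks emit cross-class edges on aligned columns", {
  dm <- Matrix::Matrix(rbind(drugx = c(1, 1, 1, 0)), sparse = TRUE)
  sm <- Matrix::Matrix(rbind(symy = c(1, 1, 1, 0), symz = c(0, 0, 0, 1)), sparse = TRUE)
  colnames(dm) <- colnames(sm) <- paste0("t", 1:4)
  net <- drug_symptom_network(dm, sm, tau = 0.05)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1.0)   # symptom present exactly where drug is
  expect_setequal(net$nodes$class, c("drug", "symptom"))
  # no within-class edges in default mode
  cls <- stats::setNames(net$nodes$class, net$nodes$name)
  expect_true(all(cls[net$edges$from] != cls[net$edges$to]))

  bad <- sm[, c(2, 1, 3, 4)]
  expect_error(drug_symptom_network(dm, bad, 0.05), "identical")

  # planted drug-symptom pairing surfaces as the top-weight edge
  ents <- list(entity_spec("drugx", class = "drug", base_rate = 0.03),
               entity_spec("drugo", class = "drug", base_rate = 0.03),
               entity_spec("symy", class = "symptom", base_rate = 0.03),
               entity_spec("symo", class = "symptom", base_rate = 0.03))
  cfg <- generator_config(n_tweets = 15000, entity_lexicon = ents,
                          community_blocks = list(list(members = c("drugx", "symy"),
                                                       boost = 20)),
                          url_fraction = 0, seed = 29)
  sim <- generate_corpus(cfg)
  tm <- sim$truth$mentions
  dmat <- build_incidence(tm, c("drugx", "drugo"), sim$corpus$tweet_id)
  smat <- build_incidence(tm, c("symy", "symo"), sim$corpus$tweet_id)
  net2 <- drug_symptom_network(dmat, smat, tau = 0)
  top <- net2$edges[which.max(net2$edges$weight), ]
  expect_setequal(c(top$from, top$to), c("drugx", "symy"))
})

test_that("modularity matches hand computations and the direct-definition oracle", {
  net <- two_triangles()
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_q(net, memb), 0.5, tolerance = 1e-12)
  expect_equal(modularity_q(net, stats::setNames(rep(1, 6), letters[1:6])), 0)

  # weighted random graphs vs oracle
  set.seed(31)
  for (rep in 1:5) {
    n <- 6
    nodes <- data.frame(name = letters[1:n], class = NA_character_)
    pairs <- t(combn(letters[1:n], 2))
    take <- runif(nrow(pairs)) < 0.5
    if (!any(take)) take[1] <- TRUE
    edges <- data.frame(from = pairs[take, 1], to = pairs[take, 2],
                        weight = runif(sum(take), 0.1, 2))
    g <- make_net(nodes, edges)
    memb <- stats::setNames(sample(1:3, n, replace = TRUE), letters[1:n])
    expect_equal(modularity_q(g, memb), modularity_oracle(g, memb), tolerance = 1e-12)
  }

  empty <- make_net(data.frame(name = c("a", "b"), class = NA_character_),
                    data.frame(from = character(), to = character(),
                               weight = numeric()))
  expect_warning(q <- modularity_q(empty, c(a = 1, b = 2)), "empty edge set")
  expect_equal(q, 0)
})

test_that("louvain maximizes modularity and never beats exhaustive search", {
  net <- two_triangles()
  lv <- louvain(net)
  expect_equal(lv$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(lv$membership)), 2L)
  expect_equal(lv$modularity, modularity_q(net, lv$membership), tolerance = 1e-15)

  single <- make_net(data.frame(name = "solo", class = NA_character_),
                     data.frame(from = character(), to = character(),
                                weight = numeric()))
  suppressWarnings(lone <- louvain(single))
  expect_equal(length(unique(lone$membership)), 1L)
  expect_equal(lone$modularity, 0)

  # seeded runs are reproducible
  set.seed(77)
  m <- random_incidence(10, 80)
  g <- build_network(m, tau = 0.05)
  expect_identical(louvain(g, seed = 4), louvain(g, seed = 4))

  # exhaustive oracle on small graphs: louvain Q <= global optimum,
  # and random partitions never exceed it either
  set.seed(55)
  for (rep in 1:3) {
    n <- 6
    nodes <- data.frame(name = letters[1:n], class = NA_character_)
    pairs <- t(combn(letters[1:n], 2))
    take <- runif(nrow(pairs)) < 0.6
    if (!any(take)) take[1] <- TRUE
    edges <- data.frame(from = pairs[take, 1], to = pairs[take, 2],
                        weight = runif(sum(take), 0.2, 1.5))
    g <- make_net(nodes, edges)
    best <- max(vapply(all_partitions(n), function(p)
      modularity_q(g, stats::setNames(p, letters[1:n])), 0))
    expect_lte(louvain(g)$modularity, best + 1e-9)
    singletons <- stats::setNames(seq_len(n), letters[1:n])
    expect_gte(louvain(g)$modularity, modularity_q(g, singletons) - 1e-12)
    for (i in 1:10) {
      rnd <- stats::setNames(sample(1:3, n, replace = TRUE), letters[1:n])
      expect_lte(modularity_q(g, rnd), best + 1e-9)
    }
  }
})

test_that("ATC annotation and partition agreement behave at the extremes", {
  net <- two_triangles()
  net <- annotate_atc(net, c(a = "N", b = "N", c = "N", d = "J"))
  expect_equal(net$nodes$atc[net$nodes$name == "e"], "unknown")

  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  ref_same <- c(a = "x", b = "x", c = "x", d = "y", e = "y", f = "y")
  ag <- partition_agreement(part, ref_same)
  expect_equal(ag$ari, 1)
  expect_equal(ag$nmi, 1)

  one_comm <- stats::setNames(rep(1, 6), letters[1:6])
  expect_equal(partition_agreement(one_comm, ref_same)$ari, 0)

  # pair-counting oracle on random labelings
  set.seed(61)
  for (i in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("top_neighbors ranks by weight with name tie-breaking", {
  nodes <- data.frame(name = c("hub", "n1", "n2", "n3"), class = NA_character_)
  edges <- data.frame(from = c("hub", "hub", "hub"), to = c("n1", "n2", "n3"),
                      weight = c(0.5, 0.9, 0.5))
  g <- make_net(nodes, edges)
  nb <- top_neighbors(g, "hub", k = 10)
  expect_equal(nb$neighbor, c("n2", "n1", "n3"))   # tie 0.5 broken by name
  expect_equal(nrow(top_neighbors(g, "hub", k = 2)), 2L)
  expect_error(top_neighbors(g, "ghost"), "unknown node")
})

test_that("GEXF and GraphML exports round-trip through Gephi-loadable files", {
  set.seed(14)
  m <- random_incidence(8, 60)
  net <- build_network(m, tau = 0.02,
                       classes = stats::setNames(rep("drug", 8), rownames(m)))
  part <- louvain(net)$membership
  for (fmt in c("gexf", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, f, membership = part)
    back <- import_network(f)
    expect_setequal(back$nodes$name, net$nodes$name)
    a <- net$edges[order(net$edges$from, net$edges$to), ]
    b <- back$edges[order(back$edges$from, back$edges$to), ]
    expect_equal(a$from, b$from)
    expect_equal(a$weight, b$weight, tolerance = 1e-9)
  }

  # empty network still yields a valid file
  empty <- make_net(data.frame(name = character(), class = character()),
                    data.frame(from = character(), to = character(),
                               weight = numeric()))
  f <- withr::local_tempfile(fileext = ".gexf")
  export_network(empty, f)
  expect_equal(nrow(import_network(f)$nodes), 0L)

  # 2-node single-edge file contains exactly one weighted edge element
  duo <- make_net(data.frame(name = c("a", "b"), class = "drug"),
                  data.frame(from = "a", to = "b", weight = 0.25))
  f2 <- withr::local_tempfile(fileext = ".gexf")
  export_network(duo, f2)
  doc <- xml2::read_xml(f2)
  xml2::xml_ns_strip(doc)
  edges <- xml2::xml_find_all(doc, ".//edges/edge")
  expect_length(edges, 1L)
  expect_equal(as.numeric(xml2::xml_attr(edges, "weight")), 0.25)

  # edge CSV
  f3 <- withr::local_tempfile(fileext = ".csv")
  export_network(duo, f3)
  csv <- utils::read.csv(f3)
  expect_equal(names(csv), c("source", "target", "weight"))
  expect_equal(csv$weight, 0.25)

  # incidence MTX round trip
  f4 <- withr::local_tempfile(fileext = ".mtx")
  write_incidence_mtx(m, f4)
  back <- read_incidence_mtx(f4)
  expect_equal(as.matrix(back), as.matrix(m) * 1)
})
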