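test_that("marginal probabilities are within-set pair fractions", {
  # one collection sampled 100% of the time
  s <- fake_posterior(list(sets = list(c("a", "b"), c("c", "d")), freq = 10))
  G <- marginal_probabilities(s)
  w <- stats::setNames(G$edges$weight, paste(G$edges$u, G$edges$v))
  expect_equal(unname(w[c("a b", "c d")]), c(1, 1))
  expect_false("a c" %in% names(w))   # across sets contributes nothing

  # two collections at 60/40 sharing the pair (a,b) only in the first
  s2 <- fake_posterior(list(sets = list(c("a", "b")), freq = 6),
                       list(sets = list(c("a", "c")), freq = 4))
  G2 <- marginal_probabilities(s2)
  w2 <- stats::setNames(G2$edges$weight, paste(G2$edges$u, G2$edges$v))
  expect_equal(unname(w2["a b"]), 0.6)
  expect_equal(unname(w2["a c"]), 0.4)
})

test_that("marginal probabilities equal a brute-force recount", {
  set.seed(14)
  genes <- letters[1:8]
  entries <- lapply(1:12, function(i) {
    g <- sample(genes, 4)
    list(sets = list(g[1:2], g[3:4]), freq = sample(1:20, 1))
  })
  s <- do.call(fake_posterior, entries)
  G <- marginal_probabilities(s)
  # recount directly from the collection log
  total <- sum(vapply(s$collections, `[[`, 0, "freq"))
  for (r in seq_len(nrow(G$edges))) {
    u <- G$edges$u[r]; v <- G$edges$v[r]
    hits <- sum(vapply(s$collections, function(cl)
      if (any(vapply(cl$sets, function(set) all(c(u, v) %in% set), TRUE)))
        cl$freq else 0, 0))
    expect_equal(G$edges$weight[r], hits / total)
  }
})

test_that("module extraction thresholds edges and keeps components >= 2", {
  s <- fake_posterior(list(sets = list(c("a", "b")), freq = 9),
                      list(sets = list(c("b", "c")), freq = 3),
                      list(sets = list(c("d", "e")), freq = 1))
  G <- marginal_probabilities(s)
  # path a-b-c with weights (0.9 * ... ) and an isolated light pair
  ms <- extract_modules(G, 0.5)
  expect_equal(ms$modules, list(c("a", "b")))
  # delta above every weight removes all modules
  expect_length(extract_modules(G, 0.95)$modules, 0)
  # delta = 0 keeps everything connected through cut vertices
  ms0 <- extract_modules(G, 0)
  expect_setequal(ms0$modules[[1]], c("a", "b", "c"))
})

test_that("components match an independent union-find computation", {
  set.seed(15)
  for (rep in 1:10) {
    genes <- paste0("g", 1:12)
    entries <- lapply(1:8, function(i)
      list(sets = list(sample(genes, 3)), freq = sample(1:10, 1)))
    s <- do.call(fake_posterior, entries)
    G <- marginal_probabilities(s)
    delta <- stats::runif(1, 0, 1)
    ms <- extract_modules(G, delta)
    keep <- G$edges[G$edges$weight >= delta, , drop = FALSE]
    verts <- unique(c(keep$u, keep$v))
    comp <- union_find_components(verts, keep$u, keep$v)
    comp <- comp[lengths(comp) >= 2]
    expect_setequal(vapply(ms$modules, paste, "", collapse = ","),
                    vapply(comp, paste, "", collapse = ","))
  }
})

test_that("modules are monotone in delta: raising delta never merges", {
  set.seed(16)
  entries <- lapply(1:10, function(i)
    list(sets = list(sample(paste0("g", 1:9), 3)), freq = sample(1:10, 1)))
  s <- do.call(fake_posterior, entries)
  G <- marginal_probabilities(s)
  deltas <- sort(stats::runif(5))
  prev <- NULL
  for (d in deltas) {
    cur <- extract_modules(G, d)$modules
    if (!is.null(prev)) {
      # every module at the higher delta is contained in one lower-delta module
      for (mod in cur) {
        container <- Filter(function(p) all(mod %in% p), prev)
        expect_gte(length(container), 1)
      }
    }
    prev <- cur
  }
  expect_gt(length(extract_modules(G, 0)$modules), 0)
})

test_that("auto delta takes the largest-gap midpoint above the floor", {
  G <- structure(list(edges = data.frame(u = c("a", "b", "c"),
                                         v = c("b", "c", "d"),
                                         weight = c(0.9, 0.85, 0.2)),
                      vertices = letters[1:4],
                      is_subtype = stats::setNames(rep(FALSE, 4), letters[1:4])),
                 class = "marginal_probability_graph")
  expect_equal(auto_delta(G), 0.525)
  G$edges$weight <- rep(0.4, 3)        # all equal: keep every edge
  expect_equal(auto_delta(G), 0.4)
  G$edges$weight <- c(0.01, 0.02, 0.03) # everything under the floor
  expect_equal(auto_delta(G), 0.05)
  G$edges <- G$edges[0, ]
  expect_error(auto_delta(G), "no edges")
})

test_that("merging runs averages normalized frequencies", {
  a <- fake_posterior(list(sets = list(c("a", "b")), freq = 8),
                      list(sets = list(c("c", "d")), freq = 2))
  # identical run at a different scale: merge is a no-op after normalization
  a10 <- fake_posterior(list(sets = list(c("a", "b")), freq = 80),
                        list(sets = list(c("c", "d")), freq = 20))
  m <- merge_runs(a, a10)
  f <- vapply(m$collections, `[[`, 0, "freq")
  expect_equal(sort(unname(f)), c(0.2, 0.8))
  expect_equal(sum(f), 1)

  # disjoint supports with equal totals: half the within-run proportion
  b <- fake_posterior(list(sets = list(c("x", "y")), freq = 10))
  m2 <- merge_runs(a, b)
  f2 <- vapply(m2$collections, `[[`, 0, "freq")
  expect_equal(sum(f2), 1)
  expect_equal(unname(f2[["x,y"]]), 0.5)
  expect_equal(unname(f2[["a,b"]]), 0.4)

  # commutative
  m3 <- merge_runs(b, a)
  expect_equal(m3$collections[names(m2$collections)], m2$collections)

  # merged marginal probability is the mean of per-run ones (disjoint supports)
  Ga <- marginal_probabilities(a); Gb <- marginal_probabilities(b)
  Gm <- marginal_probabilities(m2)
  wm <- stats::setNames(Gm$edges$weight, paste(Gm$edges$u, Gm$edges$v))
  expect_equal(unname(wm["a b"]), 0.8 / 2)
  expect_equal(unname(wm["x y"]), 1 / 2)
})

test_that("co-occurrence test matches the hypergeometric closed form", {
  # perfectly disjoint indicators: observed co-occurrence is minimal
  mat <- matrix(0L, 2, 20, dimnames = list(c("a", "b"), paste0("s", 1:20)))
  mat[1, 1:10] <- 1L; mat[2, 11:20] <- 1L
  A <- alteration_matrix(mat)
  expect_equal(cooccurrence_p(A, "a", "b"), 1, tolerance = 1e-10)

  # identical indicators, margin 5 of 50: the single most extreme table
  mat2 <- matrix(0L, 2, 50, dimnames = list(c("a", "b"), paste0("s", 1:50)))
  mat2[1, 1:5] <- 1L; mat2[2, 1:5] <- 1L
  A2 <- alteration_matrix(mat2)
  expect_equal(cooccurrence_p(A2, "a", "b"), 1 / choose(50, 5),
               tolerance = 1e-12)

  # random tables against the hypergeometric upper tail
  set.seed(19)
  for (rep in 1:10) {
    n <- 30
    A3 <- random_matrix_with_margins(sample(5:25, 2), n)
    o <- sum(A3$mat[1, ] & A3$mat[2, ])
    m1 <- sum(A3$mat[1, ]); m2 <- sum(A3$mat[2, ])
    closed <- stats::phyper(o - 1, m1, n - m1, m2, lower.tail = FALSE)
    expect_equal(cooccurrence_p(A3, "g1", "g2"), closed, tolerance = 1e-10)
  }

  # degenerate margins warn and return 1
  mat4 <- matrix(1L, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_warning(p <- cooccurrence_p(alteration_matrix(mat4), "a", "b"),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(cooccurrence_p(A2, "a", "a"), "disjoint")
})

test_that("graph exports round-trip their content", {
  s <- fake_posterior(list(sets = list(c("a", "b"), c("c", "d")), freq = 3),
                      list(sets = list(c("a", "b"), c("c", "e")), freq = 1))
  G <- marginal_probabilities(s)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(G, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$weight, G$edges$weight)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph_graphml(G, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(G$edges))
  js <- withr::local_tempfile(fileext = ".json")
  write_result_json(G, extract_modules(G, 0.5), js)
  doc <- jsonlite::read_json(js)
  expect_equal(length(doc$edges), nrow(G$edges))
  expect_equal(sort(unlist(doc$modules[[1]])), c("a", "b"))
})
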