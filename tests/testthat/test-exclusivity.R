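# The germ-cell-tumor cohort tables (53 patients) recur throughout: a pair
# mutated in 16 and 6 samples sharing exactly one, and triples built on the
# 16-mutation gene. Their published mid P-values anchor the exact test.

test_that("contingency tables cross-classify samples by altered subset", {
  # pair with margins (16, 6) sharing exactly one of 53 samples
  mat <- matrix(0L, 2, 53, dimnames = list(c("KIT", "CBL"), paste0("s", 1:53)))
  mat[1, 1:16] <- 1L
  mat[2, c(16, 50:53, 49)] <- 1L   # 6 samples, one shared with row 1
  X <- contingency_table(alteration_matrix(mat), c("KIT", "CBL"))
  expect_equal(X$cells, c(32L, 15L, 5L, 1L))
  expect_equal(unname(X$margins), c(16L, 6L))
  expect_equal(exclusivity_statistic(X), 20L)
  expect_equal(coverage(X), 21L)

  # two all-zero rows: all mass in the empty cell
  z <- alteration_matrix(matrix(0L, 3, 7,
                                dimnames = list(paste0("g", 1:3),
                                                paste0("s", 1:7))))
  Xz <- contingency_table(z, c("g1", "g2"))
  expect_equal(Xz$cells, c(7L, 0L, 0L, 0L))
  expect_equal(exclusivity_statistic(Xz), 0L)
  expect_equal(coverage(Xz), 0L)

  expect_error(contingency_table(z, c("g1", "g1")), "duplicate")
  expect_error(contingency_table(z, c("g1", "nope")), "unknown")
  expect_error(contingency_table(z, "g1"), "at least two")
})

test_that("cells match a per-sample subset tally on random matrices", {
  set.seed(11)
  for (rep in 1:20) {
    A <- random_matrix_with_margins(sample(0:10, 3, replace = TRUE), 10)
    X <- contingency_table(A, alteration_names(A))
    # direct tally: count samples by their altered subset
    expected <- integer(8)
    for (j in 1:10) {
      b <- sum(A$mat[, j] * c(1L, 2L, 4L))
      expected[b + 1] <- expected[b + 1] + 1L
    }
    expect_equal(X$cells, expected)
    # margin-sum identity: sum(margins) = T + sum_{|v|>=2} |v| x_v
    wt <- vapply(0:7, function(b) sum(bitwAnd(b, c(1L, 2L, 4L)) > 0), 0)
    co_weight <- sum((X$cells * wt)[wt >= 2])
    expect_equal(sum(X$margins), exclusivity_statistic(X) + co_weight)
    # coverage bounds
    expect_gte(coverage(X), max(X$margins))
    expect_lte(coverage(X), sum(X$margins))
  }
})

test_that("table probability matches symmetry and normalizes over all tables", {
  # k=2, n=2, margins (1,1): the exclusive and co-occurring tables are the
  # two equiprobable outcomes
  X <- new_contingency_table(c(0L, 1L, 1L, 0L))
  expect_equal(table_probability(X), 0.5)
  # forced table: one margin equal to n admits a single completion
  Xf <- new_contingency_table(c(0L, 2L, 0L, 3L))  # margins (5, 3), n = 5
  expect_equal(brute_force_tails(c(5, 3), 5, 0)$n_tables, 1)
  expect_equal(table_probability(Xf), 1)
  # normalization: sum of p over every table with margins (3,2,1), n=8
  set.seed(2)
  for (rep in 1:10) {
    Y <- random_table(c(3, 2, 1), 8)
    expect_gt(table_probability(Y), 0)
    expect_lte(table_probability(Y), 1)
  }
  expect_equal(brute_force_tails(c(3, 2, 1), 8, 0)$total, 1, tolerance = 1e-10)
})

test_that("tail enumeration reproduces the disjoint-placement closed form", {
  # perfectly exclusive triple, margins (16, 9, 3), n = 53: P(T >= T_obs) is
  # the probability that three uniform supports are pairwise disjoint
  cells <- integer(8); cells[1] <- 53 - 28
  cells[1 + 1] <- 16; cells[2 + 1] <- 9; cells[4 + 1] <- 3
  X <- new_contingency_table(cells)
  te <- tail_enumeration(X)
  closed <- exp(lchoose(37, 9) - lchoose(53, 9) +
                lchoose(28, 3) - lchoose(53, 3))
  expect_equal(te$p_ge, closed, tolerance = 1e-10)
  expect_equal(te$p_gt, 0)
  expect_true(te$complete)

  # observed T = 0: the tail is the whole table space
  X0 <- random_table(c(4, 3, 2), 9)
  te0 <- mexsets:::.tail_enum(unname(X0$margins), 9L, 0L)
  expect_equal(te0$p_ge, 1, tolerance = 1e-10)

  expect_error(mexsets:::.tail_enum(c(5L, 3L), 10L, 9L), "inconsistent")
})

test_that("exact mid P-values reproduce the published cohort values", {
  # pair (16, 6) with one co-occurring sample
  pair <- exact_phi(new_contingency_table(c(32L, 15L, 5L, 1L)))
  expect_equal(round(pair$phi, 3), 0.253)
  expect_equal(pair$method, "exact")
  expect_equal(pair$phi, (pair$p_ge + pair$p_gt) / 2)

  mk_exclusive <- function(margins, n) {
    cells <- integer(2^length(margins))
    cells[1] <- n - sum(margins)
    cells[1 + 2^(seq_along(margins) - 1)] <- margins
    new_contingency_table(cells)
  }
  expect_equal(round(exact_phi(mk_exclusive(c(16, 9, 3), 53))$phi, 3), 0.002)
  expect_equal(round(exact_phi(mk_exclusive(c(16, 9, 2), 53))$phi, 3), 0.004)
  # (16, 9, 6) with two pairwise co-occurring samples (T = 27)
  cells <- integer(8)
  cells[0 + 1] <- 53 - 29; cells[1 + 1] <- 15; cells[2 + 1] <- 8
  cells[4 + 1] <- 4; cells[5 + 1] <- 1; cells[6 + 1] <- 1
  expect_equal(round(exact_phi(new_contingency_table(cells))$phi, 3), 0.023)
  # k=2, n=2, margins (1,1), exclusive: phi = (1/2 + 0)/2
  expect_equal(exact_phi(new_contingency_table(c(0L, 1L, 1L, 0L)))$phi, 0.25)
})

test_that("binomial approximation equals a direct tail summation", {
  # T = 0 gives the full tail
  z <- new_contingency_table(c(10L, 0L, 0L, 0L))
  expect_equal(binomial_phi(z)$phi, 1)
  # margins (16, 9, 3), n = 53, T = 28, p_e = 28/53
  cells <- integer(8); cells[1] <- 25
  cells[2] <- 16; cells[3] <- 9; cells[5] <- 3
  b <- binomial_phi(new_contingency_table(cells))
  p_e <- 28 / 53
  direct <- 1 - sum(sapply(0:27, function(i)
    choose(53, i) * p_e^i * (1 - p_e)^(53 - i)))
  expect_equal(b$phi, direct, tolerance = 1e-12)
  expect_equal(b$method, "binomial")
})

test_that("binomial tracks the exact value on co-occurrence-heavy tables", {
  # sparse tables (margins a few percent of n) with enriched co-occurrence
  # sit high in the tail, where the binomial null approximates the exact
  # conditional test well
  set.seed(5)
  mk <- function(n, margins, overlap) {
    mat <- matrix(0L, 3, n, dimnames = list(paste0("g", 1:3),
                                            paste0("s", seq_len(n))))
    core <- sample.int(n, overlap)     # samples altered in all three rows
    for (j in 1:3) {
      mat[j, core] <- 1L
      mat[j, sample(setdiff(seq_len(n), core), margins[j] - overlap)] <- 1L
    }
    contingency_table(alteration_matrix(mat), paste0("g", 1:3))
  }
  diffs <- replicate(25, {
    X <- mk(100, sample(4:10, 3, replace = TRUE), sample(2:3, 1))
    abs(binomial_phi(X)$phi - exact_phi(X)$phi)
  })
  expect_lt(stats::median(diffs), 0.05)
  expect_lt(max(diffs), 0.1)
})

test_that("permutation estimate is deterministic on a single-table space", {
  # one margin equal to n forces every sampled table to the same T
  X <- new_contingency_table(c(0L, 0L, 6L, 4L))   # margins (4, 10), n = 10
  set.seed(1); a <- permutation_phi(X, L = 50)
  set.seed(2); b <- permutation_phi(X, L = 50)
  expect_equal(a$phi, b$phi)
  expect_equal(a$phi, 0.5)  # constant T: (L + 0) / (2L)
  expect_equal(a$method, "permutation")
})

test_that("permutation standard error shrinks as 1/sqrt(L)", {
  X <- new_contingency_table(c(32L, 15L, 5L, 1L))
  set.seed(33)
  est <- function(L) replicate(25, permutation_phi(X, L = L)$phi)
  s1 <- stats::sd(est(500)); s2 <- stats::sd(est(8000))
  expect_gt(s1 / s2, 2)   # expect about 4, allow wide slack
})

test_that("score dispatcher routes by co-occurrence and binomial P", {
  cfg <- phi_config()
  # perfectly exclusive triple: exact route, published value
  cells <- integer(8); cells[1] <- 25
  cells[2] <- 16; cells[3] <- 9; cells[5] <- 3
  r <- phi(new_contingency_table(cells), cfg)
  expect_equal(r$method, "exact")
  expect_equal(round(r$phi, 3), 0.002)
  # 20 co-occurring samples with kappa = 10: binomial route
  heavy <- new_contingency_table(c(20L, 5L, 5L, 20L))
  expect_equal(phi(heavy, phi_config(kappa = 10))$method, "binomial")
  # wide tables always take the binomial route
  wide <- random_table(rep(2, 8), 30)
  expect_equal(phi(wide)$method, "binomial")
  # when the dispatcher takes the exact route it IS the exact value
  set.seed(21)
  for (rep in 1:10) {
    X <- random_table(sample(2:6, 3, replace = TRUE), 20)
    r <- phi(X, cfg)
    if (r$method == "exact")
      expect_equal(r$phi, exact_phi(X)$phi, tolerance = 1e-12)
  }
})

test_that("collection score is the product of per-set scores", {
  X1 <- new_contingency_table(c(0L, 1L, 1L, 0L))  # exclusive pair, phi 0.25
  expect_equal(phi(X1)$phi, 0.25)
  expect_equal(phi_collection(list(X1)), phi(X1)$phi)
  expect_equal(phi_collection(list(X1, X1)), 0.0625)
  set.seed(9)
  tables <- replicate(4, random_table(sample(2:5, 2), 12), simplify = FALSE)
  lp <- sum(vapply(tables, function(X) log(phi(X)$phi), 0))
  expect_equal(phi_collection(tables, log = TRUE), lp, tolerance = 1e-12)
})

test_that("phi lies between its tails and within (0, 1]", {
  set.seed(13)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    X <- random_table(sample(0:8, k, replace = TRUE), 8)
    r <- exact_phi(X)
    expect_lte(r$p_gt, r$p_ge)
    expect_gte(r$phi, r$p_gt)
    expect_lte(r$phi, r$p_ge)
    expect_gt(r$phi, 0)
    expect_lte(r$phi, 1)
  }
})

test_that("exact phi is nonincreasing in the observed statistic", {
  margins <- c(7, 5, 3)
  n <- 20
  phis <- vapply(0:15, function(t_obs) {
    te <- mexsets:::.tail_enum(margins, n, as.integer(t_obs))
    (te$p_ge + te$p_gt) / 2
  }, 0)
  expect_true(all(diff(phis) <= 1e-12))
})

test_that("k=2 exact phi equals the hypergeometric closed form", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    m1 <- sample(1:(n - 1), 1); m2 <- sample(1:(n - 1), 1)
    A <- random_matrix_with_margins(c(m1, m2), n)
    X <- contingency_table(A, c("g1", "g2"))
    o <- sum(A$mat[1, ] & A$mat[2, ])
    # smaller overlap = more exclusive; mid P on the co-occurrence count
    closed <- (stats::phyper(o, m1, n - m1, m2) +
               stats::phyper(o - 1, m1, n - m1, m2)) / 2
    expect_equal(exact_phi(X)$phi, closed, tolerance = 1e-10)
  }
})
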