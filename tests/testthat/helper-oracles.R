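# Independent oracles and fixture builders shared across the test files.

# Exhaustive enumeration of ALL 2^k tables with the given margins, summing
# multivariate hypergeometric probabilities over the T >= / > t_obs tails.
# Deliberately structured unlike the package's tail enumeration: it walks
# every nonempty cell (singletons included) in increasing-|v| order and
# requires the margins to be met exactly at the leaves, with no budget
# pruning and no completion step.
brute_force_tails <- function(margins, n, t_obs) {
  k <- length(margins)
  masks <- 1:(2^k - 1)
  members <- lapply(masks, function(b) which(bitwAnd(b, 2^(0:(k - 1))) > 0))
  sizes <- lengths(members)
  ord <- order(sizes)                       # increasing |v|
  p_ge <- 0; p_gt <- 0; total <- 0; ntab <- 0
  lmarg <- sum(lfactorial(margins) + lfactorial(n - margins)) -
    (k - 1) * lfactorial(n)
  rec <- function(i, mar_rem, used, lfy, t_cur) {
    if (i > length(ord)) {
      if (any(mar_rem != 0)) return()
      x0 <- n - used
      if (x0 < 0) return()
      p <- exp(lmarg - lfy - lfactorial(x0))
      total <<- total + p; ntab <<- ntab + 1
      if (t_cur >= t_obs) p_ge <<- p_ge + p
      if (t_cur > t_obs) p_gt <<- p_gt + p
      return()
    }
    v <- members[[ord[i]]]
    for (y in 0:min(c(mar_rem[v], n - used))) {
      mr <- mar_rem; mr[v] <- mr[v] - y
      rec(i + 1, mr, used + y, lfy + lfactorial(y),
          t_cur + if (length(v) == 1) y else 0)
    }
  }
  rec(1, margins, 0, 0, 0)
  list(p_ge = p_ge, p_gt = p_gt, total = total, n_tables = ntab)
}

# mid P-value from the brute-force tails
brute_force_phi <- function(margins, n, t_obs) {
  bf <- brute_force_tails(margins, n, t_obs)
  (bf$p_ge + bf$p_gt) / 2
}

# random alteration matrix with given row margins (uniform supports)
random_matrix_with_margins <- function(margins, n) {
  k <- length(margins)
  mat <- matrix(0L, k, n,
                dimnames = list(paste0("g", seq_len(k)), paste0("s", seq_len(n))))
  for (j in seq_len(k)) mat[j, sample.int(n, margins[j])] <- 1L
  alteration_matrix(mat)
}

# contingency table of a random matrix with the given margins
random_table <- function(margins, n) {
  A <- random_matrix_with_margins(margins, n)
  contingency_table(A, alteration_names(A))
}

# small deterministic alteration matrix used across module tests:
# 6 alterations, 40 samples, mixed frequencies and overlaps
toy_matrix <- function(n = 40) {
  mat <- matrix(0L, 6, n,
                dimnames = list(paste0("g", 1:6), paste0("s", seq_len(n))))
  mat[1, 1:8] <- 1L          # freq 8
  mat[2, 9:14] <- 1L         # freq 6, exclusive with g1
  mat[3, c(1:3, 15:18)] <- 1L # freq 7, overlaps g1 in 3 samples
  mat[4, c(9, 19:23)] <- 1L  # freq 6, overlaps g2 in 1 sample
  mat[5, 24:28] <- 1L        # freq 5
  mat[6, c(24, 25, 29:31)] <- 1L # freq 5, overlaps g5 in 2 samples
  alteration_matrix(mat)
}

# hand-rolled union-find connected components over an edge list
union_find_components <- function(vertices, edges_u, edges_v) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_u)) {
    ru <- find(edges_u[i]); rv <- find(edges_v[i])
    if (ru != rv) parent[[ru]] <- rv
  }
  roots <- vapply(vertices, find, "")
  unname(lapply(split(vertices, roots), sort))
}

# posterior_sample built by hand from (sets, freq) pairs
fake_posterior <- function(..., log_phis = NULL) {
  entries <- list(...)
  collections <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    sets <- lapply(e$sets, sort)
    key <- paste(sort(vapply(sets, paste, "", collapse = ",")), collapse = "|")
    collections[[key]] <- list(
      freq = e$freq,
      log_phi = if (is.null(log_phis)) log(0.5) else log_phis[i],
      sets = sets)
  }
  structure(list(collections = collections,
                 retained = sum(vapply(entries, `[[`, 0, "freq")),
                 best_log_phi = min(vapply(collections, `[[`, 0, "log_phi")),
                 best_sets = collections[[1]]$sets),
            class = "posterior_sample")
}
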