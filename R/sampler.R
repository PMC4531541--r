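# Metropolis-Hastings sampling of collections of t disjoint k-sets in
# proportion to phi(M)^-alpha, and the margin-preserving permutation null used
# for the significance threshold phi*.

#' Sampler configuration
#'
#' @param t number of alteration sets per collection.
#' @param k number of alterations per set (>= 2).
#' @param alpha exponent of the sampling weight phi(M)^-alpha; larger values
#'   concentrate the chain on the most exclusive collections. Default 2.
#' @param iterations total MCMC iterations.
#' @param burn_in iterations discarded before recording; default 10\% of
#'   \code{iterations}.
#' @param thin record every \code{thin}-th post-burn-in state.
#' @return an object of class \code{sampler_config}.
#' @export
sampler_config <- function(t, k, alpha = 2, iterations = 1e6,
                           burn_in = floor(iterations / 10), thin = 1L) {
  stopifnot(t >= 1, k >= 2, alpha >= 1, iterations >= 1,
            burn_in >= 0, burn_in < iterations, thin >= 1)
  structure(list(t = as.integer(t), k = as.integer(k), alpha = alpha,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin)),
            class = "sampler_config")
}

# canonical order-invariant identifier of a collection given per-set sorted
# index vectors
.canonical_key <- function(sets_idx) {
  keys <- vapply(sets_idx, paste, "", collapse = ",")
  paste(sort(keys), collapse = "|")
}

# memoized log phi of the set of row indices idx (sorted). Two levels: by
# set identity, and by the sufficient statistics (sorted margins, T,
# co-occurrence count) that the score actually depends on -- distinct sets
# share statistics constantly, especially among passenger genes.
.memo_phi <- function(memo, stats_memo, mat, margins, idx, config) {
  key <- paste(idx, collapse = ",")
  got <- memo[[key]]
  if (!is.null(got)) return(got)
  counts <- .colSums(mat[idx, , drop = FALSE], length(idx), ncol(mat))
  t_obs <- sum(counts == 1L)
  co <- sum(counts >= 2L)
  skey <- paste(c(sort(margins[idx]), t_obs, co), collapse = ",")
  lp <- stats_memo[[skey]]
  if (is.null(lp)) {
    lp <- .phi_margins(margins[idx], ncol(mat), t_obs, co, config)
    stats_memo[[skey]] <- lp
  }
  memo[[key]] <- lp
  lp
}

# a set is structurally valid if it holds at most one subtype row
.valid_set <- function(idx, is_subtype) sum(is_subtype[idx]) <= 1L

# random valid initial collection: t disjoint k-sets, each with at most one
# subtype row
.initial_state <- function(m, t, k, is_subtype) {
  n_sub <- sum(is_subtype)
  if (m < t * k)
    stop("t * k = ", t * k, " exceeds the number of alterations (", m, ")")
  if (m - n_sub < t * k - t)
    stop("not enough non-subtype alterations for ", t, " sets of size ", k)
  for (try in 1:100) {
    ord <- sample.int(m)
    sets <- vector("list", t)
    used <- logical(m)
    ok <- TRUE
    for (s in seq_len(t)) {
      picked <- integer(0)
      has_sub <- FALSE
      for (i in ord) {
        if (used[i]) next
        if (is_subtype[i] && has_sub) next
        picked <- c(picked, i)
        used[i] <- TRUE
        has_sub <- has_sub || is_subtype[i]
        if (length(picked) == k) break
      }
      if (length(picked) < k) { ok <- FALSE; break }
      sets[[s]] <- sort(picked)
    }
    if (ok) return(sets)
  }
  stop("could not construct a valid initial collection")
}

# Core Metropolis-Hastings run. Proposal: pick one slot uniformly, pick a
# replacement alteration among those outside the slot's set with probability
# proportional to its frequency weight (margin + 1); if the replacement
# currently sits in another set the two alterations are exchanged (keeping
# disjointness), otherwise it simply replaces the slot's occupant. The
# frequency bias focuses proposals on recurrent alterations -- where
# exclusivity signal can live -- instead of the rare-passenger tail; the
# Hastings correction below keeps the stationary distribution exactly
# phi(M)^-alpha. Proposals placing two subtype rows in one set are rejected
# outright.
.mcmc_run <- function(A, config, phi_cfg, record = TRUE) {
  mat <- A$mat
  m <- nrow(mat)
  margins <- rowSums(mat)
  is_subtype <- A$is_subtype
  t <- config$t; k <- config$k; alpha <- config$alpha
  memo <- new.env(parent = emptyenv())
  stats_memo <- new.env(parent = emptyenv())
  counts_env <- new.env(parent = emptyenv())

  w <- margins + 1                 # +1 keeps zero-margin rows reachable
  W <- sum(w)
  cum_w <- cumsum(w)
  draw_cand <- function() {
    i <- findInterval(stats::runif(1L) * W, cum_w) + 1L
    if (i > m) m else i
  }

  sets <- .initial_state(m, t, k, is_subtype)
  member_of <- integer(m)                     # 0 = outside the collection
  for (s in seq_len(t)) member_of[sets[[s]]] <- s
  lphi <- vapply(sets, function(ix) .memo_phi(memo, stats_memo, mat, margins, ix, phi_cfg), 0)
  sw <- vapply(sets, function(ix) sum(w[ix]), 0)   # per-set proposal weight

  cur_key <- .canonical_key(sets)
  best_lphi <- sum(lphi)
  best_sets <- sets
  retained <- 0L

  can_move <- m > k   # with t = 1 and k = m the single state has no neighbor
  step_once <- function() {
    slot <- sample.int(t * k, 1L)
    s <- (slot - 1L) %/% k + 1L
    pos <- (slot - 1L) %% k + 1L
    repeat {
      cand <- draw_cand()
      if (member_of[cand] != s) break
    }
    old_i <- sets[[s]][pos]
    s2 <- member_of[cand]
    new_s <- sort(c(sets[[s]][-pos], cand))
    ok <- .valid_set(new_s, is_subtype)
    if (ok && s2 > 0L) {
      new_s2 <- sort(c(sets[[s2]][sets[[s2]] != cand], old_i))
      ok <- .valid_set(new_s2, is_subtype)
    }
    if (!ok) return()
    lp_new_s <- .memo_phi(memo, stats_memo, mat, margins, new_s, phi_cfg)
    sw_s_new <- sw[s] - w[old_i] + w[cand]
    if (s2 > 0L) {
      lp_new_s2 <- .memo_phi(memo, stats_memo, mat, margins, new_s2, phi_cfg)
      sw_s2_new <- sw[s2] - w[cand] + w[old_i]
      # an exchange is reachable through either displaced slot, forward and
      # backward; sum both routes for the Hastings ratio
      q_fwd <- w[cand] / (W - sw[s]) + w[old_i] / (W - sw[s2])
      q_rev <- w[old_i] / (W - sw_s_new) + w[cand] / (W - sw_s2_new)
      log_ratio <- alpha * ((lphi[s] + lphi[s2]) - (lp_new_s + lp_new_s2)) +
        log(q_rev) - log(q_fwd)
    } else {
      q_fwd <- w[cand] / (W - sw[s])
      q_rev <- w[old_i] / (W - sw_s_new)
      log_ratio <- alpha * (lphi[s] - lp_new_s) + log(q_rev) - log(q_fwd)
    }
    if (log_ratio >= 0 || log(stats::runif(1L)) < log_ratio) {
      sets[[s]] <<- new_s
      member_of[old_i] <<- if (s2 > 0L) s2 else 0L
      member_of[cand] <<- s
      lphi[s] <<- lp_new_s
      sw[s] <<- sw_s_new
      if (s2 > 0L) {
        sets[[s2]] <<- new_s2
        lphi[s2] <<- lp_new_s2
        sw[s2] <<- sw_s2_new
      }
      cur_key <<- .canonical_key(sets)
      tot <- sum(lphi)
      if (tot < best_lphi) {
        best_lphi <<- tot
        best_sets <<- sets
      }
    }
  }
  for (it in seq_len(config$iterations)) {
    if (can_move) step_once()
    if (record && it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      retained <- retained + 1L
      rec <- counts_env[[cur_key]]
      if (is.null(rec)) {
        counts_env[[cur_key]] <- list(freq = 1L, log_phi = sum(lphi),
                                      sets = lapply(sets, function(ix)
                                        rownames(mat)[ix]))
      } else {
        rec$freq <- rec$freq + 1L
        counts_env[[cur_key]] <- rec
      }
    }
  }
  list(collections = as.list(counts_env), retained = retained,
       best_log_phi = best_lphi,
       best_sets = lapply(best_sets, function(ix) rownames(mat)[ix]))
}

#' Sample collections of exclusive alteration sets by MCMC
#'
#' Runs a Metropolis-Hastings chain over collections of t pairwise-disjoint
#' alteration sets of size k, with stationary distribution proportional to
#' phi(M)^-alpha, starting from a uniformly random valid collection. Per-set
#' scores are memoized across the run, so revisited sets cost a lookup.
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param config a \code{\link{sampler_config}}.
#' @param phi_cfg a \code{\link{phi_config}}.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class \code{posterior_sample}: list with
#'   \code{collections} (named by canonical key; each holds \code{sets},
#'   sampled \code{freq}, and \code{log_phi}), \code{retained} (number of
#'   recorded states), \code{best_sets} and \code{best_log_phi} (the
#'   lowest-scoring collection observed anywhere in the run).
#' @export
mcmc_sample <- function(A, config, phi_cfg = phi_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- .mcmc_run(A, config, phi_cfg, record = TRUE)
  structure(out, class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("posterior_sample: %d distinct collections over %s retained states; best log phi = %.3f\n",
              length(x$collections), format(x$retained, big.mark = ","),
              x$best_log_phi))
  invisible(x)
}

#' Margin-preserving permutation of an alteration matrix
#'
#' Produces a random binary matrix with exactly the same row sums (alteration
#' frequencies) and column sums (per-sample alteration counts) by repeated
#' 2x2 checkerboard swaps on the bipartite alteration-sample incidence
#' structure: two 1-entries (r1, c1), (r2, c2) with distinct rows and columns
#' and empty opposite corners are replaced by (r1, c2), (r2, c1).
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param swaps_per_edge attempted swaps per 1-entry; the standard mixing
#'   heuristic for bipartite double-edge swaps (default 100).
#' @param seed optional integer seed.
#' @return a permuted \code{alteration_matrix} with identical margins.
#' @export
permute_matrix <- function(A, swaps_per_edge = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- A$mat
  ones <- which(mat == 1L)
  E <- length(ones)
  if (E < 2L) return(A)
  er <- (ones - 1L) %% nrow(mat) + 1L
  ec <- (ones - 1L) %/% nrow(mat) + 1L
  attempts <- ceiling(swaps_per_edge * E)
  for (a in seq_len(attempts)) {
    i <- sample.int(E, 2L, replace = TRUE)   # equal picks are lazy no-ops
    if (i[1L] == i[2L]) next
    r1 <- er[i[1L]]; c1 <- ec[i[1L]]
    r2 <- er[i[2L]]; c2 <- ec[i[2L]]
    if (r1 == r2 || c1 == c2) next
    if (mat[r1, c2] != 0L || mat[r2, c1] != 0L) next
    mat[r1, c1] <- 0L; mat[r2, c2] <- 0L
    mat[r1, c2] <- 1L; mat[r2, c1] <- 1L
    ec[i[1L]] <- c2; ec[i[2L]] <- c1
  }
  alteration_matrix(mat, A$is_subtype)
}

#' Permutation-based significance threshold phi*
#'
#' Runs the same MCMC search on N margin-preserving permutations of the
#' alteration matrix, tracking only the minimum collection score found in
#' each, and returns phi* = the minimum over all permutations. Real-data
#' collections with phi(M) <= phi* are significant at P < 1/N, since not one
#' of N permuted datasets produced a score that low.
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param config a \code{\link{sampler_config}} (the permuted-data searches
#'   reuse its iteration budget).
#' @param phi_cfg a \code{\link{phi_config}}.
#' @param n_perm number of permuted matrices N (>= 1).
#' @param swaps_per_edge see \code{\link{permute_matrix}}.
#' @param seed optional integer seed.
#' @return an object of class \code{significance_result}: list with
#'   \code{phi_star}, \code{log_phi_star}, \code{n_perm}, \code{p_bound}.
#' @export
significance_threshold <- function(A, config, phi_cfg = phi_config(),
                                   n_perm = 100L, swaps_per_edge = 100,
                                   seed = NULL) {
  stopifnot(n_perm >= 1L)
  if (!is.null(seed)) set.seed(seed)
  mins <- vapply(seq_len(n_perm), function(i) {
    P <- permute_matrix(A, swaps_per_edge)
    .mcmc_run(P, config, phi_cfg, record = FALSE)$best_log_phi
  }, 0)
  structure(list(phi_star = exp(min(mins)), log_phi_star = min(mins),
                 n_perm = as.integer(n_perm), p_bound = 1 / n_perm),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("significance threshold phi* = %.6g over %d permutations (P < %.4g)\n",
              x$phi_star, x$n_perm, x$p_bound))
  invisible(x)
}

#' Keep only significant sampled collections
#'
#' Retains the sampled collections with phi(M) <= phi*, preserving their
#' sampling frequencies. Pass a \code{sig} with \code{phi_star = Inf} (or
#' \code{NULL}) to disable filtering.
#'
#' @param samples a \code{posterior_sample}.
#' @param sig a \code{significance_result}, or NULL to disable.
#' @return a filtered \code{posterior_sample}.
#' @export
filter_significant <- function(samples, sig) {
  if (is.null(sig) || is.infinite(sig$phi_star)) return(samples)
  keep <- vapply(samples$collections, function(cl)
    cl$log_phi <= sig$log_phi_star, TRUE)
  out <- samples
  out$collections <- samples$collections[keep]
  out$retained <- sum(vapply(out$collections, function(cl)
    as.numeric(cl$freq), 0))
  if (length(out$collections) == 0L)
    warning("no sampled collection reaches the significance threshold; ",
            "summarization will yield no modules")
  out
}
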