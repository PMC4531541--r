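# The statistical core: 2^k contingency tables with fixed margins, the
# exclusivity statistic T, the exact conditional (mid P) test computed by tail
# enumeration, and its binomial and permutation approximations.

.popcount <- function(x) {
  # number of set bits for small nonnegative integers (k <= 30)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Build the 2^k contingency table of an alteration set
#'
#' Cross-classifies the n samples by which subset of the k alterations in
#' \code{alterations} they carry. Cell \code{x_v} counts the samples whose
#' altered subset within the set is exactly v; cells are indexed by bitmask
#' (cell \code{i + 1} is the subset whose j-th alteration is present iff bit
#' j-1 of i is set; cell 1 is the no-alteration cell \code{x_0}). The margins
#' (per-alteration sample counts) are the sufficient statistics that the exact
#' test conditions on.
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param alterations character vector of k >= 2 distinct alteration names.
#' @return an object of class \code{contingency_table}: list with \code{k},
#'   \code{n}, \code{cells} (integer vector of length 2^k), \code{margins},
#'   and \code{alterations}.
#' @examples
#' m <- matrix(c(1,0, 0,1, 0,0, 1,1), 2, 4,
#'             dimnames = list(c("G1","G2"), paste0("s", 1:4)))
#' X <- contingency_table(alteration_matrix(m), c("G1", "G2"))
#' exclusivity_statistic(X)  # samples with exactly one alteration
#' @export
contingency_table <- function(A, alterations) {
  if (anyDuplicated(alterations)) stop("duplicate alteration names in set")
  if (length(alterations) < 2L)
    stop("an alteration set must contain at least two alterations")
  idx <- match(alterations, alteration_names(A))
  if (anyNA(idx))
    stop("unknown alteration name(s): ",
         paste(alterations[is.na(idx)], collapse = ", "))
  k <- length(idx)
  sub <- A$mat[idx, , drop = FALSE]
  code <- as.integer(2L^(seq_len(k) - 1L) %*% sub)    # bitmask per sample
  cells <- tabulate(code + 1L, nbins = 2L^k)
  new_contingency_table(cells, alterations = alterations)
}

#' Construct a contingency table directly from cell counts
#'
#' @param cells integer vector of length 2^k in bitmask order (first element
#'   is the no-alteration cell); n is their sum.
#' @param alterations optional alteration names (length k).
#' @return a \code{contingency_table}.
#' @export
new_contingency_table <- function(cells, alterations = NULL) {
  k <- as.integer(round(log2(length(cells))))
  if (2L^k != length(cells) || k < 2L)
    stop("'cells' must have length 2^k for some k >= 2")
  cells <- as.integer(cells)
  if (anyNA(cells) || any(cells < 0L)) stop("cell counts must be nonnegative")
  masks <- seq_len(2L^k) - 1L
  margins <- vapply(seq_len(k), function(j)
    sum(cells[bitwAnd(masks, 2L^(j - 1L)) > 0L]), 0L)
  if (is.null(alterations)) alterations <- paste0("a", seq_len(k))
  names(margins) <- alterations
  structure(list(k = k, n = sum(cells), cells = cells, margins = margins,
                 alterations = alterations),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2^%d contingency table on n=%d samples; margins (%s); T=%d\n",
              x$k, x$n, paste(x$margins, collapse = ", "),
              exclusivity_statistic(x)))
  invisible(x)
}

#' Exclusivity statistic T
#'
#' The number of samples carrying exactly one alteration of the set: the sum
#' of the singleton cells of the table. T is maximal (the sum of the margins)
#' for a perfectly exclusive set and satisfies the margin-sum identity
#' sum(margins) = T + sum over co-occurring cells of |v| * x_v.
#'
#' @param X a \code{contingency_table}.
#' @return integer in [0, n].
#' @export
exclusivity_statistic <- function(X) {
  sum(X$cells[.popcount(seq_along(X$cells) - 1L) == 1L])
}

#' Coverage of an alteration set
#'
#' The number of samples with at least one alteration in the set, n - x_0.
#' This is the statistic that coverage-based exclusivity methods test; for
#' k = 2 it carries the same information as T, but for k > 2 it does not.
#'
#' @param X a \code{contingency_table}.
#' @return integer in [0, n].
#' @export
coverage <- function(X) X$n - X$cells[1L]

#' Number of samples with co-occurring alterations
#'
#' @param X a \code{contingency_table}.
#' @return integer count of samples carrying two or more alterations of the set.
#' @export
cooccurrence_count <- function(X) {
  sum(X$cells[.popcount(seq_along(X$cells) - 1L) >= 2L])
}

# log p of a table given margins, via cached log-factorials.
# lfac is lfactorial(0:n) so lfac[x+1] = log(x!).
.log_table_prob <- function(cells, margins, n, lfac) {
  k <- length(margins)
  sum(lfac[margins + 1L] + lfac[n - margins + 1L]) -
    (k - 1) * lfac[n + 1L] - sum(lfac[cells + 1L])
}

#' Multivariate hypergeometric probability of a table
#'
#' The probability of observing the table X among all 2^k tables with the
#' same margins, under uniform and independent placement of each alteration's
#' support:
#' \deqn{p_X = \frac{\prod_j x^+_{(j)}! (n - x^+_{(j)})!}{(n!)^{k-1} \prod_v x_v!}}
#' Computed in log space throughout so that large n cannot overflow.
#'
#' @param X a \code{contingency_table}.
#' @param log if TRUE return the log probability.
#' @return probability in (0, 1] (or its log).
#' @export
table_probability <- function(X, log = FALSE) {
  lfac <- lfactorial(0:X$n)
  lp <- .log_table_prob(X$cells, X$margins, X$n, lfac)
  if (log) lp else exp(lp)
}

# Core tail enumeration over co-occurring cells; compiled (see
# src/tail_enum.cpp). Enumerates every table Y with the given margins and
# T(Y) >= t_obs by assigning counts to the co-occurring cells (|v| >= 2)
# under two bounds: the remaining exclusivity budget (total co-occurrence
# weight sum |v| y_v <= sum(margins) - t_obs) and the remaining margins.
# Once the co-occurring cells are fixed, the singleton cells and the empty
# cell are determined by the margins, so each feasible assignment
# contributes exactly one table.
.tail_enum <- function(margins, n, t_obs, epsilon = NULL) {
  k <- length(margins)
  stopifnot(k >= 2L, all(margins >= 0L), all(margins <= n))
  .tail_enum_cpp(as.integer(margins), as.integer(n), as.integer(t_obs),
                 if (is.null(epsilon)) -1 else epsilon)
}

#' Tail enumeration of more-exclusive tables
#'
#' Sums the hypergeometric probabilities of every table Y with the same
#' margins as X and exclusivity T(Y) >= T(X) (\code{p_ge}) and T(Y) > T(X)
#' (\code{p_gt}). A 2^k table has 2^k - k - 1 free co-occurring cells once
#' the margins are fixed; the algorithm iterates over assignments to exactly
#' those cells, bounded by the remaining co-occurrence budget and the
#' remaining margins, and completes each assignment to the unique full table.
#' If \code{epsilon} is given, enumeration stops as soon as the accumulated
#' \code{p_ge} exceeds it, returning \code{complete = FALSE}; large tail
#' probabilities are better served by the cheaper approximations.
#'
#' @param X a \code{contingency_table}.
#' @param epsilon optional early-stopping threshold in (0, 1).
#' @return list with \code{p_ge}, \code{p_gt}, \code{complete},
#'   \code{enumerated_tables}.
#' @export
tail_enumeration <- function(X, epsilon = NULL) {
  .tail_enum(X$margins, X$n, exclusivity_statistic(X), epsilon)
}

.new_exclusivity_result <- function(phi, t_obs, method, p_ge = NA_real_,
                                    p_gt = NA_real_, enumerated_tables = NA_integer_,
                                    log_phi = log(phi)) {
  structure(list(phi = phi, log_phi = log_phi, t_obs = t_obs, p_ge = p_ge,
                 p_gt = p_gt, method = method,
                 enumerated_tables = enumerated_tables),
            class = "exclusivity_result")
}

#' @export
print.exclusivity_result <- function(x, ...) {
  cat(sprintf("exclusivity phi = %.6g (T = %d, method = %s)\n",
              x$phi, x$t_obs, x$method))
  invisible(x)
}

#' Exact exclusivity score (mid P-value)
#'
#' The score of an alteration set is the mid P-value of the conditional exact
#' test: phi = (P(T >= T_obs) + P(T > T_obs)) / 2, with both tails computed by
#' complete tail enumeration. The mid P convention mitigates the
#' conservativeness of discrete exact tests. Exact mode is supported for
#' k <= 7; beyond that the 2^k cell count makes enumeration impractical and
#' \code{\link{phi}} falls back to the binomial approximation.
#'
#' @param X a \code{contingency_table}.
#' @return an \code{exclusivity_result} with \code{method = "exact"}.
#' @examples
#' # 16 and 6 alterations on 53 samples sharing exactly one sample
#' X <- new_contingency_table(c(32, 15, 5, 1))
#' exact_phi(X)$phi   # 0.253
#' @export
exact_phi <- function(X) {
  if (X$k > 7L)
    stop("exact test supported for k <= 7 only; use binomial_phi()")
  t_obs <- exclusivity_statistic(X)
  te <- tail_enumeration(X)
  phi <- (te$p_ge + te$p_gt) / 2
  .new_exclusivity_result(max(phi, .Machine$double.xmin), t_obs, "exact",
                          te$p_ge, te$p_gt, te$enumerated_tables)
}

#' Binomial approximation to the exclusivity score
#'
#' Approximates the null distribution of T by Binomial(n, p_e) where
#' p_e = sum_j x+_(j) / n (capped at 1) is the nominal per-sample probability
#' of an exclusive alteration; the score is the upper binomial tail
#' P(Binom(n, p_e) >= T_obs). The approximation is good for tables with many
#' co-occurrences (and hence large P-values) and conservative for strongly
#' exclusive tables with large margins.
#'
#' @param X a \code{contingency_table}.
#' @return an \code{exclusivity_result} with \code{method = "binomial"}.
#' @export
binomial_phi <- function(X) {
  t_obs <- exclusivity_statistic(X)
  p_e <- min(1, sum(X$margins) / X$n)
  lphi <- stats::pbinom(t_obs - 1L, X$n, p_e, lower.tail = FALSE, log.p = TRUE)
  .new_exclusivity_result(exp(lphi), t_obs, "binomial", log_phi = lphi)
}

# Draw the exclusivity statistic under the null: each alteration's support is
# a uniform subset of the samples (margins fixed, sample sums free). Only the
# per-sample alteration count matters for T, and counts can be capped at 2,
# so the k rows are added sequentially by multivariate hypergeometric draws
# over the three count categories (0, 1, >=2) -- vectorized across all L
# replicates.
.sample_T <- function(margins, n, L) {
  n0 <- rep.int(n, L)          # samples with no alteration so far
  n1 <- rep.int(0L, L)         # samples with exactly one
  for (mj in margins) {
    if (mj == 0L) next
    h0 <- stats::rhyper(L, n0, n - n0, mj)          # hits on count-0 samples
    h1 <- stats::rhyper(L, n1, n - n0 - n1, mj - h0) # hits on count-1 samples
    n0 <- n0 - h0
    n1 <- n1 - h1 + h0
  }
  n1
}

#' Permutation approximation to the exclusivity score
#'
#' Samples L tables with the observed margins uniformly -- each alteration's
#' support is an independent uniform subset of the samples, since only the
#' row margins are fixed under the null -- and estimates the mid P-value as
#' (#\{T >= T_obs\} + #\{T > T_obs\}) / (2L), floored at 1/(2L) so the score
#' is never zero (it enters products and powers downstream).
#'
#' @param X a \code{contingency_table}.
#' @param L number of sampled tables (>= 1).
#' @return an \code{exclusivity_result} with \code{method = "permutation"}.
#' @export
permutation_phi <- function(X, L = 1000L) {
  stopifnot(L >= 1L)
  t_obs <- exclusivity_statistic(X)
  Ts <- .sample_T(X$margins, X$n, L)
  est <- (sum(Ts >= t_obs) + sum(Ts > t_obs)) / (2 * L)
  .new_exclusivity_result(max(est, 1 / (2 * L)), t_obs, "permutation")
}

#' Configuration of the hybrid score dispatcher
#'
#' @param kappa co-occurrence-count threshold: tables with more than
#'   \code{kappa} samples carrying two or more alterations of the set are
#'   scored by the binomial approximation (their enumeration is the largest
#'   and the binomial is most accurate precisely there).
#' @param psi binomial P-value threshold in (0, 1): tables that the binomial
#'   itself already scores above \code{psi} are clearly non-exclusive and
#'   keep the binomial value. Because the binomial is conservative for
#'   exclusive tables with large margins, \code{psi} is deliberately high;
#'   small values would divert strongly exclusive sets to the binomial and
#'   flatten the score.
#' @param epsilon early-stopping threshold for tail enumeration in (0, 1);
#'   when enumeration is cut short the permutation approximation is used with
#'   L = ceiling(1/epsilon) samples, enough to expect at least one table more
#'   exclusive than observed. The default 0.01 reserves complete enumeration
#'   for scores below the usual significance range while keeping the
#'   dispatcher fast on unremarkable sets.
#' @return an object of class \code{phi_config}.
#' @export
phi_config <- function(kappa = 10L, psi = 0.9, epsilon = 0.01) {
  stopifnot(kappa >= 0, psi > 0, psi < 1, epsilon > 0, epsilon < 1)
  structure(list(kappa = as.integer(kappa), psi = psi, epsilon = epsilon),
            class = "phi_config")
}

#' Exclusivity score with hybrid exact/binomial/permutation dispatch
#'
#' Computes the binomial approximation and the co-occurrence count first. If
#' the count exceeds \code{config$kappa} or the binomial P-value exceeds
#' \code{config$psi}, the binomial value is returned. Otherwise the exact
#' tail enumeration runs with stopping threshold \code{config$epsilon}:
#' if it completes the exact mid P-value is returned, and if it stops early
#' the permutation approximation with L = ceiling(1/epsilon) samples is
#' returned. Two refinements keep the dispatch sound at the edges. First,
#' the psi branch additionally requires the observed T not to exceed the
#' conditional null mean E[T] = sum_j m_j prod_{i != j} (1 - m_i/n): the
#' binomial null centers T at n p_e = sum_j m_j, which overstates E[T] by
#' the expected co-occurrence mass, so for sets with large margins the
#' binomial tail can sit near 1 for tables the exact test finds extremely
#' exclusive -- precisely the sets the search must rank. A set at or below
#' E[T] shows no excess exclusivity, and there the binomial's
#' conservativeness has nothing to hide. Second, for k = 2 enumeration
#' always runs to completion (a 2x2 table admits at most n + 1 completions,
#' so the early stop buys nothing and exactness makes pair scores
#' deterministic). For k > 7 the binomial approximation is always used.
#'
#' @param X a \code{contingency_table}.
#' @param config a \code{\link{phi_config}}.
#' @return an \code{exclusivity_result}.
#' @export
phi <- function(X, config = phi_config()) {
  b <- binomial_phi(X)
  if (X$k > 7L) return(b)
  if (cooccurrence_count(X) > config$kappa ||
      (b$phi > config$psi &&
       b$t_obs <= .null_mean_T(X$margins, X$n))) return(b)
  te <- tail_enumeration(X, epsilon = if (X$k == 2L) NULL else config$epsilon)
  if (te$complete) {
    p <- (te$p_ge + te$p_gt) / 2
    .new_exclusivity_result(max(p, .Machine$double.xmin), b$t_obs, "exact",
                            te$p_ge, te$p_gt, te$enumerated_tables)
  } else {
    permutation_phi(X, L = ceiling(1 / config$epsilon))
  }
}

#' Score of a collection of alteration sets
#'
#' The score of a collection M = (M_1, ..., M_t) is the product of the
#' per-set scores, following the null assumption that exclusivity is
#' independent across sets. Accumulated in log space.
#'
#' @param tables list of \code{contingency_table}s (t >= 1).
#' @param config a \code{\link{phi_config}}.
#' @param log if TRUE return the log score.
#' @return probability in (0, 1] (or its log).
#' @export
phi_collection <- function(tables, config = phi_config(), log = FALSE) {
  stopifnot(length(tables) >= 1L)
  lp <- sum(vapply(tables, function(X) phi(X, config)$log_phi, 0))
  if (log) lp else exp(lp)
}

# conditional null mean of T with margins fixed: each sample carries
# alteration j alone with probability (m_j/n) prod_{i != j} (1 - m_i/n)
.null_mean_T <- function(margins, n) {
  p <- margins / n
  sum(vapply(seq_along(p), function(j) margins[j] * prod(1 - p[-j]), 0))
}

# fast path used by the MCMC sampler: score a set from its margins, observed
# T, and co-occurrence count, without materializing the 2^k table.
.phi_margins <- function(margins, n, t_obs, co_count, config) {
  p_e <- sum(margins) / n
  lb <- stats::pbinom(t_obs - 1L, n, min(1, p_e), lower.tail = FALSE,
                      log.p = TRUE)
  k <- length(margins)
  if (k > 7L || co_count > config$kappa ||
      (exp(lb) > config$psi && t_obs <= .null_mean_T(margins, n)))
    return(lb)
  te <- .tail_enum(margins, n, t_obs,
                   epsilon = if (k == 2L) NULL else config$epsilon)
  if (te$complete) {
    p <- max((te$p_ge + te$p_gt) / 2, .Machine$double.xmin)
    return(log(p))
  }
  L <- ceiling(1 / config$epsilon)
  Ts <- .sample_T(margins, n, L)
  est <- max((sum(Ts >= t_obs) + sum(Ts > t_obs)) / (2 * L), 1 / (2 * L))
  log(est)
}
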