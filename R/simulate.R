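# Synthetic-data generators for the implanted-pathway benchmarks, plus the
# evaluation metrics (F-measure, adjusted Rand index) and the combinatorial
# coverage-minus-overlap weight used as a baseline.

#' Simulation configuration
#'
#' Describes a simulated cohort with three kinds of genes: (1) one or more
#' implanted pathways, each a set of k genes altered with exclusive mutations
#' in a fraction gamma of the samples (every covered sample receives exactly
#' one pathway gene); (2) a set of highly altered confounder genes whose
#' alterations are frequent but not exclusive; (3) passenger genes altered
#' independently at a low background rate.
#'
#' @param n number of samples.
#' @param m total number of genes (pathway + confounder + passenger).
#' @param pathways list of implanted-pathway specs, each
#'   \code{list(k = , gamma = )} with per-pathway coverage gamma; requires
#'   \code{gamma * n >= k}.
#' @param n_confounders number of highly altered confounder genes (default 5).
#' @param confounder_rate per-sample alteration probability of a confounder
#'   gene (default 0.3, "highly altered").
#' @param passenger_rate per-gene-per-sample passenger alteration
#'   probability q (default 0.015, i.e. passengers altered in about 1.5\% of
#'   samples).
#' @param overlap if TRUE, consecutive pathways share exactly one gene,
#'   creating the cut-node topology of overlapping pathways.
#' @param equal_freq if TRUE, the genes within a pathway are mutated in
#'   (as near as possible) the same number of samples; otherwise the gene for
#'   each covered sample is chosen uniformly.
#' @param noise_on_pathway if TRUE, passenger noise is also added to pathway
#'   genes; by default implanted mutations stay perfectly exclusive.
#' @param min_freq optional frequency filter applied to the generated matrix
#'   (e.g. 0.01 for large gene backgrounds); NULL disables.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n = 500L, m = 100L,
                              pathways = list(list(k = 3L, gamma = 0.5)),
                              n_confounders = 5L, confounder_rate = 0.3,
                              passenger_rate = 0.015, overlap = FALSE,
                              equal_freq = FALSE, noise_on_pathway = FALSE,
                              min_freq = NULL) {
  stopifnot(n >= 1, length(pathways) >= 1,
            n_confounders >= 0, confounder_rate >= 0, confounder_rate <= 1,
            passenger_rate >= 0, passenger_rate <= 1)
  for (p in pathways) {
    stopifnot(p$k >= 2, p$gamma > 0, p$gamma <= 1)
    if (ceiling(p$gamma * n) < p$k)
      stop("pathway coverage gamma * n = ", ceiling(p$gamma * n),
           " is smaller than its size k = ", p$k)
  }
  n_pathway_genes <- sum(vapply(pathways, `[[`, 0, "k")) -
    if (overlap) length(pathways) - 1L else 0L
  if (m < n_pathway_genes + n_confounders)
    stop("m too small for the implanted pathways and confounders")
  structure(list(n = as.integer(n), m = as.integer(m), pathways = pathways,
                 n_confounders = as.integer(n_confounders),
                 confounder_rate = confounder_rate,
                 passenger_rate = passenger_rate, overlap = overlap,
                 equal_freq = equal_freq, noise_on_pathway = noise_on_pathway,
                 min_freq = min_freq),
            class = "simulation_config")
}

#' Single-implanted-pathway design
#'
#' The benchmark cohort for scoring individual gene sets: n = 500 samples,
#' one implanted pathway of k = 3 genes with coverage gamma, 5 highly altered
#' confounder genes, and passenger genes filling the background.
#'
#' @param gamma implanted-pathway coverage.
#' @param n,m,k cohort and pathway dimensions.
#' @return a \code{simulation_config}.
#' @export
sim_single_pathway <- function(gamma, n = 500L, m = 100L, k = 3L) {
  simulation_config(n = n, m = m, pathways = list(list(k = k, gamma = gamma)))
}

#' Implanted-collection design
#'
#' The benchmark cohort for identifying collections: t implanted pathways
#' with equal within-pathway gene frequencies, optionally overlapping
#' (consecutive pathways share one gene), on a large passenger background
#' from which genes mutated in fewer than 1\% of samples are removed.
#'
#' @param gammas per-pathway coverages (length t).
#' @param k pathway size, or vector of sizes; default 4, the middle of the
#'   published 3-5 range. With consecutive sharing, k = 3 would leave the
#'   middle pathway a single unshared gene -- a degenerate topology -- so
#'   k >= 4 keeps at least two own genes per pathway.
#' @param n,m cohort dimensions (the published design uses m = 20000).
#' @param overlap consecutive pathways share one gene.
#' @return a \code{simulation_config}.
#' @export
sim_collection_design <- function(gammas = c(0.75, 0.75, 0.60), k = 4L,
                                  n = 500L, m = 20000L, overlap = TRUE) {
  k <- rep_len(k, length(gammas))
  simulation_config(
    n = n, m = m,
    pathways = Map(function(kk, g) list(k = kk, gamma = g), k, gammas),
    overlap = overlap, equal_freq = TRUE, min_freq = 0.01)
}

#' Generate a simulated alteration matrix with ground truth
#'
#' For each implanted pathway, ceiling(gamma * n) distinct samples each
#' receive exactly one pathway-gene alteration (chosen uniformly, or
#' balanced across genes when \code{equal_freq}), so implanted mutations are
#' perfectly exclusive within their pathway. Confounder and passenger cells
#' are i.i.d. Bernoulli at their configured rates. Deterministic given
#' \code{seed}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param seed optional integer seed.
#' @return list with \code{matrix} (an \code{alteration_matrix}, filtered if
#'   \code{config$min_freq} is set) and \code{truth}: list with
#'   \code{implanted} (list of gene-name sets) and \code{partition} (named
#'   label vector over the returned genes; non-pathway genes are
#'   "background").
#' @export
simulate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  t <- length(config$pathways)
  ks <- vapply(config$pathways, `[[`, 0, "k")

  # gene name layout; with overlap, pathway i >= 2 reuses the last gene of
  # pathway i - 1 as its first member
  implanted <- vector("list", t)
  for (i in seq_len(t)) {
    fresh <- paste0("P", i, "_g", seq_len(ks[i]))
    if (config$overlap && i > 1L)
      implanted[[i]] <- c(implanted[[i - 1L]][ks[i - 1L]], fresh[-1L])
    else
      implanted[[i]] <- fresh
  }
  pathway_genes <- unique(unlist(implanted))
  confounders <- if (config$n_confounders > 0L)
    paste0("C", seq_len(config$n_confounders)) else character(0)
  n_passenger <- config$m - length(pathway_genes) - length(confounders)
  passengers <- if (n_passenger > 0L) paste0("G", seq_len(n_passenger))
    else character(0)
  genes <- c(pathway_genes, confounders, passengers)

  mat <- matrix(0L, length(genes), n,
                dimnames = list(genes, paste0("s", seq_len(n))))

  for (i in seq_len(t)) {
    cov <- ceiling(config$pathways[[i]]$gamma * n)
    covered <- sample.int(n, cov)
    assignee <- if (config$equal_freq) {
      # balanced split: gene frequencies differ by at most one
      sample(rep_len(implanted[[i]], cov))
    } else {
      sample(implanted[[i]], cov, replace = TRUE)
    }
    for (j in seq_len(cov)) mat[assignee[j], covered[j]] <- 1L
  }
  if (length(confounders))
    mat[confounders, ] <- mat[confounders, ] |
      matrix(stats::rbinom(length(confounders) * n, 1L,
                           config$confounder_rate),
             length(confounders), n)
  noise_rows <- if (config$noise_on_pathway) c(pathway_genes, passengers)
    else passengers
  if (length(noise_rows))
    mat[noise_rows, ] <- mat[noise_rows, ] |
      matrix(stats::rbinom(length(noise_rows) * n, 1L, config$passenger_rate),
             length(noise_rows), n)
  mode(mat) <- "integer"

  A <- alteration_matrix(mat)
  if (!is.null(config$min_freq)) A <- filter_alterations(A, config$min_freq)

  partition <- stats::setNames(rep("background", nrow(A$mat)),
                               alteration_names(A))
  for (i in rev(seq_len(t))) {  # shared genes labelled by the earlier pathway
    hit <- intersect(implanted[[i]], names(partition))
    partition[hit] <- paste0("P", i)
  }
  list(matrix = A,
       truth = list(implanted = implanted, partition = partition))
}

#' F-measure of a predicted gene set
#'
#' Harmonic mean of precision and recall over gene membership:
#' F = 2PR / (P + R), with F = 0 when the prediction is empty.
#'
#' @param predicted character vector of predicted genes (may be empty).
#' @param truth nonempty character vector of true genes.
#' @return value in [0, 1].
#' @export
f_measure <- function(predicted, truth) {
  stopifnot(length(truth) >= 1L)
  if (length(predicted) == 0L) return(0)
  tp <- length(intersect(predicted, truth))
  precision <- tp / length(predicted)
  recall <- tp / length(truth)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same elements,
#' from the pair-counting contingency table: ARI = 1 for identical
#' partitions, around 0 for independent ones, and negative for systematic
#' disagreement.
#'
#' @param labels_a,labels_b label vectors over the same elements (matched by
#'   names when both are named, else by position).
#' @return value in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    stopifnot(setequal(names(labels_a), names(labels_b)))
    labels_b <- labels_b[names(labels_a)]
  }
  stopifnot(length(labels_a) == length(labels_b))
  ct <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(ct))
  sum_a <- sum(ch2(rowSums(ct)))
  sum_b <- sum(ch2(colSums(ct)))
  n2 <- ch2(length(labels_a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)  # degenerate: both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' ARI between output modules and an implanted-pathway partition
#'
#' Labels every gene of the truth partition's universe by the module that
#' contains it (or "background") and returns the adjusted Rand index against
#' the truth labels. The chance adjustment makes the score well behaved over
#' the full gene universe: predicting nothing or only spurious modules
#' scores near 0, perfect recovery scores 1, and extra passenger genes
#' riding along in a module cost a bounded amount.
#'
#' @param modules list of character vectors (e.g. from
#'   \code{\link{extract_modules}}).
#' @param partition named label vector over all genes, pathway labels for
#'   implanted genes and "background" otherwise (as produced in
#'   \code{\link{simulate_dataset}}'s ground truth).
#' @return value in [-1, 1].
#' @export
module_ari <- function(modules, partition) {
  stopifnot(!is.null(names(partition)))
  pred <- stats::setNames(rep("background", length(partition)),
                          names(partition))
  for (i in seq_along(modules)) {
    hit <- intersect(modules[[i]], names(pred))
    pred[hit] <- paste0("S", i)
  }
  adjusted_rand_index(pred, partition)
}

#' Coverage-minus-overlap weight of an alteration set
#'
#' The combinatorial baseline score W(M) = coverage - coverage overlap: the
#' number of samples with at least one alteration in M minus the number with
#' more than one. Unlike the exclusivity score phi, W does not condition on
#' the alteration frequencies, so a set dominated by one frequent gene and a
#' set of equally frequent genes with the same total coverage get the same
#' weight.
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param M nonempty character vector of alteration names.
#' @return integer weight.
#' @export
dendrix_weight <- function(A, M) {
  stopifnot(length(M) >= 1L)
  idx <- match(M, alteration_names(A))
  if (anyNA(idx)) stop("unknown alteration name(s) in M")
  counts <- colSums(A$mat[idx, , drop = FALSE])
  sum(counts >= 1L) - sum(counts > 1L)
}
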