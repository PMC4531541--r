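# End-to-end orchestration: matrix -> MCMC -> significance filter ->
# marginal probability graph -> modules, with optional paired subtype run.

#' Run the full exclusivity pipeline
#'
#' Executes the complete workflow on an alteration matrix: MCMC sampling of
#' collections, the permutation significance threshold phi*, filtering of the
#' sampled collections, marginal-probability-graph construction, and
#' delta-thresholded module extraction. When a subtype map is supplied the
#' paired workflow runs automatically: one plain run and one run on the
#' matrix augmented with subtype rows, merged before summarization (disable
#' with \code{single_run = TRUE}, which then uses only the augmented matrix).
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param t,k collection shape: t sets of k alterations (defaults 4 and 4).
#' @param alpha sampling-weight exponent (default 2).
#' @param iterations MCMC iterations per run.
#' @param burn_in burn-in iterations; default 10\% of \code{iterations}.
#' @param n_perm number of margin-preserving permutations for the
#'   significance threshold; 0 disables significance filtering (all sampled
#'   collections are summarized, with a warning).
#' @param delta module threshold in [0, 1], or \code{"auto"} (default) for
#'   the largest-gap rule of \code{\link{auto_delta}}.
#' @param subtypes optional named character vector (sample -> subtype) as
#'   from \code{\link{read_subtype_map}}.
#' @param single_run if TRUE with subtypes, skip the plain run.
#' @param phi_cfg a \code{\link{phi_config}}.
#' @param swaps_per_edge permutation mixing parameter, see
#'   \code{\link{permute_matrix}}.
#' @param seed integer seed governing the whole pipeline (chain,
#'   permutations, and permutation-test draws); reruns with the same seed are
#'   identical.
#' @param out_dir optional directory; when given, writes posterior TSV,
#'   phi* report, graph exports (TSV/GraphML/JSON), and the module list.
#' @param min_freq optional alteration frequency filter applied first.
#' @param verbose print stage progress.
#' @return list with \code{posterior} (significant collections),
#'   \code{significance}, \code{graph}, \code{delta}, \code{modules} (a
#'   \code{module_set}), and \code{matrix} (the analyzed matrix).
#' @export
run_pipeline <- function(A, t = 4L, k = 4L, alpha = 2, iterations = 1e6,
                         burn_in = floor(iterations / 10), n_perm = 100L,
                         delta = "auto", subtypes = NULL, single_run = FALSE,
                         phi_cfg = phi_config(), swaps_per_edge = 100,
                         seed = NULL, out_dir = NULL, min_freq = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(min_freq)) A <- filter_alterations(A, min_freq)

  cfg <- sampler_config(t = t, k = k, alpha = alpha, iterations = iterations,
                        burn_in = burn_in)
  runs <- list()
  if (is.null(subtypes) || !single_run) {
    say("sampling collections (%d iterations)", cfg$iterations)
    runs$plain <- mcmc_sample(A, cfg, phi_cfg)
  }
  A_aug <- A
  if (!is.null(subtypes)) {
    A_aug <- add_subtype_rows(A, subtypes)
    say("sampling collections with subtype rows")
    runs$subtype <- mcmc_sample(A_aug, cfg, phi_cfg)
  }

  sig <- NULL
  if (n_perm >= 1L) {
    say("estimating significance threshold over %d permutations", n_perm)
    sig <- significance_threshold(A_aug, cfg, phi_cfg, n_perm = n_perm,
                                  swaps_per_edge = swaps_per_edge)
    runs <- lapply(runs, filter_significant, sig = sig)
  } else {
    warning("significance filtering disabled (n_perm = 0); ",
            "summarizing all sampled collections")
  }

  posterior <- if (length(runs) == 2L) merge_runs(runs[[1L]], runs[[2L]])
               else runs[[1L]]
  say("building marginal probability graph")
  G <- marginal_probabilities(posterior, is_subtype = A_aug$is_subtype)
  if (identical(delta, "auto"))
    delta <- if (nrow(G$edges)) auto_delta(G) else 1
  modules <- extract_modules(G, delta)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_posterior_tsv(posterior, file.path(out_dir, "posterior.tsv"))
    writeLines(c(sprintf("phi_star\t%s",
                         if (is.null(sig)) "NA" else
                           format(sig$phi_star, digits = 10)),
                 sprintf("n_perm\t%d", if (is.null(sig)) 0L else sig$n_perm),
                 sprintf("delta\t%.6g", delta),
                 sprintf("seed\t%s", if (is.null(seed)) "NA" else seed),
                 sprintf("package_version\t%s",
                         as.character(utils::packageVersion("mexsets")))),
               file.path(out_dir, "run_info.tsv"))
    write_graph_tsv(G, file.path(out_dir, "graph_edges.tsv"))
    if (nrow(G$edges))
      write_graph_graphml(G, file.path(out_dir, "graph.graphml"))
    write_result_json(G, modules, file.path(out_dir, "results.json"),
                      samples = posterior, A = A_aug)
    writeLines(vapply(modules$modules, paste, "", collapse = "\t"),
               file.path(out_dir, "modules.tsv"))
  }

  list(posterior = posterior, significance = sig, graph = G, delta = delta,
       modules = modules, matrix = A_aug)
}

# posterior dump: canonical key, phi, sampling frequency
.write_posterior_tsv <- function(samples, path) {
  keys <- names(samples$collections)
  df <- data.frame(
    collection = keys,
    sets = vapply(samples$collections, function(cl)
      paste(vapply(cl$sets, paste, "", collapse = ","), collapse = "|"), ""),
    phi = vapply(samples$collections, function(cl) exp(cl$log_phi), 0),
    frequency = vapply(samples$collections, function(cl) as.numeric(cl$freq), 0),
    stringsAsFactors = FALSE)
  df <- df[order(df$phi), , drop = FALSE]
  utils::write.table(df[, c("sets", "phi", "frequency")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recompute graph and modules from a posterior at a new delta
#'
#' @param samples a \code{posterior_sample}.
#' @param delta threshold or \code{"auto"}.
#' @param is_subtype optional subtype flags for the graph.
#' @return list with \code{graph}, \code{delta}, \code{modules}.
#' @export
summarize_posterior <- function(samples, delta = "auto", is_subtype = NULL) {
  G <- marginal_probabilities(samples, is_subtype = is_subtype)
  if (identical(delta, "auto"))
    delta <- if (nrow(G$edges)) auto_delta(G) else 1
  list(graph = G, delta = delta, modules = extract_modules(G, delta))
}
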