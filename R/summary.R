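# Summarization of the sampled posterior: marginal probability graph,
# delta-thresholded modules, merging of paired runs, and the co-occurrence
# test between gene-set pairs.

#' Marginal probability graph of a sampled posterior
#'
#' For each unordered pair of alterations (u, v), the edge weight p(u, v) is
#' the frequency-weighted fraction of (significant) sampled collections that
#' place u and v in the SAME set; co-membership in the same collection but
#' different sets contributes nothing. Edges lighter than 1e-6 are not
#' materialized (posterior noise).
#'
#' @param samples a \code{posterior_sample} (possibly filtered by
#'   \code{\link{filter_significant}} or merged by \code{\link{merge_runs}}).
#' @param is_subtype optional named logical vector marking subtype vertices,
#'   carried through to exports.
#' @return an object of class \code{marginal_probability_graph}: list with
#'   \code{edges} (data.frame u, v, weight), \code{vertices},
#'   \code{is_subtype}.
#' @export
marginal_probabilities <- function(samples, is_subtype = NULL) {
  acc <- new.env(parent = emptyenv())
  total <- 0
  for (cl in samples$collections) {
    f <- cl$freq
    total <- total + f
    for (set in cl$sets) {
      set <- sort(set)
      kk <- length(set)
      if (kk < 2L) next
      for (a in 1:(kk - 1L)) for (b in (a + 1L):kk) {
        key <- paste0(set[a], "\t", set[b])
        prev <- acc[[key]]
        acc[[key]] <- if (is.null(prev)) f else prev + f
      }
    }
  }
  keys <- ls(acc)
  if (total == 0 || length(keys) == 0L) {
    edges <- data.frame(u = character(0), v = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    w <- vapply(keys, function(kk) acc[[kk]], 0) / total
    uv <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    edges <- data.frame(u = uv[, 1L], v = uv[, 2L], weight = unname(w),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$weight >= 1e-6, , drop = FALSE]
    edges <- edges[order(-edges$weight, edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  }
  vertices <- sort(unique(c(edges$u, edges$v)))
  st <- stats::setNames(rep(FALSE, length(vertices)), vertices)
  if (!is.null(is_subtype)) {
    hit <- intersect(vertices, names(is_subtype)[is_subtype])
    st[hit] <- TRUE
  }
  structure(list(edges = edges, vertices = vertices, is_subtype = st),
            class = "marginal_probability_graph")
}

#' @export
print.marginal_probability_graph <- function(x, ...) {
  cat(sprintf("marginal probability graph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Extract modules by delta-thresholding
#'
#' Removes every edge with weight below \code{delta} and returns the
#' connected components of size >= 2 of what remains. Components -- rather
#' than cliques or another partition -- are deliberate: overlapping pathways
#' appear as two alteration sets joined by a cut vertex, and a component
#' keeps them in one module.
#'
#' @param G a \code{marginal_probability_graph}.
#' @param delta threshold in [0, 1], or \code{"auto"} for
#'   \code{\link{auto_delta}}.
#' @return an object of class \code{module_set}: list with \code{delta} and
#'   \code{modules} (list of character vectors, each of size >= 2).
#' @export
extract_modules <- function(G, delta) {
  if (identical(delta, "auto")) delta <- auto_delta(G)
  stopifnot(is.numeric(delta), delta >= 0, delta <= 1)
  e <- G$edges[G$edges$weight >= delta, , drop = FALSE]
  if (nrow(e) == 0L) {
    modules <- list()
  } else {
    g <- igraph::graph_from_data_frame(e[, c("u", "v")], directed = FALSE)
    comp <- igraph::components(g)
    modules <- split(names(comp$membership), comp$membership)
    modules <- lapply(unname(modules[comp$csize >= 2L]), sort)
    modules <- modules[order(vapply(modules, `[`, "", 1L))]
  }
  structure(list(delta = delta, modules = modules), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("%d module(s) at delta = %.4g\n", length(x$modules), x$delta))
  for (i in seq_along(x$modules))
    cat(sprintf("  [%d] %s\n", i, paste(x$modules[[i]], collapse = ", ")))
  invisible(x)
}

#' Data-driven module threshold
#'
#' Returns the midpoint of the largest gap in the sorted distinct edge
#' weights at or above a floor (default 0.05): high-confidence pairs separate
#' from posterior noise by a wide gap, and the midpoint splits the two
#' regimes. When all (above-floor) weights are equal the common weight itself
#' is returned, keeping every such edge. Deterministic.
#'
#' @param G a \code{marginal_probability_graph} with at least one edge.
#' @param floor weights below this are ignored when locating the gap.
#' @return a threshold in (0, 1].
#' @export
auto_delta <- function(G, floor = 0.05) {
  if (nrow(G$edges) == 0L) stop("cannot choose delta: graph has no edges")
  w <- sort(unique(G$edges$weight))
  w <- w[w >= floor]
  if (length(w) == 0L) return(floor)
  if (length(w) == 1L) return(w)
  gaps <- diff(w)
  i <- which.max(gaps)
  if (gaps[i] <= 0) return(w[1L])
  (w[i] + w[i + 1L]) / 2
}

#' Merge two sampling runs
#'
#' Normalizes each run's sampling frequencies to sum to one, then averages
#' them per canonical collection. Used for the paired with/without-subtype
#' workflow, where two runs over the same samples (but different alteration
#' universes) are summarized by one marginal probability graph. Commutative,
#' and invariant to rescaling either run's raw counts.
#'
#' @param samples_a,samples_b \code{posterior_sample} objects.
#' @return a merged \code{posterior_sample} whose frequencies sum to 1.
#' @export
merge_runs <- function(samples_a, samples_b) {
  ta <- sum(vapply(samples_a$collections, `[[`, 0, "freq"))
  tb <- sum(vapply(samples_b$collections, `[[`, 0, "freq"))
  if (ta == 0 && tb == 0) stop("cannot merge two empty runs")
  out <- new.env(parent = emptyenv())
  put <- function(samples, total, weight) {
    if (total == 0) return()
    for (key in names(samples$collections)) {
      cl <- samples$collections[[key]]
      f <- weight * cl$freq / total
      prev <- out[[key]]
      if (is.null(prev)) {
        cl$freq <- f
        out[[key]] <- cl
      } else {
        prev$freq <- prev$freq + f
        out[[key]] <- prev
      }
    }
  }
  # each nonempty run contributes equal mass
  n_runs <- (ta > 0) + (tb > 0)
  put(samples_a, ta, 1 / n_runs)
  put(samples_b, tb, 1 / n_runs)
  merged <- as.list(out)
  structure(list(collections = merged, retained = 1,
                 best_log_phi = min(samples_a$best_log_phi,
                                    samples_b$best_log_phi),
                 best_sets = if (samples_a$best_log_phi <=
                                 samples_b$best_log_phi) samples_a$best_sets
                             else samples_b$best_sets),
            class = "posterior_sample")
}

#' Co-occurrence test between two alteration sets
#'
#' Builds the 2x2 table of the per-sample indicators "any alteration in set1"
#' against "any alteration in set2" and returns the one-sided Fisher exact
#' upper tail, i.e. the P-value for enrichment of co-occurrence. Used to ask
#' whether two mutually exclusive sets are themselves altered together --
#' the signature of two pathways that a tumor must hit jointly.
#'
#' @param A an \code{\link{alteration_matrix}}.
#' @param set1,set2 disjoint, nonempty character vectors of alteration names.
#' @return P-value in (0, 1].
#' @export
cooccurrence_p <- function(A, set1, set2) {
  stopifnot(length(set1) >= 1L, length(set2) >= 1L)
  if (length(intersect(set1, set2)))
    stop("set1 and set2 must be disjoint")
  i1 <- colSums(A$mat[match(set1, alteration_names(A)), , drop = FALSE]) > 0L
  i2 <- colSums(A$mat[match(set2, alteration_names(A)), , drop = FALSE]) > 0L
  if (all(i1) || !any(i1) || all(i2) || !any(i2)) {
    warning("degenerate margins in co-occurrence test; returning P = 1")
    return(1)
  }
  tab <- table(factor(i1, c(TRUE, FALSE)), factor(i2, c(TRUE, FALSE)))
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Export a marginal probability graph as a TSV edge list
#' @param G a \code{marginal_probability_graph}.
#' @param path output path.
#' @export
write_graph_tsv <- function(G, path) {
  utils::write.table(G$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a marginal probability graph as GraphML
#' @param G a \code{marginal_probability_graph}.
#' @param path output path.
#' @export
write_graph_graphml <- function(G, path) {
  g <- igraph::graph_from_data_frame(
    G$edges, directed = FALSE,
    vertices = data.frame(name = G$vertices,
                          subtype = unname(G$is_subtype[G$vertices])))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export graph, modules, and best-collection annotations as JSON
#'
#' @param G a \code{marginal_probability_graph}.
#' @param modules a \code{module_set}.
#' @param samples the \code{posterior_sample} behind the graph (for the
#'   best-collection annotation), or NULL.
#' @param A optional \code{alteration_matrix} for per-set coverage
#'   annotations.
#' @param path output path.
#' @export
write_result_json <- function(G, modules, path, samples = NULL, A = NULL) {
  doc <- list(
    vertices = lapply(G$vertices, function(v)
      list(name = v, subtype = unname(G$is_subtype[v]))),
    edges = G$edges,
    delta = modules$delta,
    modules = modules$modules
  )
  if (!is.null(samples) && length(samples$best_sets)) {
    best <- lapply(samples$best_sets, function(set) {
      entry <- list(alterations = set)
      if (!is.null(A)) {
        X <- contingency_table(A, set)
        entry$phi <- phi(X)$phi
        entry$coverage <- coverage(X)
      }
      entry
    })
    doc$best_collection <- list(log_phi = samples$best_log_phi, sets = best)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
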