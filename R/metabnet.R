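# Metabolite-graph projection and degree-weighted k-shortest-path linkage.

#' Path-search parameters
#'
#' @param k_paths number of loopless shortest paths to average (default 5,
#'   which buffers single-path uncertainty in network-only inference).
#' @param quantile fraction of each pathway set admitted as "short"
#'   (default 0.05, nearest-rank).
#' @param mode `"weighted"` sums degree-sum edge weights along a path;
#'   `"hops"` counts edges.
#' @export
path_params <- function(k_paths = 5L, quantile = 0.05,
                        mode = c("weighted", "hops")) {
  if (k_paths < 1) stop_invalid("k_paths must be >= 1")
  if (quantile <= 0 || quantile > 1) stop_invalid("quantile must lie in (0, 1]")
  structure(list(k_paths = as.integer(k_paths), quantile = quantile,
                 mode = match.arg(mode)), class = "path_params")
}

#' Project a stoichiometric model onto a weighted metabolite graph
#'
#' Metabolites become nodes; every (substrate, product) pair of each
#' internal reaction becomes an undirected edge (conversion edges — never
#' substrate-substrate), regardless of reversibility. Exchange and biomass
#' reactions are excluded. Parallel edges from different reactions merge
#' into one simple edge whose `reactions` attribute keeps provenance. After
#' construction, each edge is weighted by the sum of the degrees of its two
#' endpoints (computed on the merged unweighted graph), which penalizes
#' routes through high-degree currency metabolites.
#'
#' @param model a validated [metabolic_model()].
#' @return An `igraph` undirected graph with edge attributes `weight`
#'   (degree sum, >= 2) and `reactions`.
#' @export
model_to_graph <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  internal <- setdiff(names(model$reactions),
                      c(model$biomass, unname(model$exchanges)))
  if (length(internal) == 0) {
    warning("model has no internal reactions; graph is empty")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  ends <- list()
  for (rid in internal) {
    st <- model$reactions[[rid]]$stoich
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    for (s in subs) for (p in prods) {
      if (s == p) next
      ends[[length(ends) + 1L]] <- c(sort(c(s, p)), rid)
    }
  }
  em <- do.call(rbind, ends)
  key <- paste(em[, 1], em[, 2])
  prov <- vapply(split(em[, 3], key), function(r)
    paste(sort(unique(r)), collapse = ","), "")
  uniq <- em[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = uniq[, 1], to = uniq[, 2],
               reactions = unname(prov[paste(uniq[, 1], uniq[, 2])]),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = unique(c(model$metabolites, uniq[, 1], uniq[, 2])))
  recompute_degree_weights(g)
}

#' Recompute degree-sum edge weights
#'
#' Edge weights are the sum of endpoint degrees on the unweighted merged
#' graph; call after any edge edit.
#'
#' @param graph an undirected `igraph` graph.
#' @return The graph with refreshed `weight` edge attribute.
#' @export
recompute_degree_weights <- function(graph) {
  deg <- igraph::degree(graph)
  el <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  igraph::E(graph)$weight <- deg[el[, 1]] + deg[el[, 2]]
  graph
}

path_weight <- function(graph, vpath, mode) {
  if (length(vpath) < 2) return(0)
  if (mode == "hops") return(length(vpath) - 1)
  eid <- igraph::get_edge_ids(graph, rep(vpath, each = 2)[-c(1, 2 * length(vpath))])
  sum(igraph::E(graph)$weight[eid])
}

#' Mean length of the k shortest loopless paths
#'
#' Yen-style generation of up to `k_paths` simple paths in nondecreasing
#' total weight (Dijkstra on the degree-weighted graph), averaged.
#' Averaging over several near-optimal routes buffers the uncertainty of
#' purely topological pathway inference. An unreachable target yields
#' `n_paths_found = 0` and an infinite sentinel; `source == target` yields
#' 0 with a flag.
#'
#' @param graph weighted metabolite graph from [model_to_graph()].
#' @param source,target metabolite ids.
#' @param params a [path_params()].
#' @return list of class `path_result`: `source`, `target`, `mean_length`,
#'   `path_lengths`, `n_paths_found`, `same_node`.
#' @export
k_shortest_mean <- function(graph, source, target, params = path_params()) {
  vn <- igraph::V(graph)$name
  if (!source %in% vn || !target %in% vn)
    stop("source and target must be graph nodes")
  if (source == target)
    return(structure(list(source = source, target = target, mean_length = 0,
                          path_lengths = numeric(0), n_paths_found = 0L,
                          same_node = TRUE), class = "path_result"))
  w <- igraph::E(graph)$weight
  ks <- suppressWarnings(igraph::k_shortest_paths(
    graph, from = source, to = target, k = params$k_paths, weights = w))
  lens <- vapply(ks$vpaths, function(vp)
    path_weight(graph, as.integer(vp), params$mode), numeric(1))
  structure(list(source = source, target = target,
                 mean_length = if (length(lens)) mean(lens) else Inf,
                 path_lengths = lens, n_paths_found = length(lens),
                 same_node = FALSE), class = "path_result")
}

#' Pathway set from one source to every other metabolite
#'
#' @inheritParams k_shortest_mean
#' @return data.frame: `source`, `target`, `mean_length`, `n_paths_found`
#'   (one row per other node; unreachable nodes carry the infinite
#'   sentinel).
#' @export
pathway_set <- function(graph, source, params = path_params()) {
  targets <- setdiff(igraph::V(graph)$name, source)
  rows <- lapply(targets, function(tg) {
    pr <- k_shortest_mean(graph, source, tg, params)
    data.frame(source = source, target = tg, mean_length = pr$mean_length,
               n_paths_found = pr$n_paths_found, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Link screen compounds to metabolome compounds via short pathways
#'
#' For each source (an in vitro screen compound) the nearest-rank
#' `quantile` of the finite mean path lengths in its full pathway set
#' defines a "short" threshold; (source, target) pairs whose target is a
#' metabolome compound and whose mean length is at or below the threshold
#' are returned, ranked by mean length. Ties at the threshold are all
#' admitted; unreachable targets never pass. Compound-to-metabolite id
#' mapping is supplied explicitly; unmapped compounds are skipped with a
#' warning.
#'
#' @param pathway_sets named list (by source metabolite id) of
#'   [pathway_set()] data.frames.
#' @param screen_compounds compound ids from the phenotype screen (sources).
#' @param metabolome_compounds compound ids from the metabolome (targets).
#' @param params a [path_params()].
#' @param mapping optional data.frame `compound`, `metabolite`; by default
#'   compound ids are used as metabolite ids directly.
#' @return data.frame: `source_compound`, `target_compound`, `source`,
#'   `target`, `mean_length`, `threshold`, sorted by `mean_length`.
#' @export
select_cross_pairs <- function(pathway_sets, screen_compounds,
                               metabolome_compounds, params = path_params(),
                               mapping = NULL) {
  map <- function(ids) {
    if (is.null(mapping)) return(stats::setNames(ids, ids))
    mt <- stats::setNames(mapping$metabolite, mapping$compound)[ids]
    if (any(is.na(mt)))
      warning("unmapped compound(s) skipped: ",
              paste(ids[is.na(mt)], collapse = ", "))
    mt[!is.na(mt)]
  }
  src_map <- map(screen_compounds)
  tgt_map <- map(metabolome_compounds)
  out <- list()
  for (i in seq_along(src_map)) {
    s_met <- src_map[[i]]
    ps <- pathway_sets[[s_met]]
    if (is.null(ps)) {
      warning("no pathway set for source ", s_met, "; skipped")
      next
    }
    finite <- sort(ps$mean_length[is.finite(ps$mean_length)])
    if (length(finite) == 0) next
    thr <- finite[ceiling(params$quantile * length(finite))]
    hits <- ps[ps$target %in% tgt_map & is.finite(ps$mean_length) &
                 ps$mean_length <= thr, , drop = FALSE]
    if (nrow(hits) == 0) next
    hits$threshold <- thr
    hits$source_compound <- names(src_map)[i]
    hits$target_compound <- names(tgt_map)[match(hits$target, tgt_map)]
    out[[length(out) + 1L]] <- hits
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(source_compound = character(),
                      target_compound = character(), source = character(),
                      target = character(), mean_length = numeric(),
                      threshold = numeric()))
  res <- res[order(res$mean_length, res$source, res$target), ]
  rownames(res) <- NULL
  res[, c("source_compound", "target_compound", "source", "target",
          "mean_length", "threshold")]
}
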