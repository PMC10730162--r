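# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exhaustive simple-path enumeration between two nodes of a small weighted
# undirected graph given as an edge data.frame (from, to, weight).
# Returns all simple-path total weights, sorted.
enumerate_path_weights <- function(edges, source, target) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    i <- which(edges$from == v | edges$to == v)
    data.frame(nb = ifelse(edges$from[i] == v, edges$to[i], edges$from[i]),
               w = edges$weight[i], stringsAsFactors = FALSE)
  })
  out <- numeric(0)
  walk <- function(v, visited, acc) {
    if (v == target) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    a <- adj[[v]]
    for (i in seq_len(nrow(a))) {
      nb <- a$nb[i]
      if (!nb %in% visited) walk(nb, c(visited, nb), acc + a$w[i])
    }
  }
  if (!source %in% nodes || !target %in% nodes) return(numeric(0))
  walk(source, source, 0)
  sort(out)
}

# Random connected undirected graph with <= n_max nodes and random positive
# integer edge weights; returned as an edge data.frame.
random_connected_graph <- function(seed, n_max = 8) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  nodes <- paste0("m", seq_len(n))
  # spanning tree guarantees connectivity
  edges <- data.frame(from = nodes[1], to = nodes[2],
                      stringsAsFactors = FALSE)[0, ]
  for (i in 2:n) {
    edges <- rbind(edges, data.frame(from = nodes[sample(i - 1, 1)],
                                     to = nodes[i], stringsAsFactors = FALSE))
  }
  extra <- utils::combn(nodes, 2)
  pick <- sample(ncol(extra), min(ncol(extra), sample(0:6, 1)))
  for (j in pick) {
    e <- extra[, j]
    dup <- any((edges$from == e[1] & edges$to == e[2]) |
                 (edges$from == e[2] & edges$to == e[1]))
    if (!dup) edges <- rbind(edges, data.frame(from = e[1], to = e[2],
                                               stringsAsFactors = FALSE))
  }
  edges$weight <- sample(1:9, nrow(edges), replace = TRUE)
  edges
}

graph_from_edges <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- edges$weight
  g
}

# Brute-force parallel-locus detection: double loop over locus x mouse-pair.
brute_force_parallel <- function(calls, cohort) {
  inoc <- stats::setNames(cohort$inoculum_id, cohort$mouse_id)
  loci <- sort(unique(calls$locus_id))
  vapply(stats::setNames(loci, loci), function(l) {
    mice <- unique(calls$mouse_id[calls$locus_id == l])
    if (length(mice) < 2) return(FALSE)
    for (i in seq_along(mice)) for (j in seq_along(mice)) {
      if (i < j && inoc[[mice[i]]] != inoc[[mice[j]]]) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# Independent LP oracle: runs the producibility screen with
# scipy.optimize.linprog through the system python. Returns a data.frame
# (source, target, oxygen, max_flux, producible) or NULL when python/scipy
# is unavailable.
lp_oracle_screen <- function(model, cfg, sources, targets) {
  tmp_model <- tempfile(fileext = ".json")
  tmp_cfg <- tempfile(fileext = ".json")
  tmp_out <- tempfile(fileext = ".json")
  evogut::write_model_json(model, tmp_model)
  jsonlite::write_json(
    list(sources = as.list(sources), targets = as.list(targets),
         medium = as.list(cfg$medium), remove_glucose = cfg$remove_glucose,
         glucose_id = cfg$glucose_id, oxygen_id = cfg$oxygen_id,
         oxygen_levels = as.list(cfg$oxygen_levels),
         source_uptake = cfg$source_uptake,
         growth_fraction = cfg$growth_fraction,
         epsilon = cfg$producibility_epsilon),
    tmp_cfg, auto_unbox = TRUE, digits = NA)
  script <- testthat::test_path("lp-oracle.py")
  status <- suppressWarnings(
    system2("python", c(script, tmp_model, tmp_cfg, tmp_out),
            stdout = TRUE, stderr = TRUE))
  if (!file.exists(tmp_out)) {
    stop("LP oracle failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::fromJSON(tmp_out)
}

# Exchangeable nonnegative abundance matrix (lognormal) for null simulations.
with_seed_matrix <- function(seed, n, p) {
  set.seed(seed)
  matrix(exp(rnorm(n * p)), n, p)
}

# Default-config synthetic de-novo pipeline shared by several tests.
sweep_pipeline <- function(cfg = evogut::sim_config(seed = 1)) {
  cohort <- evogut::generate_cohort(cfg)
  mut <- evogut::generate_mutation_tables(cfg, cohort)
  denovo <- evogut::de_novo_calls(mut$calls, mut$inoculum_calls, cohort)
  list(cfg = cfg, cohort = cohort, mut = mut, denovo = denovo)
}
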