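#' Replicate-supported infection network
#'
#' Builds the bipartite vOTU-host infection network from collapsed infection
#' pairs, keeping only pairs detected in at least `min_support` replicate
#' samples; the edge weight is the number of supporting replicates.
#'
#' @param pairs Output of [collapse_to_pairs()].
#' @param min_support Minimum replicate support (default 2).
#' @param taxonomy Optional tibble `(node, taxonomy)` used to label nodes.
#' @return A list of class `infection_network` with `nodes` (tibble `node`,
#'   `type`, `taxonomy`) and `edges` (tibble `votu_id`, `population_id`,
#'   `condition`, `support_count`).
#' @export
build_infection_network <- function(pairs, min_support = 2,
                                    taxonomy = NULL) {
  edges <- as_tibble(pairs) |>
    filter(.data$support_count >= min_support) |>
    select("votu_id", "population_id", "condition", "support_count")
  nodes <- bind_rows(
    tibble(node = unique(edges$votu_id), type = "votu"),
    tibble(node = unique(edges$population_id), type = "host")
  )
  nodes$taxonomy <- NA_character_
  if (!is.null(taxonomy)) {
    nodes <- nodes |>
      select(-"taxonomy") |>
      left_join(as_tibble(taxonomy), by = "node")
  }
  structure(list(nodes = nodes, edges = edges, directed = FALSE,
                 method = "hic_infection", params = list(min_support = min_support)),
            class = "infection_network")
}

#' @export
print.infection_network <- function(x, ...) {
  cat(sprintf("<infection_network> %d nodes (%d vOTUs, %d hosts), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "votu"),
              sum(x$nodes$type == "host"), nrow(x$edges)))
  invisible(x)
}

cooc_network <- function(method, nodes, edges, directed, params) {
  structure(list(method = method, nodes = tibble(node = nodes),
                 edges = edges, directed = directed, params = params),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> method = %s (%s); %d nodes, %d edges\n",
              x$method, if (x$directed) "directed" else "undirected",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

check_abund_matrix <- function(abund, min_samples = 3) {
  abund <- as.matrix(abund)
  if (is.null(colnames(abund))) {
    colnames(abund) <- paste0("n", seq_len(ncol(abund)))
  }
  if (nrow(abund) < min_samples) {
    abort(sprintf("At least %d samples (rows) are required.", min_samples))
  }
  abund[, order(colnames(abund)), drop = FALSE]
}

drop_constant_nodes <- function(abund) {
  v <- apply(abund, 2, stats::var)
  if (any(v == 0)) {
    warn(paste0("Excluding zero-variance node(s): ",
                paste(head(colnames(abund)[v == 0], 5), collapse = ", "), "."))
    abund <- abund[, v > 0, drop = FALSE]
  }
  abund
}

#' Pearson correlation co-occurrence network
#'
#' Undirected edges between proxy-gene nodes whose abundance profiles have
#' `|Pearson r|` strictly greater than `cutoff`. Zero-variance nodes are
#' excluded with a warning (never NaN edges).
#'
#' @param abund Samples x nodes numeric matrix (or data frame) of
#'   relative abundances.
#' @param cutoff Absolute correlation threshold (default 0.8, strict).
#' @return A `cooccurrence_network` with edge weights equal to r.
#' @export
pearson_network <- function(abund, cutoff = 0.8) {
  abund <- drop_constant_nodes(check_abund_matrix(abund))
  r <- cor(abund)
  idx <- which(upper.tri(r) & abs(r) > cutoff, arr.ind = TRUE)
  edges <- tibble(
    from = colnames(r)[idx[, 1]], to = colnames(r)[idx[, 2]],
    weight = r[idx]
  )
  cooc_network("pearson", colnames(abund), edges, directed = FALSE,
               params = list(cutoff = cutoff, n_edges = nrow(edges)))
}

# Mutual information between two vectors via equal-frequency binning.
binned_mi <- function(x, y, bins) {
  qcut <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(rep(1L, length(v)))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  jx <- qcut(x)
  jy <- qcut(y)
  tab <- table(jx, jy) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  ex <- outer(px, py)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / ex[nz]))
}

#' CLR (context likelihood of relatedness) co-occurrence network
#'
#' Estimates a mutual-information matrix between nodes (equal-frequency
#' binning with `ceiling(sqrt(n_samples))` bins by default), applies the CLR
#' transform `z_ij = sqrt(max(0, z_i(j))^2 + max(0, z_j(i))^2)` where
#' `z_i(j)` is the z-score of `MI(i, j)` within row i, and keeps the
#' `top_edges` highest-scoring unordered pairs. Score ties at the boundary
#' are all kept; with `top_edges = NULL` the 95th-percentile rule
#' (`ceiling(0.05 * n_pairs)` edges) is used instead. The selection rule
#' actually applied is recorded in `params`.
#'
#' @param abund Samples x nodes matrix; at least 3 samples and 3 nodes.
#' @param top_edges Number of edges to keep (default 200).
#' @param bins Bin count for the MI estimator (default
#'   `ceiling(sqrt(n_samples))`).
#' @return A `cooccurrence_network` with CLR scores as edge weights; the full
#'   symmetric score matrix is attached as the `"scores"` attribute.
#' @export
clr_network <- function(abund, top_edges = 200, bins = NULL) {
  abund <- drop_constant_nodes(check_abund_matrix(abund))
  p <- ncol(abund)
  if (p < 3) abort("At least 3 non-constant nodes are required for CLR.")
  bins <- bins %||% ceiling(sqrt(nrow(abund)))

  mi <- matrix(0, p, p, dimnames = list(colnames(abund), colnames(abund)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      mi[i, j] <- mi[j, i] <- binned_mi(abund[, i], abund[, j], bins)
    }
  }
  z <- matrix(0, p, p, dimnames = dimnames(mi))
  for (i in seq_len(p)) {
    row <- mi[i, -i]
    mu <- mean(row)
    s <- sd(row)
    z[i, -i] <- if (is.na(s) || s == 0) 0 else (row - mu) / s
  }
  clr <- sqrt(pmax(z, 0)^2 + pmax(t(z), 0)^2)

  idx <- which(upper.tri(clr), arr.ind = TRUE)
  all_edges <- tibble(
    from = colnames(clr)[idx[, 1]], to = colnames(clr)[idx[, 2]],
    weight = clr[idx]
  ) |>
    arrange(desc(.data$weight), .data$from, .data$to)
  n_pairs <- nrow(all_edges)
  rule <- if (is.null(top_edges)) "percentile_95" else "top_k"
  k <- as.integer(if (is.null(top_edges)) ceiling(0.05 * n_pairs) else
    min(top_edges, n_pairs))
  boundary <- all_edges$weight[k]
  edges <- all_edges |> filter(.data$weight >= boundary) # keep boundary ties
  out <- cooc_network("clr", colnames(abund), edges, directed = FALSE,
                      params = list(rule = rule, requested = k, bins = bins,
                                    cutoff_score = boundary,
                                    n_edges = nrow(edges)))
  attr(out, "scores") <- clr
  out
}

#' Random-forest importance (GENIE3-style) co-occurrence network
#'
#' For each target node, fits a seeded random-forest regression of its
#' abundance on all other nodes and records the variable importances as
#' directed edge weights into the target. The top `top_fraction` of all
#' directed edges by importance are retained (boundary ties kept), mirroring
#' the percentile logic of the undirected methods. Constant targets are
#' skipped with a warning.
#'
#' @param abund Samples x nodes matrix; 5 or more samples recommended.
#' @param top_fraction Fraction of directed edges kept (default 0.05).
#' @param seed Mandatory integer seed; results are invariant to sample order
#'   given a fixed seed and the internal (sorted) feature order.
#' @param num_trees Trees per forest (default 200).
#' @return A directed `cooccurrence_network` with importances as weights.
#' @export
rf_importance_network <- function(abund, top_fraction = 0.05, seed,
                                  num_trees = 200) {
  if (missing(seed)) abort("A `seed` is mandatory for the forest ensemble.")
  abund <- check_abund_matrix(abund)
  # canonical row order (content sort) so results do not depend on how the
  # caller happened to order the samples
  abund <- abund[do.call(order, as.data.frame(abund)), , drop = FALSE]
  v <- apply(abund, 2, stats::var)
  if (any(v == 0)) {
    warn(paste0("Skipping constant target node(s): ",
                paste(head(colnames(abund)[v == 0], 5), collapse = ", "), "."))
  }
  nodes <- colnames(abund)
  targets <- nodes[v > 0]
  if (length(nodes) < 2) abort("At least two nodes are required.")

  all_edges <- purrr::map_dfr(seq_along(targets), function(k) {
    tgt <- targets[k]
    df <- as.data.frame(abund)
    names(df) <- make.names(names(df))
    safe_tgt <- make.names(tgt)
    fit <- ranger::ranger(
      dependent.variable.name = safe_tgt, data = df,
      num.trees = num_trees, importance = "impurity",
      seed = seed + k, num.threads = 1,
      mtry = max(1, floor(sqrt(ncol(df) - 1)))
    )
    imp <- fit$variable.importance
    tibble(from = nodes[match(names(imp), make.names(nodes))],
           to = tgt, weight = unname(imp))
  })
  all_edges <- all_edges |>
    arrange(desc(.data$weight), .data$from, .data$to)
  k <- max(1, ceiling(top_fraction * nrow(all_edges)))
  boundary <- all_edges$weight[k]
  edges <- all_edges |> filter(.data$weight >= boundary)
  cooc_network("rf_importance", nodes, edges, directed = TRUE,
               params = list(top_fraction = top_fraction, requested = k,
                             seed = seed, num_trees = num_trees,
                             cutoff_score = boundary, n_edges = nrow(edges)))
}

#' Node centrality of a network
#'
#' Betweenness via unweighted shortest paths (directed paths for directed
#' networks; unnormalized pair counts) and degree (total in+out degree for
#' directed networks), with 1-based competition ranks (descending; ties share
#' the smaller rank).
#'
#' @param net A `cooccurrence_network`, `infection_network`, or igraph object.
#' @return A tibble `(node, betweenness, degree, rank_betweenness,
#'   rank_degree)`.
#' @export
centrality <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) abort("Network is empty.")
  bet <- igraph::betweenness(g, directed = igraph::is_directed(g),
                             weights = NA)
  deg <- igraph::degree(g, mode = "total")
  tibble(node = names(bet), betweenness = unname(bet),
         degree = as.integer(unname(deg))) |>
    mutate(rank_betweenness = min_rank(desc(.data$betweenness)),
           rank_degree = min_rank(desc(.data$degree)))
}

#' Convert a network object to igraph
#'
#' @param net A `cooccurrence_network` or `infection_network` (igraph objects
#'   pass through).
#' @return An igraph graph with a `weight` edge attribute where available.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  if (inherits(net, "infection_network")) {
    edges <- net$edges |>
      select(from = "votu_id", to = "population_id",
             weight = "support_count")
    return(igraph::graph_from_data_frame(
      edges, directed = FALSE, vertices = net$nodes$node
    ))
  }
  if (inherits(net, "cooccurrence_network")) {
    return(igraph::graph_from_data_frame(
      net$edges, directed = net$directed, vertices = net$nodes$node
    ))
  }
  abort("Cannot convert this object to igraph.")
}

#' Cross-reference phage hosts with network centrality
#'
#' Annotates a centrality table with which nodes are phage hosts and reports
#' the top-`top_n` nodes by betweenness and by degree with host highlighting.
#' Node ids are mapped to host populations via `node_to_host` when proxy
#' nodes do not equal population ids (e.g. duplicated argS proxies); ids
#' that cannot be mapped are listed in the report, never dropped silently.
#'
#' @param cent Centrality table from [centrality()].
#' @param hosts Character vector of phage-host population ids.
#' @param node_to_host Optional tibble `(node, population_id)`.
#' @param top_n Size of the highlight lists (default 5).
#' @return A list of class `host_centrality_report` with `table` (annotated
#'   centrality tibble), `top_betweenness`, `top_degree`, `unmapped`.
#' @export
cross_reference_hosts <- function(cent, hosts, node_to_host = NULL,
                                  top_n = 5) {
  cent <- as_tibble(cent)
  if (is.null(node_to_host)) {
    node_to_host <- tibble(node = cent$node, population_id = cent$node)
  }
  annotated <- cent |>
    left_join(as_tibble(node_to_host), by = "node") |>
    mutate(is_host = !is.na(.data$population_id) &
             .data$population_id %in% hosts)
  unmapped <- annotated$node[is.na(annotated$population_id)]
  out <- list(
    table = annotated,
    top_betweenness = annotated |>
      filter(.data$rank_betweenness <= top_n) |>
      arrange(.data$rank_betweenness),
    top_degree = annotated |>
      filter(.data$rank_degree <= top_n) |>
      arrange(.data$rank_degree),
    unmapped = unmapped
  )
  class(out) <- "host_centrality_report"
  out
}

#' @export
print.host_centrality_report <- function(x, ...) {
  cat("<host_centrality_report>\n")
  cat(sprintf("  %d of %d central nodes are phage hosts; top by betweenness:\n",
              sum(x$table$is_host), nrow(x$table)))
  print(x$top_betweenness, n = 5)
  if (length(x$unmapped)) {
    cat("  unmapped node(s):", paste(head(x$unmapped, 5), collapse = ", "),
        "\n")
  }
  invisible(x)
}
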