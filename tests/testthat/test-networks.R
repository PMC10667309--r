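fake_pairs <- function(df) {
  df$replicate_support <- lapply(df$support_count, seq_len)
  df
}

test_that("infection network keeps replicate-supported pairs with weights", {
  pairs <- fake_pairs(tibble::tibble(
    votu_id = c("V1", "V1", "V2"),
    population_id = c("B1", "B2", "B3"),
    condition = c("pre", "pre", "post"),
    support_count = c(2L, 3L, 1L),
    host_range_class = c("multiple_hosts", "multiple_hosts", "one_host")
  ))
  net <- build_infection_network(pairs)
  expect_identical(nrow(net$edges), 2L) # the support-1 pair is excluded
  expect_setequal(net$edges$support_count, c(2L, 3L))
  # V1 with two supported hosts has degree 2 in the graph
  g <- as_igraph(net)
  expect_identical(unname(igraph::degree(g)["V1"]), 2)
  expect_true(all(c("votu", "host") %in% net$nodes$type))
})

test_that("Pearson network applies the strict absolute-correlation cutoff", {
  x <- c(1, 2, 3, 4)
  m <- cbind(a = x, b = x, c = -x, d = c(4, 1, 3, 2))
  net <- pearson_network(m, cutoff = 0.8)
  key <- paste(net$edges$from, net$edges$to)
  expect_true("a b" %in% key)  # r = 1
  expect_true("a c" %in% key)  # r = -1, absolute value
  expect_true("b c" %in% key)
  expect_false(any(grepl("d", key))) # shuffled column is uncorrelated

  # a pair just below the cutoff gets no edge
  y <- c(1, 2, 3, 4.9)
  z <- c(1.15, 1.9, 3.6, 4)
  stopifnot(cor(y, z) < 0.96, cor(y, z) > 0.90)
  m2 <- cbind(p = y, q = z, r = c(9, 1, 5, 2))
  net2 <- pearson_network(m2, cutoff = 0.96)
  expect_identical(nrow(net2$edges), 0L)

  # zero-variance nodes are excluded with a warning, never NaN edges
  m3 <- cbind(a = x, b = x, const = rep(2, 4))
  expect_warning(net3 <- pearson_network(m3), "zero-variance")
  expect_false("const" %in% net3$nodes$node)
  expect_false(any(is.na(net3$edges$weight)))
})

test_that("Pearson edges are invariant to column permutation", {
  withr::local_seed(14)
  m <- matrix(rnorm(60), nrow = 6,
              dimnames = list(NULL, paste0("n", 1:10)))
  m[, 2] <- m[, 1] + rnorm(6, sd = 0.05)
  a <- pearson_network(m, cutoff = 0.8)
  b <- pearson_network(m[, sample(10)], cutoff = 0.8)
  canon <- function(net) {
    e <- net$edges
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    sort(key)
  }
  expect_identical(canon(a), canon(b))
})

test_that("CLR scores peak for a copied node pair and top-k honours ties", {
  withr::local_seed(15)
  m <- matrix(rnorm(200), nrow = 20,
              dimnames = list(NULL, paste0("n", sprintf("%02d", 1:10))))
  m[, "n02"] <- m[, "n01"] # y = x among noise
  net <- clr_network(m, top_edges = 5)
  top <- net$edges[1, ]
  expect_setequal(c(top$from, top$to), c("n01", "n02"))
  expect_identical(net$params$requested, 5L)
  # the binned MI estimator can tie scores; the documented policy keeps
  # every pair tied with the k-th score, and exactly k edges otherwise
  scores <- attr(net, "scores")
  vals <- sort(scores[upper.tri(scores)], decreasing = TRUE)
  expected_n <- sum(vals >= vals[5])
  expect_identical(nrow(net$edges), as.integer(expected_n))
  expect_gte(nrow(net$edges), 5L)

  # scores are symmetric and non-negative by construction
  expect_identical(scores, t(scores))
  expect_true(all(scores >= 0))
  expect_true(all(net$edges$weight >= 0))

  # independent noise: the same tie-aware top-k contract holds
  m2 <- matrix(rnorm(200), nrow = 20,
               dimnames = list(NULL, paste0("m", 1:10)))
  net2 <- clr_network(m2, top_edges = 7)
  s2 <- attr(net2, "scores")
  v2 <- sort(s2[upper.tri(s2)], decreasing = TRUE)
  expect_identical(nrow(net2$edges), as.integer(sum(v2 >= v2[7])))
})

test_that("CLR edges are invariant to monotone rescaling of one node", {
  withr::local_seed(16)
  m <- matrix(rlnorm(150), nrow = 15,
              dimnames = list(NULL, paste0("n", 1:10)))
  m[, 3] <- m[, 4] * rlnorm(15, sd = 0.1)
  a <- clr_network(m, top_edges = 6)
  m2 <- m
  m2[, 3] <- log(m2[, 3]) # monotone transform; quantile bins unchanged
  b <- clr_network(m2, top_edges = 6)
  canon <- function(net) {
    sort(paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to)))
  }
  expect_identical(canon(a), canon(b))
})

test_that("forest importance recovers a planted driver edge deterministically", {
  withr::local_seed(17)
  m <- matrix(rnorm(320), nrow = 40,
              dimnames = list(NULL, c("y", paste0("x", 1:7))))
  m[, "y"] <- m[, "x1"] # exact copy
  net <- rf_importance_network(m, top_fraction = 0.1, seed = 3)
  into_y <- net$edges[net$edges$to == "y", ]
  expect_identical(into_y$from[which.max(into_y$weight)], "x1")

  # identical output for the same seed, and invariance to sample order
  net2 <- rf_importance_network(m, top_fraction = 0.1, seed = 3)
  expect_identical(net$edges, net2$edges)
  net3 <- rf_importance_network(m[sample(40), ], top_fraction = 0.1,
                                seed = 3)
  expect_identical(
    sort(paste(net$edges$from, net$edges$to)),
    sort(paste(net3$edges$from, net3$edges$to))
  )

  # rank-based selection returns the requested count on pure noise
  m4 <- matrix(rnorm(240), nrow = 30,
               dimnames = list(NULL, paste0("z", 1:8)))
  net4 <- rf_importance_network(m4, top_fraction = 0.1, seed = 5)
  expect_identical(nrow(net4$edges), as.integer(ceiling(0.1 * 8 * 7)))
  expect_true(net4$directed)

  expect_error(rf_importance_network(m4, top_fraction = 0.1),
               "seed.*mandatory")
})

test_that("centrality reproduces closed forms on path, complete and star graphs", {
  path <- cooc_edges(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  cp <- centrality(path)
  expect_identical(cp$betweenness[cp$node == "B"], 1)
  expect_identical(cp$betweenness[cp$node %in% c("A", "C")], c(0, 0))
  expect_identical(cp$rank_betweenness[cp$node == "B"], 1L)

  nodes <- LETTERS[1:5]
  cmb <- t(combn(nodes, 2))
  complete <- cooc_edges(tibble::tibble(from = cmb[, 1], to = cmb[, 2]))
  cc <- centrality(complete)
  expect_true(all(cc$betweenness == 0))
  expect_true(all(cc$degree == 4L))
  expect_true(all(cc$rank_degree == 1L)) # competition ranks share rank 1

  star <- cooc_edges(tibble::tibble(from = "hub", to = paste0("leaf", 1:4)))
  cs <- centrality(star)
  expect_identical(cs$degree[cs$node == "hub"], 4L)
  expect_true(all(cs$degree[cs$node != "hub"] == 1L))
  expect_identical(cs$betweenness[cs$node == "hub"], choose(4, 2))
})

test_that("betweenness and degree agree with exhaustive path enumeration", {
  withr::local_seed(18)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    adj <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- rbinom(1, 1, 0.45)
    }
    nodes <- paste0("n", 1:n)
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(idx) == 0) next
    net <- cooc_edges(tibble::tibble(from = nodes[idx[, 1]],
                                     to = nodes[idx[, 2]]),
                      nodes = nodes)
    got <- centrality(net)
    want <- oracle_betweenness(adj)
    expect_equal(got$betweenness[match(nodes, got$node)], want,
                 tolerance = 1e-12)
    expect_identical(got$degree[match(nodes, got$node)],
                     as.integer(rowSums(adj)))
  }
})

test_that("host cross-referencing highlights and never silently drops", {
  cent <- tibble::tibble(
    node = paste0("B", 1:10),
    betweenness = 10:1, degree = rep(5L, 10)
  ) |>
    dplyr::mutate(rank_betweenness = dplyr::min_rank(dplyr::desc(betweenness)),
                  rank_degree = dplyr::min_rank(dplyr::desc(degree)))
  rep2 <- cross_reference_hosts(cent, hosts = "B2")
  expect_true(rep2$top_betweenness$is_host[
    rep2$top_betweenness$node == "B2"
  ])
  expect_identical(nrow(rep2$top_betweenness), 5L)

  none <- cross_reference_hosts(cent, hosts = character(0))
  expect_false(any(none$table$is_host))

  all_h <- cross_reference_hosts(cent, hosts = cent$node)
  expect_true(all(all_h$top_betweenness$is_host))

  # unmapped proxy nodes are listed
  map <- tibble::tibble(node = cent$node[-1], population_id = cent$node[-1])
  with_na <- cross_reference_hosts(cent, hosts = "B2", node_to_host = map)
  expect_identical(with_na$unmapped, "B1")
})
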