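# Independent brute-force oracles. These deliberately avoid the package's
# code paths (dense matrices and explicit loops instead of keyed lookups,
# character scanning instead of Biostrings, path enumeration instead of
# igraph) so that agreement is informative.

oracle_greedy <- function(items, sims, ani_cut, af_cut) {
  ids <- items$id[order(-items$length, items$id)]
  n <- length(ids)
  ani <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  af <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  if (nrow(sims) > 0) {
    for (r in seq_len(nrow(sims))) {
      a <- sims$id_a[r]; b <- sims$id_b[r]
      if (a %in% ids && b %in% ids) {
        ani[a, b] <- max(ani[a, b], sims$ani[r])
        ani[b, a] <- ani[a, b]
        af[a, b] <- max(af[a, b], sims$af[r])
        af[b, a] <- af[a, b]
      }
    }
  }
  clusters <- list() # each: representative followed by members
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]][1]
      if (ani[id, rep_id] >= ani_cut && af[id, rep_id] >= af_cut) {
        clusters[[k]] <- c(clusters[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- id
  }
  out <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(id = cl, cluster = cl[1],
               representative = cl == cl[1])
  }))
  out[order(match(out$id, ids)), ]
}

random_cluster_instance <- function(n, seed) {
  set.seed(seed)
  items <- tibble::tibble(
    id = paste0("c", sample(100, n)),
    length = sample(50:500, n, replace = TRUE)
  )
  pairs <- t(combn(items$id, 2))
  keep <- runif(nrow(pairs)) < 0.6
  sims <- tibble::tibble(
    id_a = pairs[keep, 1], id_b = pairs[keep, 2],
    ani = round(runif(sum(keep), 80, 100), 1),
    af = round(runif(sum(keep), 60, 100), 1)
  )
  list(items = items, sims = sims)
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

count_mm <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# naive O(n*m) full scan, both strands; returns best hit over all contigs
# with the documented tie-breaks, or NULL
naive_spacer_best <- function(spacer, contigs, max_mm = 1,
                              min_identity = 0.95) {
  m <- nchar(spacer)
  budget <- min(max_mm, floor((1 - min_identity) * m))
  hits <- list()
  for (cid in names(contigs)) {
    subj <- contigs[[cid]]
    best <- Inf
    for (pat in c(spacer, revcomp_chr(spacer))) {
      if (nchar(subj) >= m) {
        for (i in 1:(nchar(subj) - m + 1)) {
          mm <- count_mm(substring(subj, i, i + m - 1), pat)
          if (mm < best) best <- mm
        }
      }
    }
    if (best <= budget) {
      hits[[length(hits) + 1]] <- data.frame(
        contig_id = cid, mismatches = best,
        contig_length = nchar(subj)
      )
    }
  }
  if (length(hits) == 0) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[order(h$mismatches, -h$contig_length, h$contig_id), ]
  h[1, ]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at_pos <- function(seq, k) {
  # plant exactly k mismatches at distinct positions
  pos <- sample(nchar(seq), k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# enumerate all simple paths s -> t and keep the shortest ones
all_shortest_paths_brute <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(adj[v, ] == 1)) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(s)
  if (length(paths) == 0) return(list())
  lens <- vapply(paths, length, 1L)
  paths[lens == min(lens)]
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bet <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      sp <- all_shortest_paths_brute(adj, s, t)
      if (length(sp) == 0) next
      for (v in setdiff(1:n, c(s, t))) {
        through <- sum(vapply(sp, function(p) v %in% p, TRUE))
        bet[v] <- bet[v] + through / length(sp)
      }
    }
  }
  bet
}

random_candidates <- function(n, seed) {
  set.seed(seed)
  n_phage <- max(2, ceiling(n / 3))
  tibble::tibble(
    phage_id = paste0("P", sample(n_phage, n, replace = TRUE)),
    mag_id = paste0("B", sample(40, n, replace = TRUE)),
    condition = "pre",
    replicate = sample(3, n, replace = TRUE),
    L = sample(1:50, n, replace = TRUE),
    len_phage_kb = runif(n, 10, 100),
    len_mag_kb = runif(n, 1000, 5000),
    V = runif(n, 0.1, 5),
    H = runif(n, 0.1, 5),
    intra = sample(0:500, n, replace = TRUE)
  ) |>
    dplyr::distinct(phage_id, mag_id, replicate, .keep_all = TRUE) |>
    dplyr::group_by(condition, replicate, phage_id) |>
    dplyr::mutate(sum_Lv = sum(L)) |>
    dplyr::ungroup() |>
    phagehic::compute_vph() |>
    phagehic::compute_r_prime()
}

oracle_roc <- function(cands, score) {
  s <- cands[[score]]
  ph <- cands$phage_id
  ts <- sort(unique(s))
  obj <- vapply(ts, function(t) {
    f <- length(unique(ph[s >= t])) / length(unique(ph))
    g <- sum(s < t) / length(s)
    f + g
  }, 1)
  # ties within the documented 1e-9 tolerance resolve to the smallest t
  best_t <- ts[which(obj > max(obj) - 1e-9)[1]]
  list(threshold = best_t, survivors = cands[s >= best_t, ])
}

oracle_round1 <- function(cands, min_links = 2, min_ratio = 0.1,
                          min_intra = 10) {
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    keep[i] <- cands$L[i] >= min_links &&
      !is.na(cands$r_prime[i]) && cands$r_prime[i] >= min_ratio &&
      cands$intra[i] >= min_intra
  }
  cands[keep, ]
}

oracle_rel80 <- function(cands, frac = 0.8) {
  key <- paste(cands$condition, cands$phage_id, cands$mag_id)
  gkey <- paste(cands$condition, cands$phage_id)
  avg <- tapply(cands$L, key, mean)
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    grp_keys <- unique(key[gkey == gkey[i]])
    keep[i] <- avg[[key[i]]] >= frac * max(avg[grp_keys])
  }
  cands[keep, ]
}

# minimal undirected graph wrapper for centrality tests
cooc_edges <- function(edges, nodes = NULL, directed = FALSE) {
  igraph::graph_from_data_frame(edges, directed = directed, vertices = nodes)
}
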