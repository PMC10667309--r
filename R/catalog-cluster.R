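#' Greedy centroid clustering on pairwise ANI / aligned fraction
#'
#' Species-rank viral clustering (vOTUs) and MAG dereplication both reduce to
#' the same greedy centroid scan: items are sorted by decreasing length (ties
#' broken lexicographically by id), the longest item founds the first cluster,
#' and each subsequent item joins the first existing cluster whose
#' *representative* it matches at `ani >= ani_cut` and `af >= af_cut`,
#' otherwise it founds a new cluster. With `(95, 85)` this yields vOTUs; with
#' `(99, 0)` on a MAG identity table it yields dereplicated host populations.
#'
#' The aligned fraction is computed on the shorter sequence of a pair. A pair
#' absent from `sims` is treated as below the cutoffs.
#'
#' @param items Data frame with columns `id` and `length` (positive).
#' @param sims Data frame with columns `id_a`, `id_b`, `ani`, `af`
#'   (percentages in `[0, 100]`); symmetric on lookup, sparse allowed.
#' @param ani_cut,af_cut Inclusive cutoffs (percent).
#' @return A tibble with one row per item: `id`, `cluster` (the representative
#'   id), `representative` (logical), ordered by the greedy scan.
#' @export
#' @examples
#' items <- tibble::tibble(id = c("a", "b", "c"), length = c(30, 20, 10))
#' sims <- tibble::tibble(id_a = "a", id_b = "b", ani = 97, af = 90)
#' greedy_centroid_cluster(items, sims, 95, 85)
greedy_centroid_cluster <- function(items, sims, ani_cut = 95, af_cut = 85) {
  items <- as_tibble(items)
  if (!all(c("id", "length") %in% names(items))) {
    abort("`items` needs columns `id` and `length`.")
  }
  if (any(items$length <= 0)) abort("All item lengths must be positive.")
  if (anyDuplicated(items$id)) abort("Item ids must be unique.")
  sims <- as_tibble(sims)
  if (nrow(sims) > 0) {
    if (!all(c("id_a", "id_b", "ani", "af") %in% names(sims))) {
      abort("`sims` needs columns `id_a`, `id_b`, `ani`, `af`.")
    }
    if (any(sims$ani < 0 | sims$ani > 100 | sims$af < 0 | sims$af > 100)) {
      abort("`ani` and `af` must lie in [0, 100].")
    }
  }

  ord <- order(-items$length, items$id)
  ids <- items$id[ord]

  # symmetric lookup of (ani, af) keyed on unordered pair
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lookup_ani <- lookup_af <- numeric(0)
  if (nrow(sims) > 0) {
    k <- key(sims$id_a, sims$id_b)
    # on duplicate entries for a pair, the best (max) similarity wins
    lookup_ani <- tapply(sims$ani, k, max)
    lookup_af <- tapply(sims$af, k, max)
  }
  passes <- function(a, b) {
    k <- key(a, b)
    ani <- lookup_ani[k]
    af <- lookup_af[k]
    !is.na(ani) && !is.na(af) && ani >= ani_cut && af >= af_cut
  }

  reps <- character(0)
  assignment <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    hit <- NA_character_
    for (r in reps) {
      if (passes(id, r)) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      hit <- id
    }
    assignment[i] <- hit
  }
  tibble(id = ids, cluster = assignment, representative = ids == assignment)
}

#' Trivial identity clustering
#'
#' Wraps a set of ids as singleton clusters (each item its own
#' representative), the degenerate case used when no similarity table is
#' available (e.g. simulator output, where every phage is its own vOTU).
#'
#' @param ids Character vector of ids.
#' @return A tibble shaped like [greedy_centroid_cluster()] output.
#' @export
identity_clusters <- function(ids) {
  tibble(id = ids, cluster = ids, representative = TRUE)
}
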