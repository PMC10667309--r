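make_records <- function(...) {
  tibble::tribble(...)
}

test_that("read-pair aggregation applies the mapping filters", {
  meta <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4"),
    length_kb = c(50, 3000, 2000, 0.5),
    mag_id = c(NA, "B1", "B1", NA)
  )
  rec <- make_records(
    ~read_id, ~contig_a, ~contig_b, ~mapq_a, ~mapq_b, ~is_duplicate,
    ~is_primary_a, ~is_primary_b,
    "r1", "c1", "c2", 30, 40, FALSE, TRUE, TRUE,  # kept
    "r2", "c1", "c2", 30, 40, TRUE,  TRUE, TRUE,  # duplicate
    "r3", "c1", "c2", 30, 40, TRUE,  TRUE, TRUE,  # duplicate
    "r4", "c1", "c2", 10, 40, FALSE, TRUE, TRUE,  # low mapq
    "r5", "c1", "c3", 30, 40, FALSE, TRUE, TRUE   # kept
  )
  out <- aggregate_read_pairs(rec, meta)
  expect_identical(sum(out$links$links), 2L)
  expect_setequal(out$links$entity_a, "B1")
  expect_setequal(out$links$entity_b, "c1")

  # both ends on one contig: excluded everywhere
  same <- make_records(
    ~read_id, ~contig_a, ~contig_b, ~mapq_a, ~mapq_b, ~is_duplicate,
    ~is_primary_a, ~is_primary_b,
    "r1", "c2", "c2", 30, 40, FALSE, TRUE, TRUE
  )
  out2 <- aggregate_read_pairs(same, meta)
  expect_identical(nrow(out2$links), 0L)
  expect_identical(nrow(out2$intra), 0L)

  # distinct contigs of one MAG: intra-MAG connectivity, no inter link
  intra <- make_records(
    ~read_id, ~contig_a, ~contig_b, ~mapq_a, ~mapq_b, ~is_duplicate,
    ~is_primary_a, ~is_primary_b,
    "r1", "c2", "c3", 30, 40, FALSE, TRUE, TRUE
  )
  out3 <- aggregate_read_pairs(intra, meta)
  expect_identical(nrow(out3$links), 0L)
  expect_identical(out3$intra$intra_links, 1L)
  expect_identical(out3$intra$mag_id, "B1")

  # non-primary alignments and short contigs are dropped; unknown contigs err
  nonprim <- dplyr::mutate(intra, is_primary_b = FALSE)
  expect_identical(nrow(aggregate_read_pairs(nonprim, meta)$intra), 0L)
  short <- dplyr::mutate(intra, contig_b = "c4")
  expect_identical(nrow(aggregate_read_pairs(short, meta)$links), 0L)
  expect_error(
    aggregate_read_pairs(dplyr::mutate(intra, contig_b = "zz"), meta),
    "absent from metadata"
  )
})

test_that("VPH follows the abundance-ratio times link-share form", {
  expect_identical(
    compute_vph(tibble::tibble(V = 4, H = 2, L = 3, sum_Lv = 6))$vph, 1
  )
  # identity case V = H, L = sum_Lv
  expect_identical(
    compute_vph(tibble::tibble(V = 2, H = 2, L = 5, sum_Lv = 5))$vph, 1
  )
  # no links -> zero estimate
  expect_identical(
    compute_vph(tibble::tibble(V = 4, H = 2, L = 0, sum_Lv = 6))$vph, 0
  )
  # undefined when H = 0 or sum_Lv = 0
  expect_true(is.na(
    compute_vph(tibble::tibble(V = 4, H = 0, L = 3, sum_Lv = 6))$vph
  ))
})

test_that("R' reproduces the hand-computed boundary candidate", {
  c0 <- tibble::tibble(
    V = 1, H = 1, L = 5, sum_Lv = 5, len_phage_kb = 10, len_mag_kb = 100,
    intra = 500
  )
  out <- compute_r_prime(compute_vph(c0))
  expect_equal(out$d_vh, 0.005)
  expect_equal(out$d_h, 0.05)
  expect_equal(out$vph, 1)
  expect_equal(out$r_prime, 0.1)
})

test_that("the R' x VPH identity and scale cancellations hold", {
  cands <- random_candidates(200, seed = 5)
  ok <- !is.na(cands$r_prime)
  expect_true(any(ok))
  expect_equal(cands$r_prime[ok] * cands$vph[ok],
               (cands$d_vh / cands$d_h)[ok], tolerance = 1e-12)
  # doubling both V and L (and sum_Lv with it) leaves r_prime * vph fixed
  doubled <- cands |>
    dplyr::mutate(V = 2 * V, L = 2 * L, sum_Lv = 2 * sum_Lv) |>
    compute_vph() |>
    compute_r_prime()
  expect_equal((doubled$r_prime * doubled$vph)[ok],
               2 * (cands$r_prime * cands$vph)[ok], tolerance = 1e-12)
})

test_that("round-1 filtering applies inclusive thresholds", {
  boundary <- compute_r_prime(compute_vph(tibble::tibble(
    phage_id = "P1", V = 1, H = 1, L = 5, sum_Lv = 5,
    len_phage_kb = 10, len_mag_kb = 100, intra = 500
  )))
  expect_identical(nrow(round1_filter(boundary)), 1L) # r_prime exactly 0.1

  low_links <- dplyr::mutate(boundary, L = 1, sum_Lv = 1) |>
    compute_vph() |> compute_r_prime()
  expect_identical(nrow(round1_filter(low_links)), 0L)

  cands <- random_candidates(120, seed = 9)
  kept <- round1_filter(cands)
  audit <- attr(kept, "audit")
  expect_identical(nrow(audit), nrow(cands))
  # flags exactly explain survival
  expect_identical(
    nrow(kept),
    sum(audit$flag_min_links & audit$flag_ratio & audit$flag_intra)
  )
  # rejected-on-ratio example
  rej <- audit[!audit$flag_ratio & audit$flag_min_links & audit$flag_intra, ]
  if (nrow(rej) > 0) expect_true(all(rej$r_prime < 0.1))
})

test_that("the threshold scan reproduces the stated examples", {
  base <- tibble::tibble(
    phage_id = c("A", "A", "B"),
    score = c(0.9, 0.05, 0.9)
  )
  res <- roc_threshold(base, score = "score")
  expect_identical(res$threshold, 0.9)
  expect_identical(nrow(res$survivors), 2L)
  expect_false(0.05 %in% res$survivors$score)

  # one shared score value: everything retained
  flat <- tibble::tibble(phage_id = c("A", "B", "C"), score = 0.4)
  res_flat <- roc_threshold(flat, score = "score")
  expect_identical(res_flat$threshold, 0.4)
  expect_identical(nrow(res_flat$survivors), 3L)

  # single candidate: threshold equals its score, candidate kept
  solo <- tibble::tibble(phage_id = "A", score = 0.7)
  res_solo <- roc_threshold(solo, score = "score")
  expect_identical(res_solo$threshold, 0.7)
  expect_identical(nrow(res_solo$survivors), 1L)

  expect_error(roc_threshold(flat[0, ], score = "score"), "non-empty")
})

test_that("the threshold scan equals exhaustive search", {
  for (seed in 1:25) {
    cands <- random_candidates(sample(5:50, 1), seed = 100 + seed)
    for (sc in c("r_prime", "L")) {
      got <- roc_threshold(cands, score = sc)
      want <- oracle_roc(cands, score = sc)
      expect_identical(got$threshold, want$threshold)
      expect_identical(as.data.frame(got$survivors),
                       as.data.frame(want$survivors))
    }
  }
})

test_that("the relative-count rule drops links under 80% of the phage maximum", {
  one_phage <- tibble::tibble(
    phage_id = "P1", mag_id = c("B1", "B2", "B3"), condition = "pre",
    replicate = 1L, L = c(10, 9, 7)
  )
  kept <- relative_count_filter(one_phage)
  expect_setequal(kept$mag_id, c("B1", "B2")) # 7 < 0.8 * 10

  # exactly at the boundary is kept ("less than" is strict)
  edge <- dplyr::mutate(one_phage[1:2, ], L = c(10, 8))
  expect_identical(nrow(relative_count_filter(edge)), 2L)

  # single-host phage always kept
  solo <- one_phage[1, ]
  expect_identical(nrow(relative_count_filter(solo)), 1L)

  # counts are averaged across the replicates in which a pair appears
  multi <- tibble::tibble(
    phage_id = "P1",
    mag_id = c("B1", "B1", "B2"),
    condition = "pre",
    replicate = c(1L, 2L, 1L),
    L = c(10, 2, 7)
  )
  # B1 average 6, B2 average 7 -> max 7, keep both (6 >= 5.6)
  expect_identical(nrow(relative_count_filter(multi)), 3L)
  # but B2 at 12 in a second replicate pushes the max to 9.5 > 6 / 0.8
  multi2 <- dplyr::bind_rows(
    multi, tibble::tibble(phage_id = "P1", mag_id = "B2", condition = "pre",
                          replicate = 2L, L = 12)
  )
  kept2 <- relative_count_filter(multi2)
  expect_setequal(kept2$mag_id, "B2")
})

test_that("relative-count filtering matches a brute-force re-implementation", {
  for (seed in 1:25) {
    cands <- random_candidates(sample(5:50, 1), seed = 200 + seed)
    got <- relative_count_filter(cands)
    want <- oracle_rel80(cands)
    norm <- function(x) {
      x <- as.data.frame(x)[, c("phage_id", "mag_id", "replicate", "L")]
      x[order(x$phage_id, x$mag_id, x$replicate), ]
    }
    expect_identical(norm(got), norm(want))
  }
})

test_that("round-1 filtering matches a brute-force re-implementation", {
  for (seed in 1:25) {
    cands <- random_candidates(sample(5:50, 1), seed = 300 + seed)
    got <- as.data.frame(round1_filter(cands))
    attr(got, "audit") <- NULL
    want <- as.data.frame(oracle_round1(cands))
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("promiscuous phages are flagged and removed under the default policy", {
  cands <- tibble::tibble(
    phage_id = rep(c("P1", "P2"), c(30, 2)),
    mag_id = paste0("B", c(1:30, 1:2)),
    condition = "pre", replicate = 1L, L = 5
  )
  res <- promiscuity_adjust(cands, n_mags = 100)
  expect_true(res$report$flagged[res$report$phage_id == "P1"])
  expect_false(res$report$flagged[res$report$phage_id == "P2"])
  expect_setequal(unique(res$candidates$phage_id), "P2")

  # disabled policy is a no-op but still reports
  res_off <- promiscuity_adjust(cands, n_mags = 100, max_host_fraction = 1)
  expect_identical(nrow(res_off$candidates), nrow(cands))
  expect_false(any(res_off$report$flagged))

  # flag without removal
  res_keep <- promiscuity_adjust(cands, n_mags = 100, remove = FALSE)
  expect_identical(nrow(res_keep$candidates), nrow(cands))
  expect_true(any(res_keep$report$flagged))
})

test_that("candidates collapse to unique replicate-supported pairs", {
  cands <- tibble::tibble(
    phage_id = c("p1a", "p1b", "p2", "p2"),
    mag_id = c("B1", "B2", "B3", "B4"),
    condition = c("pre", "pre", "pre", "pre"),
    replicate = c(1L, 2L, 1L, 1L),
    L = 5, vph = 1
  )
  votus <- tibble::tibble(id = c("p1a", "p1b", "p2"),
                          cluster = c("V1", "V1", "V2"),
                          representative = c(TRUE, FALSE, TRUE))
  mags <- tibble::tibble(id = paste0("B", 1:4),
                         cluster = c("B1", "B1", "B3", "B4"),
                         representative = c(TRUE, FALSE, TRUE, TRUE))
  pairs <- collapse_to_pairs(cands, votus, mags)
  # two contigs of one vOTU linked to 99%-identical bins in different
  # replicates -> one pair with support {1, 2}
  v1 <- pairs[pairs$votu_id == "V1", ]
  expect_identical(nrow(v1), 1L)
  expect_identical(v1$replicate_support[[1]], c(1L, 2L))
  expect_identical(v1$support_count, 2L)
  expect_identical(v1$host_range_class, "one_host")
  # a vOTU linked to two populations is a multi-host vOTU
  v2 <- pairs[pairs$votu_id == "V2", ]
  expect_identical(nrow(v2), 2L)
  expect_setequal(v2$host_range_class, "multiple_hosts")

  expect_error(collapse_to_pairs(cands, votus[-1, ], mags), "Unassigned")
})

test_that("per-host VPH sums the phage contributions", {
  cands <- tibble::tibble(
    phage_id = c("p1", "p2", "p3"),
    mag_id = c("B1", "B1", "B2"),
    condition = "pre", replicate = 1L,
    vph = c(0.5, 0.25, 2)
  )
  tbl <- vph_per_host(cands)
  expect_identical(tbl$total_vph[tbl$population_id == "B1"], 0.75)
  expect_identical(tbl$total_vph[tbl$population_id == "B2"], 2)
  # hosts with no surviving links are absent, not zero
  expect_false("B3" %in% tbl$population_id)
})

test_that("filtering stages are monotone on simulated data", {
  sim <- simulate_community(small_config(seed = 21))
  pres <- call_presence(sim$data$coverage_dna)
  ab <- dplyr::select(pres, entity_id, condition, replicate, abundance)
  cands <- build_candidates(sim$data$links, sim$data$intra, ab,
                            sim$data$entities)
  r1 <- round1_filter(cands)
  r2 <- dplyr::bind_rows(lapply(
    split(r1, interaction(r1$condition, r1$replicate, drop = TRUE)),
    function(g) roc_threshold(g, score = "L")$survivors
  ))
  r3 <- relative_count_filter(r2)
  r4 <- promiscuity_adjust(r3, n_mags = 12)$candidates
  key <- function(x) paste(x$phage_id, x$mag_id, x$condition, x$replicate)
  expect_true(all(key(r1) %in% key(cands)))
  expect_true(all(key(r2) %in% key(r1)))
  expect_true(all(key(r3) %in% key(r2)))
  expect_true(all(key(r4) %in% key(r3)))
  # rejected candidates carry reasons
  rej <- attr(cands, "rejected")
  expect_true(all(!is.na(rej$reason)))
})
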