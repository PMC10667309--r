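#' Build phage-host candidate records from link tables
#'
#' Assembles one row per (phage contig, MAG, replicate) Hi-C link, carrying
#' everything the VPH and connectivity-ratio estimators need: the pair link
#' count `L`, the phage's total links to all MAGs in the same replicate table
#' `sum_Lv` (evaluated before any filtering), the normalized abundances `V`
#' (phage) and `H` (host), entity lengths, and the host's intra-MAG link
#' count. VPH and R' are computed on the way out.
#'
#' Candidates whose estimators are undefined — host or phage not detected
#' (`H = 0` / `V = 0`), no phage-host links (`sum_Lv = 0`), or zero intra-MAG
#' connectivity — are split off with a reason; retrieve them with
#' `attr(x, "rejected")`.
#'
#' @param links Tibble `(condition, replicate, entity_a, entity_b, links)`.
#' @param intra Tibble `(condition, replicate, mag_id, intra_links)`.
#' @param abundance Tibble `(entity_id, condition, replicate, abundance)` of
#'   normalized abundances (see [call_presence()]); absent entities must carry
#'   0, not be missing.
#' @param entities Tibble `(entity_id, type, length_kb)` with type `"phage"`
#'   or `"host"`.
#' @return A tibble of candidates with columns `phage_id`, `mag_id`,
#'   `condition`, `replicate`, `L`, `sum_Lv`, `V`, `H`, `len_phage_kb`,
#'   `len_mag_kb`, `intra`, `d_vh`, `d_h`, `vph`, `r_prime`; rejected rows
#'   (with a `reason` column) as the `"rejected"` attribute.
#' @export
build_candidates <- function(links, intra, abundance, entities) {
  entities <- as_tibble(entities)
  typ <- setNames(entities$type, entities$entity_id)
  len <- setNames(entities$length_kb, entities$entity_id)
  links <- as_tibble(links)
  unknown <- setdiff(unique(c(links$entity_a, links$entity_b)),
                     entities$entity_id)
  if (length(unknown) > 0) {
    abort(paste0("Link table references unknown entit(ies): ",
                 paste(head(unknown, 5), collapse = ", "), "."))
  }

  ph <- links |>
    mutate(
      type_a = unname(typ[.data$entity_a]),
      type_b = unname(typ[.data$entity_b])
    ) |>
    filter(.data$type_a != .data$type_b) |>
    mutate(
      phage_id = if_else(.data$type_a == "phage", .data$entity_a,
                         .data$entity_b),
      mag_id = if_else(.data$type_a == "phage", .data$entity_b,
                       .data$entity_a),
      L = .data$links
    ) |>
    select("condition", "replicate", "phage_id", "mag_id", "L")

  ph <- ph |>
    group_by(.data$condition, .data$replicate, .data$phage_id) |>
    mutate(sum_Lv = sum(.data$L)) |>
    ungroup()

  ab <- as_tibble(abundance)
  cands <- ph |>
    left_join(ab |> rename(phage_id = "entity_id", V = "abundance"),
              by = c("phage_id", "condition", "replicate")) |>
    left_join(ab |> rename(mag_id = "entity_id", H = "abundance"),
              by = c("mag_id", "condition", "replicate")) |>
    mutate(
      V = dplyr::coalesce(.data$V, 0),
      H = dplyr::coalesce(.data$H, 0),
      len_phage_kb = unname(len[.data$phage_id]),
      len_mag_kb = unname(len[.data$mag_id])
    ) |>
    left_join(as_tibble(intra), by = c("condition", "replicate", "mag_id")) |>
    mutate(intra = dplyr::coalesce(.data$intra_links, 0L)) |>
    select(-dplyr::any_of("intra_links"))

  reason <- dplyr::case_when(
    cands$H <= 0 ~ "host not detected (H = 0)",
    cands$V <= 0 ~ "phage not detected (V = 0)",
    cands$sum_Lv <= 0 ~ "no phage-host links (sum L(v) = 0)",
    cands$intra <= 0 ~ "zero intra-MAG connectivity (D_H undefined)",
    TRUE ~ NA_character_
  )
  rejected <- cands[!is.na(reason), ]
  rejected$reason <- reason[!is.na(reason)]
  out <- cands[is.na(reason), ] |>
    compute_vph() |>
    compute_r_prime()
  attr(out, "rejected") <- rejected
  out
}

#' Viral copies per host cell (VPH)
#'
#' `vph = (V / H) * (L / sum_Lv)`: the phage-to-host abundance ratio,
#' apportioned to one host by that host's share of the phage's Hi-C links.
#'
#' @param cands Candidate tibble with columns `V`, `H`, `L`, `sum_Lv`.
#' @return `cands` with a `vph` column appended (rows with `H = 0` or
#'   `sum_Lv = 0` get `NA`).
#' @export
#' @examples
#' compute_vph(tibble::tibble(V = 4, H = 2, L = 3, sum_Lv = 6))$vph # 1
compute_vph <- function(cands) {
  cands |>
    mutate(vph = if_else(
      .data$H > 0 & .data$sum_Lv > 0,
      (.data$V / .data$H) * (.data$L / .data$sum_Lv),
      NA_real_
    ))
}

#' Phage-host connectivity ratio (R')
#'
#' The link density of the phage-host pair relative to the host's internal
#' link density, normalized by VPH:
#' `r_prime = (d_vh / d_h) * (H * sum_Lv) / (V * L)` with
#' `d_vh = L / (len_phage_kb * len_mag_kb)` and
#' `d_h = intra / len_mag_kb^2`. The algebraic identity
#' `r_prime * vph = d_vh / d_h` holds for every well-defined candidate.
#'
#' @param cands Candidate tibble with columns `L`, `V`, `H`, `sum_Lv`,
#'   `len_phage_kb`, `len_mag_kb`, `intra`.
#' @return `cands` with `d_vh`, `d_h` and `r_prime` columns appended (rows
#'   with zero intra-MAG links or `V = 0` get `NA`).
#' @export
compute_r_prime <- function(cands) {
  cands |>
    mutate(
      d_vh = .data$L / (.data$len_phage_kb * .data$len_mag_kb),
      d_h = if_else(.data$intra > 0,
                    .data$intra / .data$len_mag_kb^2, NA_real_),
      r_prime = if_else(
        .data$intra > 0 & .data$V > 0 & .data$L > 0,
        (.data$d_vh / .data$d_h) * (.data$H * .data$sum_Lv) /
          (.data$V * .data$L),
        NA_real_
      )
    )
}
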