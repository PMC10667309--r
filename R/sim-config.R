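#' Configuration for the synthetic soil-community simulator
#'
#' Builds a validated configuration object for [simulate_community()]. The
#' defaults describe a moderately diverse soil community observed with a
#' paired shotgun + proximity-ligation (Hi-C) design: host genomes (MAGs) with
#' log-normal abundances, a phage community with a mix of specialists and
#' generalists, Poisson-distributed Hi-C link counts, and a replicated
#' two-condition (pre/post desiccation) sampling structure.
#'
#' Link counts are generated at the entity level. For a true infection the
#' expected phage-host link count is
#' `inter_link_efficiency * true_vph * host_abundance * phage_kb * host_kb`;
#' the expected within-MAG (intra) link count is
#' `intra_link_rate * host_abundance * host_kb^2`; spurious background links
#' are drawn uniformly over unordered entity pairs with mean `noise_link_rate`
#' per pair. All counts are Poisson draws around these means.
#'
#' @param n_hosts,n_phages Number of host MAGs and phage contigs.
#' @param host_length_kb,phage_length_kb Length ranges (kb), sampled uniformly.
#' @param host_abundance Named vector `c(meanlog=, sdlog=)` of the log-normal
#'   host abundance distribution (arbitrary relative units).
#' @param condition_jitter_sdlog Log-normal sd of the per-condition drift
#'   applied to host abundances after the first condition.
#' @param p_no_host Probability a phage is free-living in this community: it
#'   appears in the metagenome but has no infected host among the binned
#'   MAGs, so it can never be truly host-associated (the dominant class in
#'   real soil, where most vOTUs have no detected host).
#' @param free_phage_abundance Named `c(meanlog=, sdlog=)` log-normal for the
#'   abundance of free phages in their active conditions.
#' @param p_generalist Probability that an infecting phage infects more than
#'   one host.
#' @param host_range_size Integer range of host-range sizes for generalists.
#' @param vph_truth Range of true viral copies per host cell per infection.
#' @param post_vph_multiplier Multiplier applied to true VPH in conditions
#'   after the first (emulates the rise in lysogeny after drying).
#' @param vph_condition_jitter_sdlog Log-normal jitter on the per-condition VPH.
#' @param p_lysogenic Probability a phage is labelled lysogenic (lower
#'   transcriptional activity).
#' @param p_both_conditions Probability a phage is active in every condition;
#'   otherwise it is active in exactly one condition, chosen uniformly.
#' @param phage_free_factor_sdlog Log-normal sdlog of the per-(phage,
#'   condition) multiplier between the copies a phage maintains inside its
#'   hosts and its observed metagenome abundance. Free virions, burst-size
#'   variation and extraction efficiency make the observed phage abundance an
#'   imperfect proxy for the host-associated copy number, which is what makes
#'   the VPH estimator noisy in real data; 0 disables the effect.
#' @param intra_link_rate Expected intra-MAG links per kb^2 per unit abundance.
#' @param inter_link_efficiency Scale factor for true phage-host link means.
#' @param noise_link_rate Expected spurious links per unordered entity pair.
#' @param n_replicates Biological replicates per condition.
#' @param conditions Character vector of condition labels; the first is the
#'   baseline (no VPH multiplier).
#' @param breadth_present,breadth_absent Beta shape pairs for coverage breadth
#'   of present entities, and of absent entities (the latter rescaled into
#'   `[0, 0.5)` so absent entities always fall below the detection boundary).
#' @param depth_cv Log-normal sdlog of multiplicative noise on read depths.
#' @param library_size_dna,library_size_rna Reads per metagenome /
#'   metatranscriptome library.
#' @param rna_silent_p Probability a present phage shows zero transcription in
#'   a given sample.
#' @param lysogenic_activity Transcriptional activity of lysogenic phages
#'   relative to lytic ones.
#' @param post_activity_multiplier Multiplier on phage transcriptional
#'   activity in conditions after the first.
#' @param args_noise_sdlog Log-normal noise on the argS proxy transcript
#'   abundances.
#' @param n_duplicated_proxies Number of MAGs contributing two argS proxy
#'   nodes (default one per MAG).
#' @param seed Integer RNG seed; identical configurations produce identical
#'   datasets.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_hosts = 10, n_phages = 15)
#' cfg$n_replicates
sim_config <- function(n_hosts = 100,
                       n_phages = 150,
                       host_length_kb = c(1500, 5000),
                       phage_length_kb = c(20, 100),
                       host_abundance = c(meanlog = 0, sdlog = 0.7),
                       condition_jitter_sdlog = 0.3,
                       p_no_host = 0.55,
                       free_phage_abundance = c(meanlog = 0.7, sdlog = 1),
                       p_generalist = 0.15,
                       host_range_size = c(2L, 3L),
                       vph_truth = c(0.5, 4),
                       post_vph_multiplier = 1.6,
                       vph_condition_jitter_sdlog = 0.15,
                       p_lysogenic = 0.3,
                       p_both_conditions = 0.2,
                       phage_free_factor_sdlog = 0.3,
                       intra_link_rate = 2e-4,
                       inter_link_efficiency = 2e-3,
                       noise_link_rate = 0.3,
                       n_replicates = 3,
                       conditions = c("pre", "post"),
                       breadth_present = c(8, 2),
                       breadth_absent = c(2, 2),
                       depth_cv = 0.05,
                       library_size_dna = 2e7,
                       library_size_rna = 1e7,
                       rna_silent_p = 0.3,
                       lysogenic_activity = 0.1,
                       post_activity_multiplier = 0.5,
                       args_noise_sdlog = 0.3,
                       n_duplicated_proxies = 0,
                       seed = 1L) {
  cfg <- list(
    n_hosts = as.integer(n_hosts), n_phages = as.integer(n_phages),
    host_length_kb = as.numeric(host_length_kb),
    phage_length_kb = as.numeric(phage_length_kb),
    host_abundance = host_abundance,
    condition_jitter_sdlog = condition_jitter_sdlog,
    p_no_host = p_no_host,
    free_phage_abundance = free_phage_abundance,
    p_generalist = p_generalist,
    host_range_size = as.integer(host_range_size),
    vph_truth = as.numeric(vph_truth),
    post_vph_multiplier = post_vph_multiplier,
    vph_condition_jitter_sdlog = vph_condition_jitter_sdlog,
    p_lysogenic = p_lysogenic,
    p_both_conditions = p_both_conditions,
    phage_free_factor_sdlog = phage_free_factor_sdlog,
    intra_link_rate = intra_link_rate,
    inter_link_efficiency = inter_link_efficiency,
    noise_link_rate = noise_link_rate,
    n_replicates = as.integer(n_replicates),
    conditions = as.character(conditions),
    breadth_present = breadth_present, breadth_absent = breadth_absent,
    depth_cv = depth_cv,
    library_size_dna = library_size_dna, library_size_rna = library_size_rna,
    rna_silent_p = rna_silent_p, lysogenic_activity = lysogenic_activity,
    post_activity_multiplier = post_activity_multiplier,
    args_noise_sdlog = args_noise_sdlog,
    n_duplicated_proxies = as.integer(n_duplicated_proxies),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_hosts < 1L || cfg$n_phages < 1L || cfg$n_replicates < 1L) {
    abort("`n_hosts`, `n_phages` and `n_replicates` must all be >= 1.")
  }
  probs <- c(cfg$p_generalist, cfg$p_lysogenic, cfg$p_both_conditions,
             cfg$rna_silent_p, cfg$p_no_host)
  if (any(probs < 0 | probs > 1)) {
    abort("All probability parameters must lie in [0, 1].")
  }
  for (fld in c("host_length_kb", "phage_length_kb", "vph_truth",
                "host_range_size")) {
    rng <- cfg[[fld]]
    if (length(rng) != 2L || any(is.na(rng)) || rng[2] < rng[1]) {
      abort(sprintf("`%s` must be a non-decreasing range of length 2.", fld))
    }
  }
  if (any(cfg$host_length_kb <= 0) || any(cfg$phage_length_kb <= 0)) {
    abort("Length ranges must be positive.")
  }
  if (any(cfg$vph_truth < 0)) abort("`vph_truth` must be non-negative.")
  if (cfg$host_range_size[1] < 1L) abort("`host_range_size` must be >= 1.")
  if (length(cfg$conditions) < 1L || anyDuplicated(cfg$conditions)) {
    abort("`conditions` must be a non-empty set of unique labels.")
  }
  if (cfg$noise_link_rate < 0 || cfg$intra_link_rate < 0 ||
      cfg$inter_link_efficiency < 0) {
    abort("Link rates must be non-negative.")
  }
  if (cfg$library_size_dna <= 0 || cfg$library_size_rna <= 0) {
    abort("Library sizes must be positive.")
  }
  # The whole downstream pipeline keys on within-MAG connectivity; a
  # configuration whose typical MAG cannot even produce one intra link is
  # untestable and is rejected outright.
  expected_intra <- cfg$intra_link_rate *
    exp(cfg$host_abundance[["meanlog"]]) * min(cfg$host_length_kb)^2
  if (expected_intra < 1) {
    abort(paste0(
      "Expected intra-MAG link count at median abundance is ",
      signif(expected_intra, 3),
      " (< 1): the pipeline cannot be exercised with this configuration. ",
      "Increase `intra_link_rate`, the host lengths, or the abundance scale."
    ))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d hosts, %d phages; %d replicate(s) x conditions {%s}\n",
              x$n_hosts, x$n_phages, x$n_replicates,
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  link rates: intra %.2g /kb^2, inter efficiency %.2g, noise %.2g /pair\n",
              x$intra_link_rate, x$inter_link_efficiency, x$noise_link_rate))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
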