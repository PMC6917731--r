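# Shared fixture builders for the simulation tests.

# One fully linked bi-allelic marker on a single contig.
single_marker_genome <- function(r = 0) {
  genome_spec(
    n_contigs = 1L, sites_per_contig = 1L, causal_contig = 1L,
    causal_site = 1L, informative_fraction = 1, r_causal = r
  )
}

# Genotype-level (noise-free) alternate-allele pool frequencies of one
# simulated cross at the single marker.
marker_pool_freqs <- function(design, seed, r = 0) {
  cs <- simulate_cross(
    cross_config(design, seed = seed),
    single_marker_genome(r)
  )
  c(
    alba = mean(pool_haplotypes(cs, "alba")[, 1]),
    orange = mean(pool_haplotypes(cs, "orange")[, 1])
  )
}

# Read-count-level pool allele-frequency difference at the single marker.
marker_pool_diff <- function(design, seed, depth, r = 0, seq_error = 0) {
  cfg <- cross_config(design, pool_depth_mean = depth,
    seq_error = seq_error, seed = seed)
  cs <- simulate_cross(cfg, single_marker_genome(r))
  sy <- simulate_cross_pools(cs)
  pool_diff(sy$pools$alba[1, ], sy$pools$orange[1, ])
}

# A panel with every site unlinked and the causal row removed: a pure
# null for FDR-control checks.
null_panel <- function(seed, n_contigs = 2L, sites_per_contig = 30L) {
  gs <- genome_spec(
    n_contigs = n_contigs, sites_per_contig = sites_per_contig,
    causal_contig = 1L, causal_site = 1L, r_causal = 0.5
  )
  p <- simulate_panel(gs, seed = seed)
  idx <- p$truth$causal_index
  p$sites <- p$sites[-idx, , drop = FALSE]
  p$gt <- p$gt[-idx, , drop = FALSE]
  p$dp <- p$dp[-idx, , drop = FALSE]
  p
}
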