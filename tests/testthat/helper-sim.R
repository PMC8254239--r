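# Small, fast simulation configs for unit tests.

small_config <- function(seed = 1, ...) {
  args <- list(n_individuals = 300,
               chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
               marker_spacing = 2e5,
               causal_chrom = "chr1", causal_pos = 1e6,
               pool_size_green = 30, pool_size_yellow = 30,
               mean_depth = 40, seq_error = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(f2_sim_config, args)
}

# nine-SNP triage fixture mirroring a recessive-model candidate screen:
# two heterozygous-in-mutant-bulk SNPs, six shared-upstream SNPs between a
# downregulated and an upregulated gene, one homozygous 5'-UTR SNP.
triage_fixture <- function() {
  data.frame(
    snp_id = c("C3329472G", "T3330502C",
               "G3330282C", "C3330324T", "A3330374T",
               "T3330536C", "C3330589A", "C3330981T",
               "A3330215T"),
    pos = c(3329472, 3330502, 3330282, 3330324, 3330374,
            3330536, 3330589, 3330981, 3330215),
    zygosity_y = c("het", "het", rep("hom", 7)),
    location_class = c("exonic", "five_prime_utr", rep("upstream", 6),
                       "five_prime_utr"),
    upstream_of = c("", "", rep("Ghir_D10G003980,Ghir_D10G003990", 6), ""),
    stringsAsFactors = FALSE)
}

triage_directions <- c(Ghir_D10G003980 = "down", Ghir_D10G003990 = "up")
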