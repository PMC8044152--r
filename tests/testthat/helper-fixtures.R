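# small configurations used across tests; sizes chosen for speed, not to
# mirror the default study conditions
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_samples = 2000L, n_genes = 10L, n_best_genes = 3L,
         n_pairs = 3000L, n_common_snps = 50L, variants_per_gene = 15),
    list(...)
  )
  do.call(simulation_config, args)
}

# independent full-enumeration oracle for the exact HWE test: enumerates
# every genotype configuration compatible with the observed allele counts
# and accumulates the conditional probabilities of configurations no more
# probable than the observed one
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  if (na == 0 || na == 2 * n) return(1)
  hets <- seq.int(na %% 2, min(na, 2 * n - na), by = 2)
  logw <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    AA <- n - h - aa
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
      h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[hets == n_Aa]
  sum(w[w <= obs * (1 + 1e-7)])
}

# brute-force minimum vertex cover size over all subsets (tiny graphs only):
# the smallest number of removals that eliminates every close-kin pair
min_removals_bruteforce <- function(ids, pairs) {
  for (k in 0:length(ids)) {
    subsets <- utils::combn(ids, k, simplify = FALSE)
    for (s in subsets) {
      left <- !(pairs$id1 %in% s) & !(pairs$id2 %in% s)
      if (!any(left)) return(k)
    }
  }
  length(ids)
}
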