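# Small, fast configurations used throughout the unit tests.

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_background_genes = 5L, ...)
}

# Reduced genotype panel for scan-level tests; planted effects restricted
# to SNPs that exist in the reduced panel.
small_geno_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_background_genes = 5L, n_snps = 60L,
    ld_block_size = 10L,
    trans_effects = tibble::tibble(snp = "snp_00015", gene = "SST",
                                   stratum = "female", beta = 1.4),
    cis_effects = tibble::tibble(snp = "snp_00005", gene = "XG01",
                                 stratum = "female", beta = 1.4),
    ...
  )
}

# A minimal hand-built study object for adjust_covariates tests.
toy_study <- function(y, covariates, declared, gene = "G1") {
  expr <- matrix(y, nrow = 1,
                 dimnames = list(gene, covariates$subject))
  list(expression = expr, covariates = covariates,
       declared_covariates = declared)
}

# Build a gene_network object directly from an edge tibble (for graph
# logic tests that need exact control over topology).
manual_network <- function(nodes, edges, threshold = 0.5) {
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         cor_matrix = NULL),
    class = "gene_network"
  )
}
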