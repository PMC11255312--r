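# Shared fixtures, all built in code.

# tiny hand-checkable dataset: 2 samples, 3 taxa, 4 genes
make_minimal_dataset <- function() {
  catalog <- ht_catalog(
    pathways = data.frame(
      gene_id = c("K00001", "K00002", "K90001", "GH1"),
      level1 = "Metabolism",
      level2 = "Metabolism (level 2)",
      level3 = c("Glycolysis / Gluconeogenesis", "Glycolysis / Gluconeogenesis",
                 "Energy metabolism", "Energy metabolism"),
      stringsAsFactors = FALSE),
    mechanisms = rbind(
      data.frame(mechanism_id = "Na_extrusion", category = "salt_resistance",
                 gene_id = "K90001"),
      data.frame(mechanism_id = "K_uptake", category = "salt_resistance",
                 gene_id = "K90002"),
      data.frame(mechanism_id = "osmotic_solute", category = "salt_resistance",
                 gene_id = "K90003"),
      data.frame(mechanism_id = paste0("cfix", 1:7), category = "c_fixation",
                 gene_id = paste0("K8000", 1:7)),
      data.frame(mechanism_id = c("GH", "GT", "PL", "CE", "AA", "CBM"),
                 category = "cazyme",
                 gene_id = c("GH1", "GT1", "PL1", "CE1", "AA1", "CBM1"))))
  samples <- data.frame(sample_id = c("S1", "S2"), ec = c(0.5, 9.8),
                        stringsAsFactors = FALSE)
  taxa <- data.frame(taxon_id = c("T1", "T2", "T3"),
                     domain = c("bacteria", "bacteria", "archaea"),
                     phylum = c("Proteobacteria", "Chloroflexi", "Euryarchaeota"),
                     genus = c("Halomonas", "Bacillus", NA),
                     genome_size_mb = c(3.2, 4.8, NA),
                     stringsAsFactors = FALSE)
  ab <- matrix(c(10, 40, 25, 5, 0, 80), 3, 2, byrow = TRUE,
               dimnames = list(taxa$taxon_id, samples$sample_id))
  genes <- data.frame(
    taxon_id = c("T1", "T1", "T2", "T3"),
    gene_id = c("K00001", "K90001", "K00002", "GH1"),
    sample_id = c("S1", "S2", "S1", "S2"),
    abundance = c(20, 80, 50, 160),
    stringsAsFactors = FALSE)
  refs <- list(salt_tolerant_genera = c("Halo", "Vibrio"),
               reference_genomes = list(Euryarchaeota = c(2.1, 2.5, 2.9)))
  ht_dataset(samples, taxa, ab, genes, catalog, refs)
}

# small noiseless synthetic world (exact planted values recoverable)
noiseless_config <- function(seed = 42L, ...) {
  synth_config(
    counts = list(
      bacteria = c(linear_pos = 10L, linear_neg = 10L, threshold_pos = 0L,
                   threshold_neg = 0L, null = 10L),
      archaea = c(linear_pos = 0L, linear_neg = 0L, threshold_pos = 10L,
                  threshold_neg = 10L, null = 5L)),
    abundance_noise = "none", gene_noise_sdlog = 0, seed = seed, ...)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
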