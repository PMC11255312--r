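test_that("NACG reproduces the normalization arithmetic", {
  ds <- make_minimal_dataset()
  # one sample, member genes [2,3,5], taxon abundance 2 -> NACG 5
  samples <- data.frame(sample_id = "S1", ec = 1)
  taxa <- data.frame(taxon_id = "T1", domain = "bacteria", phylum = "P",
                     genus = NA, genome_size_mb = 3)
  ab <- matrix(2, 1, 1, dimnames = list("T1", "S1"))
  genes <- data.frame(taxon_id = "T1", gene_id = c("K00001", "K00002", "K90001"),
                      sample_id = "S1", abundance = c(2, 3, 5))
  one <- ht_dataset(samples, taxa, ab, genes, ds$catalog)
  expect_equal(nacg(one, "T1", "overall_KO")$nacg, 5)
  # all member genes absent -> 0
  expect_equal(nacg(one, "T1", "cazyme")$nacg, 0)
  # salt_resistance members: only K90001 -> 5/2
  expect_equal(nacg(one, "T1", "salt_resistance")$nacg, 2.5)
  # zero-abundance taxon -> missing with warning, never an error
  ab0 <- matrix(0, 1, 1, dimnames = list("T1", "S1"))
  zero <- ht_dataset(samples, taxa, ab0, genes[0, ], ds$catalog)
  expect_warning(v <- nacg(zero, "T1", "overall_KO"), "zero total abundance")
  expect_true(is.na(v$nacg))
})

test_that("per-sample scope excludes zero-abundance samples", {
  ds <- make_minimal_dataset()
  v <- nacg(ds, "T3", "overall_KO", scope = "per_sample")
  expect_true(is.na(v$nacg[v$sample_id == "S1"]))   # T3 absent from S1
  expect_equal(v$nacg[v$sample_id == "S2"], 160 / 80)
})

test_that("Eq-1 style scale invariance and additivity hold", {
  gen <- generate_dataset(noiseless_config(seed = 2))
  ds <- gen$dataset
  tx <- rownames(ds$abundance)[5]
  base <- nacg(ds, tx, "overall_KO")$nacg
  # jointly scaling the taxon's abundance and its gene abundances
  ab2 <- ds$abundance; ab2[tx, ] <- ab2[tx, ] * 41.3
  g2 <- ds$genes
  g2$abundance[g2$taxon_id == tx] <- g2$abundance[g2$taxon_id == tx] * 41.3
  ds2 <- ht_dataset(ds$samples, ds$taxa, ab2, g2, ds$catalog, ds$refs)
  expect_equal(nacg(ds2, tx, "overall_KO")$nacg, base, tolerance = 1e-12)
  # additivity over disjoint gene sets: c_fixation and cazyme members are
  # disjoint and their union is total_c_acquisition
  expect_equal(nacg(ds, tx, "c_fixation")$nacg + nacg(ds, tx, "cazyme")$nacg,
               nacg(ds, tx, "total_c_acquisition")$nacg, tolerance = 1e-12)
})

test_that("noiseless planted copy numbers are recovered exactly", {
  gen <- generate_dataset(noiseless_config(seed = 23))
  ds <- gen$dataset
  cp <- gen$truth$copies
  for (tx in sample(rownames(ds$abundance), 8)) {
    planted <- sum(cp$copies[cp$taxon_id == tx])
    expect_equal(nacg(ds, tx, "overall_KO")$nacg, planted, tolerance = 1e-9,
                 label = paste("overall copies of", tx))
    cacq <- category_genes(ds$catalog, "total_c_acquisition")
    planted_cacq <- sum(cp$copies[cp$taxon_id == tx & cp$gene_id %in% cacq])
    expect_equal(nacg(ds, tx, "total_c_acquisition")$nacg, planted_cacq,
                 tolerance = 1e-9)
  }
})

test_that("pathway aggregation partitions or double-counts as declared", {
  gen <- generate_dataset(noiseless_config(seed = 3))
  ds <- gen$dataset
  tx <- rownames(ds$abundance)[1]
  pa <- quiet(pathway_abundance(ds, tx, level = 3))
  # default catalog maps each gene to exactly one level-3 pathway:
  # pathway NACGs sum to the overall NACG
  expect_equal(sum(pa$nacg), nacg(ds, tx, "overall_KO")$nacg, tolerance = 1e-9)
  # a gene mapped to two pathways appears in both rows
  pw <- ds$catalog$pathways
  extra <- pw[pw$gene_id == "K00001", ][1, ]
  extra$level3 <- "Second home"
  cat2 <- ht_catalog(rbind(pw, extra), ds$catalog$mechanisms)
  ds2 <- ht_dataset(ds$samples, ds$taxa, ds$abundance, ds$genes, cat2, ds$refs)
  carrier <- unique(ds$genes$taxon_id[ds$genes$gene_id == "K00001"])[1]
  pa2 <- quiet(pathway_abundance(ds2, carrier, level = 3))
  orig <- quiet(pathway_abundance(ds, carrier, level = 3))
  expect_gt(pa2$nacg[pa2$pathway == "Second home"], 0)
  expect_equal(pa2$nacg[pa2$pathway == "Glycolysis / Gluconeogenesis"],
               orig$nacg[orig$pathway == "Glycolysis / Gluconeogenesis"],
               tolerance = 1e-12)
  expect_error(pathway_abundance(ds, tx, level = 2), "level must be 1 or 3")
})

test_that("investment fraction is a pure gene-abundance ratio", {
  ds <- make_minimal_dataset()
  # T3 carries only a CAZyme gene -> fraction 1
  expect_equal(c_acquisition_fraction(ds, "T3")$fraction, 1)
  # T2 carries only a background KO -> fraction 0
  expect_equal(c_acquisition_fraction(ds, "T2")$fraction, 0)
  # invariant to the taxon's own abundance
  gen <- generate_dataset(noiseless_config(seed = 6))
  d <- gen$dataset
  tx <- rownames(d$abundance)[2]
  base <- c_acquisition_fraction(d, tx)$fraction
  ab2 <- d$abundance; ab2[tx, ] <- ab2[tx, ] * 9
  d2 <- ht_dataset(d$samples, d$taxa, ab2, d$genes, d$catalog, d$refs)
  expect_equal(c_acquisition_fraction(d2, tx)$fraction, base, tolerance = 1e-12)
  # noiseless planted fraction is exact
  want <- gen$truth$c_acq_fraction[[
    gen$truth$taxa$group[gen$truth$taxa$taxon_id == tx]]]
  expect_equal(base, unname(want), tolerance = 1e-9)
})

test_that("planted group C-acquisition fractions recovered under default noise", {
  gen <- generate_dataset(synth_config(seed = 17))
  ds <- gen$dataset
  tr <- gen$truth$taxa
  for (g in c("pos_arch", "neg_arch")) {
    ids <- tr$taxon_id[tr$group == g]
    fr <- vapply(ids, function(tx) c_acquisition_fraction(ds, tx)$fraction, 1)
    expect_equal(mean(fr), unname(gen$truth$c_acq_fraction[[g]]),
                 tolerance = 0.01, label = g)
  }
})

test_that("KO alpha diversity matches closed forms", {
  ds <- make_minimal_dataset()
  # S1 has two genes at 20 and 50
  d1 <- ko_alpha_diversity(ds, "S1")
  p <- c(20, 50) / 70
  expect_identical(d1$richness, 2L)
  expect_equal(d1$shannon, -sum(p * log(p)), tolerance = 1e-12)
  # equal-abundance pair gives ln 2; single gene gives 0
  samples <- data.frame(sample_id = c("A", "B"), ec = c(1, 2))
  taxa <- data.frame(taxon_id = "T1", domain = "bacteria", phylum = "P",
                     genus = NA, genome_size_mb = 1)
  ab <- matrix(1, 1, 2, dimnames = list("T1", c("A", "B")))
  genes <- data.frame(taxon_id = "T1", gene_id = c("K00001", "K00002", "K00001"),
                      sample_id = c("A", "A", "B"), abundance = c(3, 3, 9))
  d <- ht_dataset(samples, taxa, ab, genes, ds$catalog)
  expect_equal(ko_alpha_diversity(d, "A")$shannon, log(2), tolerance = 1e-12)
  expect_equal(ko_alpha_diversity(d, "B")$shannon, 0)
  # random vector against independent hand computation
  set.seed(9)
  v <- rexp(25)
  genes_r <- data.frame(taxon_id = "T1", gene_id = sprintf("K%05d", 1:25),
                        sample_id = "A", abundance = v)
  dr <- ht_dataset(samples, taxa, ab, genes_r, ds$catalog)
  pr <- v / sum(v)
  expect_equal(ko_alpha_diversity(dr, "A")$shannon, -sum(pr * log(pr)),
               tolerance = 1e-12)
  expect_error(ko_alpha_diversity(ds, "nope"), "unknown sample")
})

test_that("row z-scoring handles regular and degenerate rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  set.seed(2)
  r <- matrix(rnorm(40), 4)
  zr <- zscore_rows(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 4), tolerance = 1e-12)
  expect_error(zscore_rows(matrix(c(1, NA, 2, 3), 2)), "finite")
})
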