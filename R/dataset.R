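#' Gradient dataset container
#'
#' Bundles the five inputs of the trait analysis: the sample table with the
#' salinity gradient (electrical conductivity, dS/m) and optional edaphic
#' covariates, the taxon metadata table, the taxon-by-sample abundance matrix,
#' the long-format (taxon, gene, sample) gene-abundance table, the function
#' catalog and the reference sets.  The constructor enforces referential
#' integrity across all components.
#'
#' @param samples data.frame with columns `sample_id`, `ec` and optional
#'   numeric covariate columns.
#' @param taxa data.frame with columns `taxon_id`, `domain`
#'   (`"bacteria"`/`"archaea"`), `phylum`, `genus` (may be `NA`),
#'   `genome_size_mb` (may be `NA`).
#' @param abundance numeric matrix, taxa in rows (rownames = taxon ids),
#'   samples in columns (colnames = sample ids); non-negative.
#' @param genes data.frame with columns `taxon_id`, `gene_id`, `sample_id`,
#'   `abundance`; (taxon, gene, sample) triples unique, abundances
#'   non-negative.
#' @param catalog an [ht_catalog()].
#' @param refs reference sets: list with `salt_tolerant_genera` (character,
#'   prefix patterns allowed) and `reference_genomes` (named list of numeric
#'   genome-size vectors, Mb, keyed by phylum).
#' @return An object of class `ht_dataset`.
#' @export
ht_dataset <- function(samples, taxa, abundance, genes, catalog,
                       refs = list(salt_tolerant_genera = character(),
                                   reference_genomes = list())) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "ec") %in% names(samples)))
    stop("format error in samples: need columns sample_id, ec")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(samples$ec)) || any(samples$ec < 0))
    stop("ec must be finite and >= 0")
  need_t <- c("taxon_id", "domain", "phylum", "genus", "genome_size_mb")
  if (!all(need_t %in% names(taxa)))
    stop("format error in taxa: need columns ", paste(need_t, collapse = ", "))
  if (anyDuplicated(taxa$taxon_id)) stop("duplicate taxon ids")
  if (!all(taxa$domain %in% c("bacteria", "archaea")))
    stop("domain must be 'bacteria' or 'archaea'")
  gs <- taxa$genome_size_mb
  if (any(!is.na(gs) & gs <= 0)) stop("genome_size_mb must be > 0 when present")
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs taxon rownames and sample colnames")
  if (!setequal(rownames(abundance), taxa$taxon_id) ||
      nrow(abundance) != nrow(taxa))
    stop("abundance rows must match taxa table ids")
  if (!setequal(colnames(abundance), samples$sample_id) ||
      ncol(abundance) != nrow(samples))
    stop("abundance columns must match sample table ids")
  if (any(abundance < 0)) stop("abundance values must be >= 0")
  abundance <- abundance[taxa$taxon_id, samples$sample_id, drop = FALSE]
  need_g <- c("taxon_id", "gene_id", "sample_id", "abundance")
  if (!all(need_g %in% names(genes)))
    stop("format error in gene table: need columns ", paste(need_g, collapse = ", "))
  if (any(genes$abundance < 0)) stop("gene abundances must be >= 0")
  bad_t <- setdiff(unique(genes$taxon_id), taxa$taxon_id)
  if (length(bad_t))
    stop("referential-integrity error: gene table references unknown taxa: ",
         paste(bad_t, collapse = ", "))
  bad_s <- setdiff(unique(genes$sample_id), samples$sample_id)
  if (length(bad_s))
    stop("referential-integrity error: gene table references unknown samples: ",
         paste(bad_s, collapse = ", "))
  if (anyDuplicated(genes[c("taxon_id", "gene_id", "sample_id")]))
    stop("duplicate (taxon, gene, sample) triples in gene table")
  if (!inherits(catalog, "ht_catalog")) stop("catalog must be an ht_catalog")
  structure(list(samples = samples, taxa = taxa, abundance = abundance,
                 genes = genes, catalog = catalog, refs = refs),
            class = "ht_dataset")
}

#' Per-taxon total abundance (row sums across all samples)
#' @param dataset an [ht_dataset()]
#' @return named numeric vector
#' @export
total_abundance <- function(dataset) rowSums(dataset$abundance)

#' Non-destructive dataset validation report
#'
#' Lists taxa lacking a genome size, genes absent from the catalog, and
#' samples lacking an EC value.  Reporting only; never mutates or fails.
#'
#' @param dataset an [ht_dataset()]
#' @return list with `taxa_missing_genome_size`, `uncatalogued_genes`,
#'   `samples_missing_ec`, and `counts` (taxa/samples/genes totals).
#' @export
validate_dataset <- function(dataset) {
  known <- catalog_genes(dataset$catalog)
  list(
    taxa_missing_genome_size =
      dataset$taxa$taxon_id[is.na(dataset$taxa$genome_size_mb)],
    uncatalogued_genes = sort(setdiff(unique(dataset$genes$gene_id), known)),
    samples_missing_ec = dataset$samples$sample_id[is.na(dataset$samples$ec)],
    counts = c(taxa = nrow(dataset$taxa), samples = nrow(dataset$samples),
               genes = length(unique(dataset$genes$gene_id)),
               gene_records = nrow(dataset$genes))
  )
}

#' Read / write a dataset directory
#'
#' The on-disk layout is plain text: `samples.tsv`, `taxa.tsv`,
#' `abundance.tsv` (taxon_id + one column per sample), `gene_abundance.tsv`
#' (long format), `catalog.json`, `references.json`.
#'
#' @param dir directory path
#' @return [read_dataset()] returns an [ht_dataset()]; [write_dataset()]
#'   returns `dir` invisibly.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("samples.tsv", "taxa.tsv", "abundance.tsv", "gene_abundance.tsv",
              "catalog.json"))
    if (!file.exists(p(f))) stop("missing dataset file: ", p(f))
  samples <- as.data.frame(data.table::fread(p("samples.tsv"), sep = "\t"))
  taxa <- as.data.frame(data.table::fread(p("taxa.tsv"), sep = "\t",
                                          na.strings = c("NA", "")))
  taxa$genus <- as.character(taxa$genus)
  ab <- as.data.frame(data.table::fread(p("abundance.tsv"), sep = "\t"))
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$taxon_id
  genes <- as.data.frame(data.table::fread(p("gene_abundance.tsv"), sep = "\t"))
  catalog <- read_catalog(p("catalog.json"))
  refs <- if (file.exists(p("references.json"))) read_references(p("references.json"))
          else list(salt_tolerant_genera = character(), reference_genomes = list())
  ds <- ht_dataset(samples, taxa, m, genes, catalog, refs)
  message(sprintf("loaded dataset: %d taxa, %d samples, %d genes, %d gene records",
                  nrow(ds$taxa), nrow(ds$samples),
                  length(unique(ds$genes$gene_id)), nrow(ds$genes)))
  ds
}

#' @rdname read_dataset
#' @param dataset an [ht_dataset()]
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  fw <- function(x, f) data.table::fwrite(x, p(f), sep = "\t", na = "NA",
                                          quote = FALSE)
  fw(dataset$samples, "samples.tsv")
  fw(dataset$taxa, "taxa.tsv")
  ab <- data.frame(taxon_id = rownames(dataset$abundance),
                   dataset$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fw(ab, "abundance.tsv")
  fw(dataset$genes, "gene_abundance.tsv")
  write_catalog(dataset$catalog, p("catalog.json"))
  write_references(dataset$refs, p("references.json"))
  invisible(dir)
}

#' Read / write reference sets (salt-tolerant genera, phylum genome sizes)
#' @param path file path
#' @export
read_references <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  list(salt_tolerant_genera = as.character(doc$salt_tolerant_genera),
       reference_genomes = lapply(doc$reference_genomes, as.numeric))
}

#' @rdname read_references
#' @param refs reference-set list
#' @export
write_references <- function(refs, path) {
  jsonlite::write_json(refs, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.ht_dataset <- function(x, ...) {
  cat("ht_dataset:", nrow(x$taxa), "taxa x", nrow(x$samples), "samples;",
      nrow(x$genes), "gene-abundance records;",
      "EC range", paste(signif(range(x$samples$ec), 4), collapse = "-"), "dS/m\n")
  invisible(x)
}
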