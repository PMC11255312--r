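# Per-taxon functional-trait normalization.
#
# Scaffold-based gene abundances scale with the abundance of the taxon that
# carries them, so raw gene abundances confound gene content with taxon
# abundance.  The normalized abundance of category genes (NACG) removes that
# coupling: for taxon i and a gene category with members j = 1..n,
#   NACG_i = sum_j sum_s ACG_ijs / sum_s AT_is
# (pooled scope), or the same ratio within a single sample (per-sample
# scope).  Samples where the taxon has zero abundance are excluded from the
# pooled sums and yield a missing per-sample value.

# taxon abundance row as a named vector (single-column matrices drop names)
.taxon_row <- function(dataset, taxon) {
  stats::setNames(dataset$abundance[taxon, ], colnames(dataset$abundance))
}

# pooled (per taxon x gene) abundance, restricted to samples with AT > 0
.pooled_genes <- function(dataset, taxon) {
  g <- dataset$genes[dataset$genes$taxon_id == taxon, , drop = FALSE]
  at <- .taxon_row(dataset, taxon)
  ok <- names(at)[at > 0]
  g <- g[g$sample_id %in% ok, , drop = FALSE]
  tapply(g$abundance, g$gene_id, sum)
}

#' Normalized abundance of category genes (NACG) for one taxon
#'
#' @param dataset an [ht_dataset()]
#' @param taxon taxon id
#' @param category trait category resolvable by [category_genes()]
#'   (`"overall_KO"`, `"salt_resistance"`, `"c_fixation"`, `"cazyme"`,
#'   `"total_c_acquisition"`, or a pathway label)
#' @param scope `"pooled"` (sum over samples before dividing; default) or
#'   `"per_sample"`
#' @return data.frame with `taxon_id`, `category`, `scope`, `sample_id` (`NA`
#'   for pooled scope) and `nacg`.  A taxon with zero total abundance yields
#'   `NA` with a warning, never a division error.
#' @export
nacg <- function(dataset, taxon, category, scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  if (!taxon %in% rownames(dataset$abundance)) stop("unknown taxon: ", taxon)
  members <- category_genes(dataset$catalog, category)
  at <- .taxon_row(dataset, taxon)
  g <- dataset$genes[dataset$genes$taxon_id == taxon &
                       dataset$genes$gene_id %in% members, , drop = FALSE]
  if (scope == "pooled") {
    denom <- sum(at[at > 0])
    if (denom == 0) {
      warning("taxon ", taxon, " has zero total abundance; NACG is missing")
      val <- NA_real_
    } else {
      val <- sum(g$abundance[g$sample_id %in% names(at)[at > 0]]) / denom
    }
    return(data.frame(taxon_id = taxon, category = category, scope = "pooled",
                      sample_id = NA_character_, nacg = val,
                      stringsAsFactors = FALSE))
  }
  num <- tapply(g$abundance, factor(g$sample_id, levels = names(at)), sum,
                default = 0)
  val <- ifelse(at > 0, num / at, NA_real_)
  data.frame(taxon_id = taxon, category = category, scope = "per_sample",
             sample_id = names(at), nacg = as.numeric(val),
             stringsAsFactors = FALSE)
}

#' Pooled NACG for every taxon and several categories at once
#'
#' Vectorized companion of [nacg()] used by the pipeline stages.
#'
#' @param dataset an [ht_dataset()]
#' @param taxa_ids taxa to include (default all)
#' @param categories character vector of categories
#' @return matrix, taxa x categories, of pooled NACG values
#' @export
nacg_matrix <- function(dataset, taxa_ids = rownames(dataset$abundance),
                        categories = c("overall_KO", "salt_resistance",
                                       "c_fixation", "cazyme",
                                       "total_c_acquisition")) {
  gd <- data.table::as.data.table(dataset$genes)
  at <- dataset$abundance
  atl <- data.table::data.table(taxon_id = rep(rownames(at), ncol(at)),
                                sample_id = rep(colnames(at), each = nrow(at)),
                                at = as.vector(at))
  gd <- gd[atl[at > 0], on = c("taxon_id", "sample_id"), nomatch = 0L]
  denom <- rowSums(at)[taxa_ids]
  out <- matrix(NA_real_, length(taxa_ids), length(categories),
                dimnames = list(taxa_ids, categories))
  for (cat in categories) {
    members <- category_genes(dataset$catalog, cat)
    num <- gd[gene_id %in% members, list(s = sum(abundance)), by = "taxon_id"]
    v <- numeric(length(taxa_ids)); names(v) <- taxa_ids
    v[num$taxon_id[num$taxon_id %in% taxa_ids]] <-
      num$s[num$taxon_id %in% taxa_ids]
    out[, cat] <- ifelse(denom > 0, v / denom, NA_real_)
  }
  out
}

#' Pathway-level NACG profile of one taxon
#'
#' One pooled NACG per pathway label at BRITE hierarchy level 1 or 3.  Genes
#' mapping to several pathways contribute to each of them (standard KEGG
#' multi-membership; the double-counting across pathways is deliberate).
#' Genes absent from the catalog are ignored, with their count reported in the
#' `n_uncatalogued` attribute.
#'
#' @param dataset an [ht_dataset()]
#' @param taxon taxon id
#' @param level 1 or 3
#' @return data.frame with `taxon_id`, `pathway`, `level`, `nacg`
#' @export
pathway_abundance <- function(dataset, taxon, level = 3L) {
  if (!level %in% c(1L, 3L)) stop("level must be 1 or 3")
  col <- paste0("level", level)
  labels <- sort(unique(dataset$catalog$pathways[[col]]))
  m <- pathway_nacg_matrix(dataset, taxon, level = level)
  out <- data.frame(taxon_id = taxon, pathway = colnames(m),
                    level = level, nacg = as.numeric(m[1, ]),
                    stringsAsFactors = FALSE)
  attr(out, "n_uncatalogued") <- attr(m, "n_uncatalogued")
  out
}

#' Taxa-by-pathway matrix of pooled NACG values
#'
#' @param dataset an [ht_dataset()]
#' @param taxa_ids taxa to include
#' @param level BRITE level (1 or 3)
#' @return matrix taxa x pathway labels; attribute `n_uncatalogued` counts
#'   gene records ignored because their gene id is absent from the catalog
#' @export
pathway_nacg_matrix <- function(dataset, taxa_ids = rownames(dataset$abundance),
                                level = 3L) {
  if (!level %in% c(1L, 3L)) stop("level must be 1 or 3")
  col <- paste0("level", level)
  map <- data.table::as.data.table(
    unique(dataset$catalog$pathways[c("gene_id", col)]))
  data.table::setnames(map, col, "pathway")
  gd <- data.table::as.data.table(dataset$genes)[taxon_id %in% taxa_ids]
  at <- dataset$abundance
  atl <- data.table::data.table(taxon_id = rep(rownames(at), ncol(at)),
                                sample_id = rep(colnames(at), each = nrow(at)),
                                at = as.vector(at))
  gd <- gd[atl[at > 0], on = c("taxon_id", "sample_id"), nomatch = 0L]
  n_unc <- sum(!gd$gene_id %in% map$gene_id)
  if (n_unc > 0)
    message(n_unc, " gene record(s) not in the catalog pathway map; ignored")
  gd <- map[gd, on = "gene_id", nomatch = 0L, allow.cartesian = TRUE]
  agg <- gd[, list(s = sum(abundance)), by = c("taxon_id", "pathway")]
  labels <- sort(unique(map$pathway))
  denom <- rowSums(at)[taxa_ids]
  out <- matrix(0, length(taxa_ids), length(labels),
                dimnames = list(taxa_ids, labels))
  out[cbind(match(agg$taxon_id, taxa_ids), match(agg$pathway, labels))] <- agg$s
  out <- sweep(out, 1, denom, "/")
  out[denom == 0, ] <- NA_real_
  attr(out, "n_uncatalogued") <- n_unc
  out
}

#' Per-sample pathway NACG aggregated over a set of taxa
#'
#' Group-scope normalization used for along-gradient trait trends and the
#' random-forest stage: for each sample,
#' `sum over group taxa of pathway gene abundance / sum over group taxa of
#' taxon abundance`.
#'
#' @param dataset an [ht_dataset()]
#' @param taxa_ids member taxa of the group
#' @param level BRITE level (1 or 3)
#' @return matrix samples x pathway labels
#' @export
group_pathway_sample_matrix <- function(dataset, taxa_ids, level = 3L) {
  col <- paste0("level", level)
  map <- data.table::as.data.table(
    unique(dataset$catalog$pathways[c("gene_id", col)]))
  data.table::setnames(map, col, "pathway")
  gd <- data.table::as.data.table(dataset$genes)[taxon_id %in% taxa_ids]
  gd <- map[gd, on = "gene_id", nomatch = 0L, allow.cartesian = TRUE]
  agg <- gd[, list(s = sum(abundance)), by = c("sample_id", "pathway")]
  at <- colSums(dataset$abundance[taxa_ids, , drop = FALSE])
  labels <- sort(unique(map$pathway))
  sids <- colnames(dataset$abundance)
  out <- matrix(0, length(sids), length(labels), dimnames = list(sids, labels))
  out[cbind(match(agg$sample_id, sids), match(agg$pathway, labels))] <- agg$s
  out <- sweep(out, 1, at, "/")
  out[at == 0, ] <- NA_real_
  out
}

#' Carbon-acquisition investment fraction of one taxon
#'
#' Fraction of the taxon's total catalogued gene abundance contributed by
#' C-fixation plus CAZyme genes, pooled over samples.  Being a ratio of gene
#' sums it is invariant to the taxon's own abundance.
#'
#' @param dataset an [ht_dataset()]
#' @param taxon taxon id
#' @return data.frame with `taxon_id` and `fraction` in `[0, 1]` (`NA` when
#'   the taxon has no catalogued gene abundance)
#' @export
c_acquisition_fraction <- function(dataset, taxon) {
  pooled <- .pooled_genes(dataset, taxon)
  known <- catalog_genes(dataset$catalog)
  pooled <- pooled[names(pooled) %in% known]
  tot <- sum(pooled)
  if (!length(pooled) || tot == 0)
    return(data.frame(taxon_id = taxon, fraction = NA_real_,
                      stringsAsFactors = FALSE))
  cacq <- category_genes(dataset$catalog, "total_c_acquisition")
  data.frame(taxon_id = taxon,
             fraction = sum(pooled[names(pooled) %in% cacq]) / tot,
             stringsAsFactors = FALSE)
}

#' KO alpha diversity of one sample
#'
#' Richness is the number of genes with positive summed abundance in the
#' sample; Shannon is `-sum p log p` over gene relative abundances.
#'
#' @param dataset an [ht_dataset()]
#' @param sample sample id
#' @return list with `richness` and `shannon` (`NA` when the sample carries no
#'   gene abundance)
#' @export
ko_alpha_diversity <- function(dataset, sample) {
  if (!sample %in% dataset$samples$sample_id) stop("unknown sample: ", sample)
  g <- dataset$genes[dataset$genes$sample_id == sample, , drop = FALSE]
  ab <- tapply(g$abundance, g$gene_id, sum)
  ab <- ab[ab > 0]
  if (!length(ab)) return(list(richness = 0L, shannon = NA_real_))
  p <- ab / sum(ab)
  list(richness = length(ab), shannon = -sum(p * log(p)))
}

#' Row-wise z-scoring
#'
#' Per row: subtract the mean and divide by the sample standard deviation
#' (denominator `n - 1`).  Constant rows map to all zeros.
#'
#' @param m numeric matrix (each row needs >= 2 finite values)
#' @return z-scored matrix of the same shape
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (any(rowSums(is.finite(m)) < 2L))
    stop("every row needs at least 2 finite values")
  t(apply(m, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) return(rep(0, length(r)))
    (r - mean(r)) / s
  }))
}
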