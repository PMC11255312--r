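#' Mechanism presence profile of one taxon
#'
#' A mechanism counts as present when at least `min_genes` of its member genes
#' have positive pooled abundance in the taxon.  The default `min_genes = 1`
#' with no abundance floor is the most permissive detection rule; raising
#' `min_genes` can only shrink presence sets.
#'
#' @param dataset an [ht_dataset()]
#' @param taxon taxon id
#' @param category `"salt_resistance"`, `"c_fixation"` or `"cazyme"`
#' @param min_genes minimum member genes with positive abundance (default 1)
#' @return list of class `ht_mech_profile`: `taxon_id`, `category`,
#'   `present_mechanisms` (character), `completeness` (integer),
#'   `category_size`
#' @export
mechanism_presence <- function(dataset, taxon, category, min_genes = 1L) {
  mechs <- category_mechanisms(dataset$catalog, category)
  pooled <- .pooled_genes(dataset, taxon)
  pos <- names(pooled)[pooled > 0]
  mtab <- dataset$catalog$mechanisms
  present <- vapply(mechs, function(m) {
    members <- mtab$gene_id[mtab$mechanism_id == m & mtab$category == category]
    sum(members %in% pos) >= min_genes
  }, logical(1))
  structure(list(taxon_id = taxon, category = category,
                 present_mechanisms = mechs[present],
                 completeness = sum(present),
                 category_size = length(mechs)),
            class = "ht_mech_profile")
}

#' Mechanism profiles for a set of taxa
#'
#' Vectorized companion of [mechanism_presence()].
#'
#' @param dataset an [ht_dataset()]
#' @param taxa_ids taxa to profile
#' @param category mechanism category
#' @param min_genes see [mechanism_presence()]
#' @return list of `ht_mech_profile` objects, named by taxon
#' @export
mechanism_profiles <- function(dataset, taxa_ids, category, min_genes = 1L) {
  mechs <- category_mechanisms(dataset$catalog, category)
  mtab <- dataset$catalog$mechanisms
  members <- lapply(mechs, function(m)
    mtab$gene_id[mtab$mechanism_id == m & mtab$category == category])
  gd <- data.table::as.data.table(dataset$genes)[taxon_id %in% taxa_ids]
  at <- dataset$abundance
  atl <- data.table::data.table(taxon_id = rep(rownames(at), ncol(at)),
                                sample_id = rep(colnames(at), each = nrow(at)),
                                at = as.vector(at))
  gd <- gd[atl[at > 0], on = c("taxon_id", "sample_id"), nomatch = 0L]
  pooled <- gd[, list(s = sum(abundance)), by = c("taxon_id", "gene_id")]
  pooled <- pooled[s > 0]
  out <- lapply(taxa_ids, function(tx) {
    pos <- pooled$gene_id[pooled$taxon_id == tx]
    pres <- vapply(members, function(mem) sum(mem %in% pos) >= min_genes,
                   logical(1))
    structure(list(taxon_id = tx, category = category,
                   present_mechanisms = mechs[pres],
                   completeness = sum(pres), category_size = length(mechs)),
              class = "ht_mech_profile")
  })
  names(out) <- taxa_ids
  out
}

#' Exact-subset (UpSet) intersection counts for a group of profiles
#'
#' Each taxon is assigned to exactly one subset: its exact present-mechanism
#' set, including the empty set.  Subset counts therefore sum to the group
#' size.  Per-mechanism marginal totals (taxa carrying that mechanism,
#' regardless of what else they carry) are also returned.
#'
#' @param profiles list of `ht_mech_profile` objects sharing one category
#' @return list with `subsets` (data.frame: `subset` as "+"-joined sorted
#'   mechanism ids, `"(none)"` for the empty set; `count`), `marginals`
#'   (named integer vector per mechanism) and `group_size`
#' @export
upset_counts <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  cats <- unique(vapply(profiles, `[[`, character(1), "category"))
  if (length(cats) != 1L) stop("profiles mix categories: ",
                               paste(cats, collapse = ", "))
  keys <- vapply(profiles, function(p) {
    if (!length(p$present_mechanisms)) "(none)"
    else paste(sort(p$present_mechanisms), collapse = "+")
  }, character(1))
  tab <- table(keys)
  subsets <- data.frame(subset = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  subsets <- subsets[order(-subsets$count, subsets$subset), ]
  rownames(subsets) <- NULL
  mechs <- sort(unique(unlist(lapply(profiles, `[[`, "present_mechanisms"))))
  marg <- vapply(mechs, function(m)
    sum(vapply(profiles, function(p) m %in% p$present_mechanisms, logical(1))),
    integer(1))
  list(subsets = subsets, marginals = marg, group_size = length(profiles))
}

#' Completeness histogram and all-mechanisms fraction for a group
#'
#' @param profiles list of `ht_mech_profile` objects sharing one category
#' @return list with `histogram` (named integer vector over completeness
#'   0..K), `complete_fraction` (share of taxa carrying all K mechanisms;
#'   `NA` for an empty group) and `group_size`
#' @export
completeness_distribution <- function(profiles) {
  if (!length(profiles))
    return(list(histogram = integer(), complete_fraction = NA_real_,
                group_size = 0L))
  cats <- unique(vapply(profiles, `[[`, character(1), "category"))
  if (length(cats) != 1L) stop("profiles mix categories")
  k <- profiles[[1]]$category_size
  comp <- vapply(profiles, `[[`, integer(1), "completeness")
  hist <- table(factor(comp, levels = 0:k))
  hist <- stats::setNames(as.integer(hist), names(hist))
  list(histogram = hist,
       complete_fraction = unname(hist[as.character(k)]) / length(profiles),
       group_size = length(profiles))
}

#' @export
print.ht_mech_profile <- function(x, ...) {
  cat(sprintf("%s [%s]: %d/%d mechanisms (%s)\n", x$taxon_id, x$category,
              x$completeness, x$category_size,
              if (length(x$present_mechanisms))
                paste(x$present_mechanisms, collapse = ", ") else "none"))
  invisible(x)
}
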