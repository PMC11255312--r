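#' Function catalog: gene-to-pathway and gene-to-mechanism maps
#'
#' A `ht_catalog` binds every annotated gene id (KEGG orthology `K#####` ids
#' and CAZyme family ids such as `GH13`) to (i) its BRITE pathway labels at
#' hierarchy levels 1-3 and (ii) the stress-adaptation / carbon-acquisition
#' mechanisms it belongs to.  Mechanisms come in three categories:
#' `salt_resistance` (3 mechanisms: sodium extrusion, potassium uptake,
#' osmotic-solute accumulation), `c_fixation` (the 7 inorganic carbon-fixation
#' pathways) and `cazyme` (the 6 CAZyme classes AA/CBM/CE/GH/GT/PL).
#'
#' @param pathways data.frame with columns `gene_id`, `level1`, `level2`,
#'   `level3`; a gene may appear on several rows (multi-pathway membership).
#' @param mechanisms data.frame with columns `mechanism_id`, `category`,
#'   `gene_id` (long format; one row per mechanism member gene).
#' @return An object of class `ht_catalog`.
#' @export
ht_catalog <- function(pathways, mechanisms) {
  pathways <- as.data.frame(pathways, stringsAsFactors = FALSE)
  mechanisms <- as.data.frame(mechanisms, stringsAsFactors = FALSE)
  need_p <- c("gene_id", "level1", "level2", "level3")
  need_m <- c("mechanism_id", "category", "gene_id")
  if (!all(need_p %in% names(pathways)))
    stop("catalog pathways table needs columns: ", paste(need_p, collapse = ", "))
  if (!all(need_m %in% names(mechanisms)))
    stop("catalog mechanisms table needs columns: ", paste(need_m, collapse = ", "))
  bad <- setdiff(unique(mechanisms$category), c("salt_resistance", "c_fixation", "cazyme"))
  if (length(bad))
    stop("unknown mechanism category: ", paste(bad, collapse = ", "))
  empty <- tapply(mechanisms$gene_id, mechanisms$mechanism_id, length) == 0
  if (any(empty)) stop("mechanisms with empty member sets: ",
                       paste(names(empty)[empty], collapse = ", "))
  structure(list(pathways = pathways[order(pathways$gene_id, pathways$level3), ,
                                     drop = FALSE],
                 mechanisms = mechanisms[order(mechanisms$category,
                                               mechanisms$mechanism_id,
                                               mechanisms$gene_id), , drop = FALSE]),
            class = "ht_catalog")
}

#' All gene ids known to a catalog
#' @param catalog an [ht_catalog()]
#' @return character vector of unique gene ids (pathway map plus mechanism members)
#' @export
catalog_genes <- function(catalog) {
  sort(unique(c(catalog$pathways$gene_id, catalog$mechanisms$gene_id)))
}

#' Resolve a trait category to its member gene set
#'
#' `overall_KO` means every catalogued gene; `salt_resistance`, `c_fixation`
#' and `cazyme` are the unions of their mechanisms' members;
#' `total_c_acquisition` is the union of `c_fixation` and `cazyme`; any other
#' string is interpreted as a pathway label (matched at level 1, then level 3).
#'
#' @param catalog an [ht_catalog()]
#' @param category character scalar
#' @return character vector of gene ids
#' @export
category_genes <- function(catalog, category) {
  stopifnot(is.character(category), length(category) == 1L)
  mech <- catalog$mechanisms
  if (category == "overall_KO") return(catalog_genes(catalog))
  if (category %in% c("salt_resistance", "c_fixation", "cazyme"))
    return(sort(unique(mech$gene_id[mech$category == category])))
  if (category == "total_c_acquisition")
    return(sort(unique(mech$gene_id[mech$category %in% c("c_fixation", "cazyme")])))
  pw <- catalog$pathways
  hit <- pw$gene_id[pw$level1 == category | pw$level3 == category]
  if (!length(hit))
    stop("category '", category, "' matches no mechanism category or pathway label")
  sort(unique(hit))
}

#' Mechanism ids of one category
#' @param catalog an [ht_catalog()]
#' @param category one of `"salt_resistance"`, `"c_fixation"`, `"cazyme"`
#' @return character vector of mechanism ids
#' @export
category_mechanisms <- function(catalog, category) {
  if (!category %in% c("salt_resistance", "c_fixation", "cazyme"))
    stop("unknown mechanism category: ", category)
  sort(unique(catalog$mechanisms$mechanism_id[catalog$mechanisms$category == category]))
}

# expected mechanism counts for the default catalog layout
.mech_sizes <- c(salt_resistance = 3L, c_fixation = 7L, cazyme = 6L)

#' Default function catalog with placeholder KO sets
#'
#' Builds a self-consistent catalog for simulation and testing: synthetic KO
#' ids grouped into level-3 pathways nested under four BRITE level-1 classes,
#' plus the three salt-resistance mechanisms, the seven inorganic C-fixation
#' pathways and the six CAZyme classes.  The KO membership of each mechanism
#' is a placeholder; users with real annotations supply their own catalog via
#' [read_catalog()].
#'
#' @param kos_per_pathway number of background KOs in each level-3 pathway
#' @return An [ht_catalog()].
#' @export
default_catalog <- function(kos_per_pathway = 5L) {
  level1 <- c("Metabolism", "Genetic Information Processing",
              "Environmental Information Processing", "Cellular Processes")
  l3 <- list(
    "Metabolism" = c("Glycolysis / Gluconeogenesis", "Citrate cycle (TCA cycle)",
                     "Fatty acid metabolism", "Glycine, serine and threonine metabolism",
                     "Porphyrin and chlorophyll metabolism", "Oxidative phosphorylation"),
    "Genetic Information Processing" = c("DNA replication", "Mismatch repair",
                                         "RNA polymerase", "Homologous recombination"),
    "Environmental Information Processing" = c("ABC transporters",
                                               "Two-component system"),
    "Cellular Processes" = c("Biofilm formation", "Flagellar assembly")
  )
  rows <- list()
  ko <- 0L
  for (l1 in level1) {
    for (p3 in l3[[l1]]) {
      ids <- sprintf("K%05d", ko + seq_len(kos_per_pathway))
      ko <- ko + kos_per_pathway
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ids, level1 = l1, level2 = paste(l1, "(level 2)"),
        level3 = p3, stringsAsFactors = FALSE)
    }
  }
  # mechanism member genes: KOs for salt resistance and C fixation,
  # CAZyme family ids for carbon degradation
  mk <- function(mechanism, category, ids)
    data.frame(mechanism_id = mechanism, category = category, gene_id = ids,
               stringsAsFactors = FALSE)
  salt <- list(
    Na_extrusion   = sprintf("K9%04d", 1:4),   # Na+/H+ antiporters
    K_uptake       = sprintf("K9%04d", 11:14), # K+ transport / K+/H+ antiporter
    osmotic_solute = sprintf("K9%04d", 21:24)  # compatible-solute uptake/synthesis
  )
  cfix_names <- c("Calvin cycle", "Arnon-Buchanan cycle",
                  "3-Hydroxypropionate bi-cycle",
                  "Hydroxypropionate-hydroxybutylate cycle",
                  "Dicarboxylate-hydroxybutyrate cycle",
                  "Wood-Ljungdahl pathway",
                  "Incomplete reductive citrate cycle")
  cfix <- lapply(seq_along(cfix_names), function(i) sprintf("K8%04d", (i - 1L) * 3L + 1:3))
  names(cfix) <- cfix_names
  caz <- list(AA = paste0("AA", 1:3), CBM = paste0("CBM", 1:3), CE = paste0("CE", 1:3),
              GH = paste0("GH", 1:3), GT = paste0("GT", 1:3), PL = paste0("PL", 1:3))
  mech <- rbind(
    do.call(rbind, Map(mk, names(salt), "salt_resistance", salt)),
    do.call(rbind, Map(mk, names(cfix), "c_fixation", cfix)),
    do.call(rbind, Map(mk, names(caz), "cazyme", caz))
  )
  # mechanism KOs / CAZyme families also carry pathway labels so that
  # overall_KO aggregation covers them
  mech_pw <- data.frame(
    gene_id = unique(mech$gene_id),
    level1 = "Metabolism", level2 = "Metabolism (level 2)",
    level3 = "Energy metabolism", stringsAsFactors = FALSE)
  ht_catalog(rbind(do.call(rbind, rows), mech_pw), mech)
}

#' Read / write a catalog as JSON
#'
#' The JSON layout is user-editable: a `pathways` array of
#' `{gene_id, level1, level2, level3}` records and a `mechanisms` array of
#' `{mechanism_id, category, genes: [...]}` records.
#' @param path file path
#' @return [read_catalog()] returns an [ht_catalog()]; [write_catalog()]
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  mech <- do.call(rbind, lapply(seq_len(nrow(doc$mechanisms)), function(i)
    data.frame(mechanism_id = doc$mechanisms$mechanism_id[i],
               category = doc$mechanisms$category[i],
               gene_id = unlist(doc$mechanisms$genes[i]),
               stringsAsFactors = FALSE)))
  ht_catalog(doc$pathways, mech)
}

#' @rdname read_catalog
#' @param catalog an [ht_catalog()]
#' @export
write_catalog <- function(catalog, path) {
  mech_ids <- unique(catalog$mechanisms[c("mechanism_id", "category")])
  genes <- lapply(mech_ids$mechanism_id, function(m)
    catalog$mechanisms$gene_id[catalog$mechanisms$mechanism_id == m])
  doc <- list(pathways = catalog$pathways,
              mechanisms = data.frame(mech_ids, stringsAsFactors = FALSE))
  doc$mechanisms$genes <- genes
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.ht_catalog <- function(x, ...) {
  tab <- table(unique(x$mechanisms[c("mechanism_id", "category")])$category)
  cat("ht_catalog:", length(catalog_genes(x)), "genes,",
      length(unique(x$pathways$level3)), "level-3 pathways; mechanisms:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
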