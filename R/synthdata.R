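#' Configuration for the synthetic gradient-dataset generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' 37-sample electrical-conductivity gradient spanning 0.14-13.65 dS/m,
#' bacterial taxa responding (mostly) linearly to salinity, archaeal taxa with
#' thresholded (breakpoint) responses at 4.2 dS/m (positive responders) and
#' 3.4 dS/m (negative responders), negative-binomial abundance noise, a gene
#' layer coupled multiplicatively to taxon abundance, clade-structured
#' lognormal genome sizes, planted mechanism-completeness fractions and
#' planted carbon-acquisition investment fractions.  All planted values have
#' documented defaults; see the methods vignette for their provenance.
#'
#' @param n_samples number of gradient samples (default 37)
#' @param ec_range min/max electrical conductivity, dS/m (default 0.14-13.65)
#' @param ec optional explicit EC vector (overrides `n_samples`/`ec_range`)
#' @param counts per-domain taxon counts by response class; named list
#'   `bacteria`/`archaea`, each a named vector over classes
#'   `linear_pos`, `linear_neg`, `threshold_pos`, `threshold_neg`, `null`
#' @param class_params per-class mean-response parameters: `intercept` and
#'   `slope` ranges (uniform draw per taxon) and breakpoint `psi` (dS/m) for
#'   threshold classes
#' @param abundance_noise `"nb"` (negative binomial around the class mean) or
#'   `"none"` (observed abundance equals the mean exactly)
#' @param nb_size negative-binomial size (dispersion) parameter; larger is
#'   less overdispersed
#' @param gene_noise_sdlog sdlog of mean-one lognormal multiplicative noise on
#'   the gene layer; 0 disables it
#' @param genome_meanlog,genome_sdlog per-group lognormal genome-size
#'   parameters (Mb scale), named over
#'   `pos_bac`, `neg_bac`, `pos_arch`, `neg_arch`, `null_bac`, `null_arch`
#' @param genome_missing_frac fraction of taxa whose genome size is withheld
#' @param completeness per-category, per-group fraction of taxa planted with
#'   the complete mechanism set (list over `salt_resistance`, `c_fixation`,
#'   `cazyme`, each named over the six groups)
#' @param incomplete_presence_prob per-mechanism presence probability for taxa
#'   not planted complete
#' @param c_acq_fraction per-group planted carbon-acquisition investment
#'   fraction (C-fixation + CAZyme gene abundance over all catalogued genes)
#' @param background_gene_prob probability a taxon carries each background
#'   (non-mechanism) KO
#' @param mech_gene_prob probability each member gene of a present mechanism is
#'   carried (at least one is forced)
#' @param copy_range integer range of base per-gene copy numbers
#' @param ref_genus_frac per-group fraction of genus-identified taxa assigned a
#'   genus matching the packaged salt-tolerant reference patterns
#' @param genus_missing_frac fraction of taxa left unidentified at genus level
#' @param seed RNG seed used by [generate_dataset()]
#' @return list of class `ht_synth_config`
#' @export
synth_config <- function(
    n_samples = 37L,
    ec_range = c(0.14, 13.65),
    ec = NULL,
    counts = list(
      bacteria = c(linear_pos = 60L, linear_neg = 60L, threshold_pos = 0L,
                   threshold_neg = 0L, null = 60L),
      archaea  = c(linear_pos = 0L, linear_neg = 0L, threshold_pos = 50L,
                   threshold_neg = 50L, null = 10L)),
    class_params = list(
      # slope ranges keep the mean non-negative across the full EC range, so
      # the planted (piecewise-)linear response is well-specified everywhere
      # (the floor at zero remains as a guard, not as a routine regime)
      linear_pos    = list(intercept = c(10, 30),   slope = c(4, 10)),
      linear_neg    = list(intercept = c(120, 160), slope = c(-8.5, -6)),
      threshold_pos = list(intercept = c(10, 30),   slope = c(8, 16),  psi = 4.2),
      threshold_neg = list(intercept = c(125, 155), slope = c(-12, -10), psi = 3.4),
      null          = list(intercept = c(30, 80),   slope = c(0, 0))),
    abundance_noise = c("nb", "none"),
    nb_size = 100,
    gene_noise_sdlog = 0.2,
    genome_meanlog = log(c(pos_bac = 3.0, neg_bac = 4.5, pos_arch = 3.74,
                           neg_arch = 1.60, null_bac = 4.0, null_arch = 1.5)),
    genome_sdlog = c(pos_bac = 0.25, neg_bac = 0.25, pos_arch = 0.25,
                     neg_arch = 0.2, null_bac = 0.3, null_arch = 0.25),
    genome_missing_frac = 0.02,
    completeness = list(
      salt_resistance = c(pos_bac = 0.30, neg_bac = 0.60, pos_arch = 0.76,
                          neg_arch = 0.20, null_bac = 0.25, null_arch = 0.25),
      c_fixation      = c(pos_bac = 0.345, neg_bac = 0.815, pos_arch = 0.68,
                          neg_arch = 0.22, null_bac = 0.40, null_arch = 0.40),
      cazyme          = c(pos_bac = 0.43, neg_bac = 0.695, pos_arch = 0.70,
                          neg_arch = 0.12, null_bac = 0.40, null_arch = 0.40)),
    incomplete_presence_prob = 0.5,
    c_acq_fraction = c(pos_bac = 0.1349, neg_bac = 0.1243, pos_arch = 0.2437,
                       neg_arch = 0.1265, null_bac = 0.12, null_arch = 0.12),
    background_gene_prob = 0.6,
    mech_gene_prob = 0.8,
    copy_range = c(1L, 5L),
    ref_genus_frac = c(pos_bac = 0.618, neg_bac = 0, pos_arch = 1,
                       neg_arch = 0, null_bac = 0, null_arch = 0),
    genus_missing_frac = 0.138,
    seed = 1L) {
  abundance_noise <- match.arg(abundance_noise)
  # normalize counts (configs may arrive as named lists, e.g. from YAML);
  # absent classes default to zero
  classes <- c("linear_pos", "linear_neg", "threshold_pos", "threshold_neg", "null")
  counts <- lapply(counts, function(v) {
    v <- unlist(v)
    if (is.null(names(v)) || !all(names(v) %in% classes))
      stop("counts must be named by response class: ",
           paste(classes, collapse = ", "))
    full <- stats::setNames(integer(length(classes)), classes)
    full[names(v)] <- as.integer(v)
    full
  })
  stopifnot(length(ec_range) == 2L, ec_range[1] < ec_range[2],
            nb_size > 0, gene_noise_sdlog >= 0,
            all(unlist(counts) >= 0),
            all(unlist(completeness) >= 0), all(unlist(completeness) <= 1),
            all(c_acq_fraction >= 0), all(c_acq_fraction < 1),
            copy_range[1] >= 1, copy_range[2] >= copy_range[1])
  structure(as.list(environment()), class = "ht_synth_config")
}

#' Class mean-abundance function of the generator
#'
#' Linear classes follow `a + b * ec`; threshold classes are flat at `a` up to
#' the breakpoint `psi` and linear with slope `b` beyond it (continuous at
#' `psi`); `null` is constant at `a`.  The result is floored at zero.
#'
#' @param ec numeric EC value(s), dS/m
#' @param class one of `linear_pos`, `linear_neg`, `threshold_pos`,
#'   `threshold_neg`, `null`
#' @param params list with `intercept` (a), `slope` (b) and, for threshold
#'   classes, `psi`
#' @return numeric mean abundance, same length as `ec`
#' @export
class_mean <- function(ec, class, params) {
  a <- params$intercept[1]
  b <- params$slope[1]
  mu <- switch(class,
    linear_pos = ,
    linear_neg = a + b * ec,
    threshold_pos = ,
    threshold_neg = a + b * pmax(0, ec - params$psi),
    null = rep(a, length(ec)),
    stop("unknown response class: ", class))
  pmax(0, mu)
}

.group_of <- function(class, domain) {
  dir <- c(linear_pos = "pos", threshold_pos = "pos",
           linear_neg = "neg", threshold_neg = "neg", null = "null")[class]
  paste0(dir, "_", ifelse(domain == "bacteria", "bac", "arch"))
}

# deterministic "round(frac * n)" head-count used for exactly-planted fractions
.planted_count <- function(frac, n) as.integer(round(frac * n))

#' Generate a synthetic gradient dataset with planted ground truth
#'
#' @param config an [synth_config()]
#' @return list with `dataset` (an [ht_dataset()]) and `truth`, a list of
#'   class `ht_ground_truth` holding `taxa` (true class, slope, breakpoint,
#'   genome group, planted C-acquisition fraction, reference-genus flag),
#'   `copies` (true per-gene copy numbers) and `mechanisms` (planted presence
#'   by taxon, category and mechanism).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "ht_synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  catalog <- default_catalog()

  ec <- if (!is.null(config$ec)) sort(as.numeric(config$ec)) else
    sort(stats::runif(config$n_samples, config$ec_range[1], config$ec_range[2]))
  n_s <- length(ec)
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  samples <- data.frame(sample_id = sample_ids, ec = ec,
                        # two edaphic covariates: one EC-coupled (soil moisture
                        # proxy), one independent (pH)
                        moisture = 20 + 1.5 * ec + stats::rnorm(n_s, 0, 2),
                        ph = stats::rnorm(n_s, 8, 0.3),
                        stringsAsFactors = FALSE)

  # ---- taxon frame with planted classes -----------------------------------
  tax_list <- list()
  for (dom in c("bacteria", "archaea")) {
    cnt <- config$counts[[dom]]
    for (cls in names(cnt)) {
      if (cnt[[cls]] > 0L)
        tax_list[[length(tax_list) + 1L]] <- data.frame(
          domain = dom, class = cls, stringsAsFactors = FALSE)[rep(1, cnt[[cls]]), ]
    }
  }
  taxa <- do.call(rbind, tax_list)
  rownames(taxa) <- NULL
  taxa$taxon_id <- NA_character_
  ib <- which(taxa$domain == "bacteria"); ia <- which(taxa$domain == "archaea")
  taxa$taxon_id[ib] <- sprintf("B%04d", seq_along(ib))
  taxa$taxon_id[ia] <- sprintf("A%04d", seq_along(ia))
  taxa$group <- .group_of(taxa$class, taxa$domain)
  n_t <- nrow(taxa)

  # per-taxon mean-response parameters
  taxa$intercept <- NA_real_; taxa$slope <- NA_real_; taxa$psi <- NA_real_
  for (cls in unique(taxa$class)) {
    idx <- which(taxa$class == cls)
    pp <- config$class_params[[cls]]
    taxa$intercept[idx] <- stats::runif(length(idx), pp$intercept[1], pp$intercept[2])
    taxa$slope[idx] <- stats::runif(length(idx), min(pp$slope), max(pp$slope))
    if (!is.null(pp$psi)) taxa$psi[idx] <- pp$psi
  }

  # ---- abundance matrix ----------------------------------------------------
  mu <- matrix(0, n_t, n_s, dimnames = list(taxa$taxon_id, sample_ids))
  for (i in seq_len(n_t)) {
    pp <- list(intercept = taxa$intercept[i], slope = taxa$slope[i], psi = taxa$psi[i])
    m <- class_mean(ec, taxa$class[i], pp)
    raw <- if (taxa$class[i] %in% c("linear_pos", "linear_neg"))
      taxa$intercept[i] + taxa$slope[i] * ec
    else if (taxa$class[i] %in% c("threshold_pos", "threshold_neg"))
      taxa$intercept[i] + taxa$slope[i] * pmax(0, ec - taxa$psi[i])
    else rep(taxa$intercept[i], n_s)
    if (all(raw < 0))
      stop("config error: taxon ", taxa$taxon_id[i],
           " has negative mean abundance at every EC design point")
    mu[i, ] <- m
  }
  abund <- if (config$abundance_noise == "nb") {
    a <- matrix(stats::rnbinom(n_t * n_s, mu = pmax(mu, 1e-12), size = config$nb_size),
                n_t, n_s)
    dimnames(a) <- dimnames(mu)
    a
  } else mu

  # ---- phylum / genus / genome size ---------------------------------------
  ref_genera <- c("Halomonas", "Salinibacter", "Thioalkalivibrio", "Oceanicola",
                  "Marinobacter", "Aquisalimonas", "Aliifodinibius",
                  "Roseovarius", "Rubrivirga", "Vibrio")
  other_bac <- c("Bacillus", "Streptomyces", "Pseudomonas", "Nitrospira",
                 "Geobacter", "Flavobacterium")
  other_arch <- c("Nitrosopumilus", "Nitrososphaera", "Methanosarcina")
  taxa$phylum <- NA_character_
  arch <- taxa$domain == "archaea"
  taxa$phylum[arch & taxa$group == "pos_arch"] <- "Euryarchaeota"
  taxa$phylum[arch & taxa$group != "pos_arch"] <- "Thaumarchaeota"
  bac <- which(!arch)
  taxa$phylum[bac] <- sample(c("Proteobacteria", "Actinobacteria", "Chloroflexi",
                               "Bacteroidetes"),
                             length(bac), replace = TRUE,
                             prob = c(0.5, 0.2, 0.1, 0.2))
  taxa$genus <- NA_character_
  taxa$ref_genus <- FALSE
  for (g in unique(taxa$group)) {
    idx <- which(taxa$group == g)
    n_missing <- .planted_count(config$genus_missing_frac, length(idx))
    miss <- if (n_missing > 0) sample(idx, n_missing) else integer()
    ident <- setdiff(idx, miss)
    n_ref <- .planted_count(config$ref_genus_frac[[g]], length(ident))
    refi <- if (n_ref > 0) sample(ident, n_ref) else integer()
    taxa$ref_genus[refi] <- TRUE
    taxa$genus[refi] <- sample(ref_genera, length(refi), replace = TRUE)
    oth <- setdiff(ident, refi)
    pool <- if (g %in% c("pos_arch", "neg_arch", "null_arch")) other_arch else other_bac
    taxa$genus[oth] <- sample(pool, length(oth), replace = TRUE)
  }
  taxa$genome_size_mb <- stats::rlnorm(n_t, config$genome_meanlog[taxa$group],
                                       config$genome_sdlog[taxa$group])
  n_gs_miss <- .planted_count(config$genome_missing_frac, n_t)
  if (n_gs_miss > 0) taxa$genome_size_mb[sample(n_t, n_gs_miss)] <- NA_real_

  # ---- mechanism presence and gene copy numbers ---------------------------
  mech_tab <- unique(catalog$mechanisms[c("mechanism_id", "category")])
  mech_members <- split(catalog$mechanisms$gene_id, catalog$mechanisms$mechanism_id)
  bg_genes <- setdiff(catalog$pathways$gene_id, catalog$mechanisms$gene_id)
  cacq_genes <- category_genes(catalog, "total_c_acquisition")

  mech_rows <- vector("list", 3L * n_t)
  copy_rows <- vector("list", n_t)
  mr <- 0L
  for (g in unique(taxa$group)) {
    idx <- which(taxa$group == g)
    complete_by_cat <- list()
    for (cat in names(config$completeness)) {
      k <- .planted_count(config$completeness[[cat]][[g]], length(idx))
      complete_by_cat[[cat]] <- idx[seq_len(k)]       # deterministic head count
    }
    for (i in idx) {
      present <- character()
      for (cat in names(config$completeness)) {
        mechs <- mech_tab$mechanism_id[mech_tab$category == cat]
        if (i %in% complete_by_cat[[cat]]) {
          pres <- mechs
        } else {
          keep <- stats::runif(length(mechs)) < config$incomplete_presence_prob
          if (all(keep)) keep[sample(length(mechs), 1L)] <- FALSE
          pres <- mechs[keep]
        }
        mr <- mr + 1L
        mech_rows[[mr]] <- data.frame(taxon_id = taxa$taxon_id[i], category = cat,
                                      mechanism_id = mechs,
                                      present = mechs %in% pres,
                                      stringsAsFactors = FALSE)
        present <- c(present, pres)
      }
      # carried genes: members of present mechanisms (>=1 each) + background KOs
      gene_ids <- character(); copies <- numeric()
      for (m in present) {
        mem <- mech_members[[m]]
        keep <- stats::runif(length(mem)) < config$mech_gene_prob
        if (!any(keep)) keep[1L] <- TRUE
        gene_ids <- c(gene_ids, mem[keep])
      }
      bg_keep <- bg_genes[stats::runif(length(bg_genes)) < config$background_gene_prob]
      gene_ids <- c(gene_ids, bg_keep)
      copies <- as.numeric(sample(seq(config$copy_range[1], config$copy_range[2]),
                                  length(gene_ids), replace = TRUE))
      # rescale C-acquisition copies so that the taxon's investment fraction
      # equals the planted group value exactly (copy numbers may be fractional)
      is_cacq <- gene_ids %in% cacq_genes
      target <- config$c_acq_fraction[[g]]
      if (any(is_cacq) && any(!is_cacq) && target > 0) {
        B <- sum(copies[!is_cacq])
        copies[is_cacq] <- copies[is_cacq] *
          (target / (1 - target)) * B / sum(copies[is_cacq])
      }
      copy_rows[[i]] <- data.frame(taxon_id = rep(taxa$taxon_id[i], length(gene_ids)),
                                   gene_id = gene_ids,
                                   copies = copies, stringsAsFactors = FALSE)
    }
  }
  truth_mech <- do.call(rbind, mech_rows[seq_len(mr)])
  truth_copies <- do.call(rbind, copy_rows)
  rownames(truth_mech) <- rownames(truth_copies) <- NULL

  # ---- gene-abundance tensor ----------------------------------------------
  ab_dt <- data.table::data.table(
    taxon_id = rep(rownames(abund), n_s),
    sample_id = rep(colnames(abund), each = n_t),
    at = as.vector(abund))
  cp_dt <- data.table::as.data.table(truth_copies)
  if (nrow(cp_dt) == 0L) {
    genes_dt <- data.table::data.table(taxon_id = character(), gene_id = character(),
                                       sample_id = character(), copies = numeric(),
                                       at = numeric())
  } else {
    genes_dt <- cp_dt[ab_dt, on = "taxon_id", allow.cartesian = TRUE]
    genes_dt <- genes_dt[!is.na(gene_id) & at > 0]
  }
  noise <- if (config$gene_noise_sdlog > 0)
    stats::rlnorm(nrow(genes_dt), -config$gene_noise_sdlog^2 / 2,
                  config$gene_noise_sdlog)
  else 1
  genes_dt[, abundance := copies * at * noise]
  genes <- as.data.frame(genes_dt[, list(taxon_id, gene_id, sample_id, abundance)])
  genes <- genes[order(genes$taxon_id, genes$gene_id, genes$sample_id), ]
  rownames(genes) <- NULL

  refs <- list(
    salt_tolerant_genera = c("Halo", "Salini", "Thio", "Ocean", "Marin",
                             "Aquisalimonas", "Aliifodinibius", "Roseovarius",
                             "Rubrivirga", "Vibrio"),
    reference_genomes = list(
      Euryarchaeota = stats::rlnorm(500, log(2.49), 0.4),
      Thaumarchaeota = stats::rlnorm(500, log(1.36), 0.3)))

  taxa_out <- taxa[c("taxon_id", "domain", "phylum", "genus", "genome_size_mb")]
  dataset <- ht_dataset(samples, taxa_out, abund, genes, catalog, refs)
  truth <- structure(list(
    taxa = taxa[c("taxon_id", "domain", "class", "group", "intercept", "slope",
                  "psi", "ref_genus")],
    copies = truth_copies,
    mechanisms = truth_mech,
    c_acq_fraction = config$c_acq_fraction,
    config = config), class = "ht_ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate a samples-by-pathways trait matrix with planted salinity signals
#'
#' Convenience generator for the random-forest biomarker stage: `n_signal`
#' pathway columns vary linearly with EC (slopes drawn uniformly from
#' `slope_range`, random sign), the rest are pure noise around a constant
#' baseline.  Gaussian noise with standard deviation `noise_sd` is added to
#' every column.
#'
#' @param ec per-sample EC vector
#' @param n_pathways total number of pathway columns
#' @param n_signal number of EC-coupled columns (the first `n_signal`)
#' @param slope_range magnitude range of planted slopes
#' @param noise_sd Gaussian noise standard deviation
#' @param baseline constant baseline level
#' @return list with `x` (matrix, columns `P001`...) and `signal` (planted
#'   column names)
#' @export
simulate_pathway_matrix <- function(ec, n_pathways = 100L, n_signal = 5L,
                                    slope_range = c(0.5, 1), noise_sd = 0.5,
                                    baseline = 5) {
  n <- length(ec)
  x <- matrix(baseline + stats::rnorm(n * n_pathways, 0, noise_sd), n, n_pathways)
  colnames(x) <- sprintf("P%03d", seq_len(n_pathways))
  if (n_signal > 0) {
    sl <- stats::runif(n_signal, slope_range[1], slope_range[2]) *
      sample(c(-1, 1), n_signal, replace = TRUE)
    for (j in seq_len(n_signal)) x[, j] <- x[, j] + sl[j] * ec
  }
  list(x = x, signal = colnames(x)[seq_len(n_signal)])
}

#' Simulate per-taxon pathway profiles for two groups with planted differences
#'
#' Builds taxa-by-pathways matrices for two groups where `diff_idx` columns
#' differ in mean by `delta` (group A higher) and all other columns share the
#' same baseline.  Used to exercise the difference-threshold biomarker rule.
#'
#' @param n_a,n_b group sizes
#' @param n_pathways number of pathway columns
#' @param diff_idx indices of differential pathways
#' @param delta planted mean difference
#' @param noise_sd Gaussian noise standard deviation (0 for the noiseless case)
#' @param baseline shared baseline level
#' @return list with matrices `a` and `b` and `differential` (column names)
#' @export
simulate_group_profiles <- function(n_a, n_b, n_pathways = 60L,
                                    diff_idx = 1:6, delta = 0.01,
                                    noise_sd = 0, baseline = 0.05) {
  mk <- function(n, shift) {
    m <- matrix(baseline + stats::rnorm(n * n_pathways, 0, noise_sd), n, n_pathways)
    colnames(m) <- sprintf("P%03d", seq_len(n_pathways))
    m[, diff_idx] <- m[, diff_idx] + shift
    m
  }
  list(a = mk(n_a, delta), b = mk(n_b, 0),
       differential = sprintf("P%03d", diff_idx))
}

#' @export
print.ht_ground_truth <- function(x, ...) {
  cat("ht_ground_truth:", nrow(x$taxa), "taxa;",
    paste(names(table(x$taxa$group)), table(x$taxa$group), sep = "=", collapse = ", "),
    "\n")
  invisible(x)
}
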