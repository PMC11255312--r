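# Pipeline orchestration and command-line entry point.
#
# `halotrait run --config config.yaml --out outdir` executes every stage;
# the subcommands simulate / classify / segfit / traits / mechanisms /
# contrasts / rf-select run one stage each.  All outputs are TSV or JSON.

#' Default pipeline configuration
#'
#' @return nested list of stage options; any subset can be overridden by a
#'   YAML or JSON config file (see [read_config()])
#' @export
default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    synth = list(),                      # overrides passed to synth_config()
    classify = list(min_total = 100, alpha = 0.05, n_bac = 200L, n_arch = 50L),
    segfit = list(grid_points = 201L, alpha = 0.05, criterion = "f_test"),
    biomarker = list(diff_threshold = 0.001, alpha = 0.05),
    rf = list(n_trees = 200L, iterations = 20L, folds = 10L, k_max = 10L)
  )
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Unspecified options fall back to [default_config()].
#'
#' @param path config file path, or `NULL` for pure defaults
#' @return configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  modifyList(cfg, user)
}

.log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
}

.tsv <- function(x, path) data.table::fwrite(x, path, sep = "\t", na = "NA",
                                             quote = FALSE)
.json_out <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                    digits = NA, pretty = TRUE)

#' Simulate a dataset to a directory
#'
#' Writes the six dataset files plus `ground_truth.tsv` (per-taxon class,
#' slope, breakpoint) and the planted copy-number and mechanism tables.
#'
#' @param config pipeline configuration (see [read_config()])
#' @param outdir output directory
#' @return the generated `list(dataset, truth)`, invisibly
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- do.call(synth_config, c(config$synth, list(seed = config$seed)))
  gen <- generate_dataset(sc)
  write_dataset(gen$dataset, outdir)
  .tsv(gen$truth$taxa, file.path(outdir, "ground_truth.tsv"))
  .tsv(gen$truth$copies, file.path(outdir, "truth_copies.tsv"))
  .tsv(gen$truth$mechanisms, file.path(outdir, "truth_mechanisms.tsv"))
  .log(config, "simulated dataset written to ", outdir)
  invisible(gen)
}

.stage_classify <- function(ds, config, outdir) {
  cc <- config$classify
  assignments <- classify_taxa(ds, min_total = cc$min_total, alpha = cc$alpha)
  groups <- suppressWarnings(
    select_response_groups(assignments, n_bac = cc$n_bac, n_arch = cc$n_arch))
  if (!is.null(outdir)) {
    .tsv(groups, file.path(outdir, "assignments.tsv"))
    trends <- rbind(group_trend(groups, ds, "absolute"),
                    suppressWarnings(group_trend(groups, ds, "relative")))
    .tsv(trends, file.path(outdir, "group_trends.tsv"))
    rv <- reference_validation(groups, ds$taxa, ds$refs)
    .json_out(rv, file.path(outdir, "reference_validation.json"))
  }
  groups
}

.stage_segfit <- function(ds, groups, config, outdir) {
  sf <- config$segfit
  labs <- sort(setdiff(unique(groups$group), "none"))
  tot <- colSums(ds$abundance)
  rows <- list()
  for (g in labs) for (mode in c("absolute", "relative")) {
    ids <- groups$taxon_id[groups$group == g]
    y <- colSums(ds$abundance[ids, , drop = FALSE])
    if (mode == "relative") y <- ifelse(tot > 0, y / tot, NA)
    ok <- is.finite(y)
    fit <- fit_segmented(ds$samples$ec[ok], y[ok], grid_points = sf$grid_points)
    sel <- select_model(fit, alpha = sf$alpha, criterion = sf$criterion)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, mode = mode, psi = fit$psi, intercept = fit$intercept,
      left_slope = fit$left_slope, slope_change = fit$slope_change,
      rss_segmented = fit$rss_segmented, rss_linear = fit$rss_linear,
      n = fit$n, statistic = sel$statistic,
      p_value = if (!is.null(sel$p_value)) sel$p_value else NA_real_,
      chosen_model = sel$chosen_model, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) .tsv(out, file.path(outdir, "segfit.tsv"))
  out
}

.stage_traits <- function(ds, groups, config, outdir) {
  sel <- groups[groups$group != "none", ]
  cats <- c("overall_KO", "salt_resistance", "c_fixation", "cazyme",
            "total_c_acquisition")
  pooled <- nacg_matrix(ds, sel$taxon_id, cats)
  pooled_df <- data.frame(taxon_id = rownames(pooled),
                          group = sel$group[match(rownames(pooled), sel$taxon_id)],
                          pooled, check.names = FALSE, stringsAsFactors = FALSE)
  inv <- data.frame(taxon_id = rownames(pooled),
                    group = pooled_df$group,
                    fraction = pooled[, "total_c_acquisition"] / pooled[, "overall_KO"],
                    stringsAsFactors = FALSE)
  # per-sample, group-scope trait trends along the gradient
  per_sample <- list()
  gd <- data.table::as.data.table(ds$genes)
  for (g in sort(unique(sel$group))) {
    ids <- sel$taxon_id[sel$group == g]
    at <- colSums(ds$abundance[ids, , drop = FALSE])
    gg <- gd[taxon_id %in% ids]
    for (cat in cats) {
      members <- category_genes(ds$catalog, cat)
      num <- gg[gene_id %in% members, list(s = sum(abundance)), by = "sample_id"]
      v <- stats::setNames(numeric(length(at)), names(at))
      v[num$sample_id] <- num$s
      per_sample[[length(per_sample) + 1L]] <- data.frame(
        group = g, category = cat, sample_id = names(at), ec = ds$samples$ec,
        nacg = ifelse(at > 0, v / at, NA_real_), stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, per_sample)
  # per-sample KO alpha diversity of the whole community
  agg <- gd[, list(s = sum(abundance)), by = c("sample_id", "gene_id")]
  div <- do.call(rbind, lapply(ds$samples$sample_id, function(sid) {
    ab <- agg$s[agg$sample_id == sid & agg$s > 0]
    sh <- if (length(ab)) { p <- ab / sum(ab); -sum(p * log(p)) } else NA_real_
    data.frame(sample_id = sid, ec = ds$samples$ec[ds$samples$sample_id == sid],
               richness = length(ab), shannon = sh, stringsAsFactors = FALSE)
  }))
  if (!is.null(outdir)) {
    .tsv(pooled_df, file.path(outdir, "traits_pooled.tsv"))
    .tsv(per_sample, file.path(outdir, "traits_per_sample.tsv"))
    .tsv(inv, file.path(outdir, "investment_fractions.tsv"))
    .tsv(div, file.path(outdir, "ko_diversity.tsv"))
  }
  list(pooled = pooled_df, per_sample = per_sample, investment = inv,
       diversity = div)
}

.stage_mechanisms <- function(ds, groups, config, outdir) {
  sel <- groups[groups$group != "none", ]
  prof_rows <- list(); comp_rows <- list(); upset <- list()
  for (g in sort(unique(sel$group))) {
    ids <- sel$taxon_id[sel$group == g]
    for (cat in c("salt_resistance", "c_fixation", "cazyme")) {
      profs <- mechanism_profiles(ds, ids, cat)
      for (p in profs)
        prof_rows[[length(prof_rows) + 1L]] <- data.frame(
          taxon_id = p$taxon_id, group = g, category = cat,
          completeness = p$completeness, category_size = p$category_size,
          present = paste(p$present_mechanisms, collapse = "+"),
          stringsAsFactors = FALSE)
      up <- upset_counts(profs)
      upset[[g]][[cat]] <- list(subsets = up$subsets,
                                marginals = as.list(up$marginals),
                                group_size = up$group_size)
      cd <- completeness_distribution(profs)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        group = g, category = cat, completeness = names(cd$histogram),
        count = cd$histogram, complete_fraction = cd$complete_fraction,
        stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, prof_rows)
  completeness <- do.call(rbind, comp_rows)
  rownames(completeness) <- NULL
  if (!is.null(outdir)) {
    .tsv(profiles, file.path(outdir, "mechanism_profiles.tsv"))
    .tsv(completeness, file.path(outdir, "completeness.tsv"))
    .json_out(upset, file.path(outdir, "upset_counts.json"))
  }
  list(profiles = profiles, completeness = completeness, upset = upset)
}

.stage_contrasts <- function(ds, groups, traits, config, outdir) {
  bc <- config$biomarker
  sel <- groups[groups$group != "none", ]
  pooled <- traits$pooled
  cats <- c("overall_KO", "salt_resistance", "c_fixation", "cazyme",
            "total_c_acquisition")
  rows <- list()
  for (pair in list(c("pos-bac", "neg-bac"), c("pos-arch", "neg-arch"))) {
    a <- pooled[pooled$group == pair[1], , drop = FALSE]
    b <- pooled[pooled$group == pair[2], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    for (cat in cats) {
      xa <- a[[cat]][is.finite(a[[cat]])]; xb <- b[[cat]][is.finite(b[[cat]])]
      if (length(xa) < 1L || length(xb) < 1L) next
      t <- mann_whitney(xa, xb)
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0(cat, ": ", pair[1], " vs ", pair[2]),
        group_a = pair[1], group_b = pair[2], n_a = t$n_a, n_b = t$n_b,
        median_a = t$median_a, median_b = t$median_b, u = t$u,
        p_value = t$p_value, significant = t$p_value < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  nacg_contrasts <- do.call(rbind, rows)
  shared <- intersect(
    unique(ds$taxa$phylum[match(sel$taxon_id[sel$group == "pos-bac"],
                                ds$taxa$taxon_id)]),
    unique(ds$taxa$phylum[match(sel$taxon_id[sel$group == "neg-bac"],
                                ds$taxa$taxon_id)]))
  shared <- if (length(shared)) shared[1] else "Proteobacteria"
  gsc <- suppressWarnings(genome_size_contrasts(groups, ds$taxa, ds$refs,
                                                shared_phylum = shared))
  gsc2 <- if (!is.null(gsc))
    data.frame(label = paste0("genome size: ", gsc$label), group_a = gsc$group_a,
               group_b = gsc$group_b, n_a = gsc$n_a, n_b = gsc$n_b,
               median_a = gsc$median_a, median_b = gsc$median_b, u = gsc$u,
               p_value = gsc$p_value, significant = gsc$significant,
               stringsAsFactors = FALSE)
  contrasts <- rbind(nacg_contrasts, gsc2)
  # partial correlations: edaphic covariates vs community trait summaries,
  # controlling EC
  covars <- setdiff(names(ds$samples), c("sample_id", "ec"))
  resp <- split(traits$per_sample, traits$per_sample$category)
  pc_rows <- list()
  for (cv in covars) {
    for (cat in names(resp)) {
      y <- tapply(resp[[cat]]$nacg, resp[[cat]]$sample_id, mean, na.rm = TRUE)
      y <- y[ds$samples$sample_id]
      ok <- is.finite(y)
      if (sum(ok) < 4L) next
      pc <- partial_corr(ds$samples[[cv]][ok], y[ok], ds$samples$ec[ok])
      pc_rows[[length(pc_rows) + 1L]] <- data.frame(
        covariate = cv, response = cat, r_partial = pc$r_partial,
        p_value = pc$p_value, n = pc$n, stringsAsFactors = FALSE)
    }
  }
  partials <- do.call(rbind, pc_rows)
  # level-3 biomarker rule + clustering of selected pathways
  bm_rows <- list(); cluster <- list()
  for (pair in list(c("pos-bac", "neg-bac"), c("pos-arch", "neg-arch"))) {
    ids_a <- sel$taxon_id[sel$group == pair[1]]
    ids_b <- sel$taxon_id[sel$group == pair[2]]
    if (length(ids_a) < 2L || length(ids_b) < 2L) next
    ma <- pathway_nacg_matrix(ds, ids_a, level = 3L)
    mb <- pathway_nacg_matrix(ds, ids_b, level = 3L)
    bm <- biomarker_pathways(ma, mb, diff_threshold = bc$diff_threshold,
                             alpha = bc$alpha)
    bm$pair <- paste(pair, collapse = " vs ")
    bm_rows[[length(bm_rows) + 1L]] <- bm
    selp <- bm$pathway[bm$selected]
    if (length(selp) >= 2L) {
      gm <- cbind(colMeans(ma[, selp, drop = FALSE], na.rm = TRUE),
                  colMeans(mb[, selp, drop = FALSE], na.rm = TRUE))
      colnames(gm) <- pair
      hc <- hcluster_order(gm)
      cluster[[paste(pair, collapse = "_vs_")]] <- list(
        pathways = hc$labels[hc$order], merges = hc$merges)
    }
  }
  biomarkers <- do.call(rbind, bm_rows)
  if (!is.null(outdir)) {
    .tsv(contrasts, file.path(outdir, "contrasts.tsv"))
    if (!is.null(partials)) .tsv(partials, file.path(outdir, "partial_correlations.tsv"))
    if (!is.null(biomarkers)) .tsv(biomarkers, file.path(outdir, "biomarkers.tsv"))
    .json_out(cluster, file.path(outdir, "cluster_order.json"))
  }
  list(contrasts = contrasts, partials = partials, biomarkers = biomarkers,
       cluster = cluster)
}

.stage_rf <- function(ds, groups, config, outdir) {
  rc <- config$rf
  sel <- groups[groups$group != "none", ]
  imp_rows <- list(); curve_rows <- list(); selected <- list()
  gi <- 0L
  for (g in sort(unique(sel$group))) {
    gi <- gi + 1L
    ids <- sel$taxon_id[sel$group == g]
    x <- group_pathway_sample_matrix(ds, ids, level = 3L)
    ok <- apply(x, 1, function(r) all(is.finite(r)))
    x <- x[ok, , drop = FALSE]
    if (nrow(x) < 10L) next
    ec <- ds$samples$ec[match(rownames(x), ds$samples$sample_id)]
    rk <- suppressWarnings(
      rf_rank(x, ec, n_trees = rc$n_trees, iterations = rc$iterations,
              seed = config$seed + 1000L * gi))
    cv <- cv_select_count(rk, x[, rk$table$pathway, drop = FALSE], ec,
                          folds = min(rc$folds, nrow(x)),
                          seed = config$seed + 1000L * gi + 500L,
                          k_max = rc$k_max, n_trees = rc$n_trees)
    imp <- rk$table; imp$group <- g
    imp_rows[[length(imp_rows) + 1L]] <- imp
    curve_rows[[length(curve_rows) + 1L]] <- data.frame(
      group = g, k = seq_len(cv$k_max), cv_error = cv$cv_error,
      cv_se = cv$cv_se, stringsAsFactors = FALSE)
    selected[[g]] <- list(selected_count = cv$selected_count, rule = cv$rule,
                          pathways = rk$table$pathway[seq_len(cv$selected_count)])
  }
  if (!is.null(outdir)) {
    .tsv(do.call(rbind, imp_rows), file.path(outdir, "rf_importance.tsv"))
    .tsv(do.call(rbind, curve_rows), file.path(outdir, "rf_cv_curve.tsv"))
    .json_out(selected, file.path(outdir, "rf_selected.json"))
  }
  selected
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a dataset and runs classification, breakpoint fits,
#' trait normalization, mechanism accounting, group contrasts and
#' random-forest biomarker selection, writing every output table to `outdir`.
#'
#' @param config configuration list from [read_config()] (or `NULL` for
#'   defaults)
#' @param outdir output directory
#' @param data_dir optional directory with an existing dataset (as written by
#'   [write_dataset()]); when `NULL` a dataset is simulated into
#'   `outdir/dataset`
#' @return invisible list of per-stage results
#' @export
run_pipeline <- function(config = NULL, outdir, data_dir = NULL) {
  if (is.null(config)) config <- default_config()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- if (is.null(data_dir)) {
    run_simulate(config, file.path(outdir, "dataset"))$dataset
  } else {
    suppressMessages(read_dataset(data_dir))
  }
  .log(config, "stage: classify")
  groups <- .stage_classify(ds, config, outdir)
  .log(config, "stage: segfit")
  seg <- .stage_segfit(ds, groups, config, outdir)
  .log(config, "stage: traits")
  traits <- suppressMessages(.stage_traits(ds, groups, config, outdir))
  .log(config, "stage: mechanisms")
  mech <- .stage_mechanisms(ds, groups, config, outdir)
  .log(config, "stage: contrasts")
  contr <- suppressMessages(.stage_contrasts(ds, groups, traits, config, outdir))
  .log(config, "stage: rf-select")
  rf <- suppressMessages(.stage_rf(ds, groups, config, outdir))
  invisible(list(dataset = ds, groups = groups, segfit = seg, traits = traits,
                 mechanisms = mech, contrasts = contr, rf = rf))
}

#' Command-line entry point
#'
#' Implements `halotrait <subcommand> [--config FILE] [--out DIR]
#' [--data DIR] [--seed INT] [--log-level LEVEL]` with subcommands `run`,
#' `simulate`, `classify`, `segfit`, `traits`, `mechanisms`, `contrasts`,
#' `rf-select`.  Installed as `inst/cli/halotrait.R` (run with `Rscript`).
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
halotrait_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("run", "simulate", "classify", "segfit", "traits", "mechanisms",
            "contrasts", "rf-select")
  if (!length(args) || !args[1] %in% cmds)
    stop("usage: halotrait <", paste(cmds, collapse = "|"),
         "> [--config FILE] [--out DIR] [--data DIR] [--seed INT] [--log-level LEVEL]")
  cmd <- args[1]
  opt <- list(config = NULL, out = "halotrait_out", data = NULL,
              seed = NULL, `log-level` = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    if (i + 1L > length(args)) stop("option ", args[i], " needs a value")
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- read_config(opt$config)
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$`log-level`)) config$log_level <- opt$`log-level`
  outdir <- opt$out
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  load_ds <- function() {
    dd <- if (!is.null(opt$data)) opt$data else file.path(outdir, "dataset")
    if (!dir.exists(dd)) stop("dataset directory not found: ", dd,
                              " (run `halotrait simulate` first or pass --data)")
    suppressMessages(read_dataset(dd))
  }
  switch(cmd,
    run = run_pipeline(config, outdir, data_dir = opt$data),
    simulate = run_simulate(config, outdir),
    classify = .stage_classify(load_ds(), config, outdir),
    segfit = {
      ds <- load_ds(); g <- .stage_classify(ds, config, NULL)
      .stage_segfit(ds, g, config, outdir)
    },
    traits = {
      ds <- load_ds(); g <- .stage_classify(ds, config, NULL)
      suppressMessages(.stage_traits(ds, g, config, outdir))
    },
    mechanisms = {
      ds <- load_ds(); g <- .stage_classify(ds, config, NULL)
      .stage_mechanisms(ds, g, config, outdir)
    },
    contrasts = {
      ds <- load_ds(); g <- .stage_classify(ds, config, NULL)
      tr <- suppressMessages(.stage_traits(ds, g, config, NULL))
      suppressMessages(.stage_contrasts(ds, g, tr, config, outdir))
    },
    `rf-select` = {
      ds <- load_ds(); g <- .stage_classify(ds, config, NULL)
      suppressMessages(.stage_rf(ds, g, config, outdir))
    })
  invisible(0L)
}
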