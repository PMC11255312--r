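#' Per-taxon ordinary least squares of abundance on salinity
#'
#' Fits `abundance = intercept + slope * ec` by least squares and returns the
#' two-sided p-value of the slope from its t statistic on `n - 2` degrees of
#' freedom.  A perfectly constant response is defined as slope 0, p = 1 (the
#' degenerate case must not crash batch classification).
#'
#' @param abundance per-sample abundance vector
#' @param ec per-sample electrical conductivity, dS/m
#' @return list with `slope`, `intercept`, `p_value`, `r_squared`, `n_used`
#' @export
taxon_ols <- function(abundance, ec) {
  n <- length(ec)
  if (length(abundance) != n) stop("abundance and ec lengths differ")
  if (n < 3L) stop("need at least 3 samples for the per-taxon regression")
  sxx <- sum((ec - mean(ec))^2)
  if (sxx == 0) stop("ec is constant; slope not identifiable")
  y <- as.numeric(abundance)
  sxy <- sum((ec - mean(ec)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(ec)
  res <- y - intercept - slope * ec
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {   # constant response: define slope 0, p 1
    return(list(slope = 0, intercept = mean(y), p_value = 1,
                r_squared = NA_real_, n_used = n))
  }
  r2 <- 1 - rss / tss
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2)
  list(slope = slope, intercept = intercept, p_value = p,
       r_squared = r2, n_used = n)
}

#' Assign salinity-response directions to all taxa
#'
#' Reproduces the screening stage of the four-group construction: taxa with
#' total abundance below `min_total` across all samples are excluded; the
#' rest are regressed on EC and called `positive` or `negative` by slope sign
#' when the slope p-value is below `alpha`, otherwise left unassigned.  No
#' multiple-testing correction is applied by default (matching the stated
#' P < 0.05 rule); set `p_adjust = "BH"` for a Benjamini-Hochberg variant.
#'
#' @param dataset an [ht_dataset()]
#' @param min_total total-abundance filter (default 100)
#' @param alpha significance level on the per-taxon slope (default 0.05)
#' @param p_adjust `"none"` (default) or `"BH"`
#' @return data.frame with one row per taxon: `taxon_id`, `domain`,
#'   `total_abundance`, `slope`, `p_value`, `r_squared`, `direction`
#'   (`positive`/`negative`/`none`), `excluded_reason`
#'   (`low_abundance`/`nonsignificant`/`none`)
#' @export
classify_taxa <- function(dataset, min_total = 100, alpha = 0.05,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(dataset$abundance) == 0L) stop("empty abundance matrix")
  ec <- dataset$samples$ec
  tot <- total_abundance(dataset)
  out <- data.frame(taxon_id = dataset$taxa$taxon_id,
                    domain = dataset$taxa$domain,
                    total_abundance = as.numeric(tot[dataset$taxa$taxon_id]),
                    slope = NA_real_, p_value = NA_real_, r_squared = NA_real_,
                    direction = "none", excluded_reason = "none",
                    stringsAsFactors = FALSE)
  keep <- out$total_abundance >= min_total
  out$excluded_reason[!keep] <- "low_abundance"
  for (i in which(keep)) {
    fit <- taxon_ols(dataset$abundance[out$taxon_id[i], ], ec)
    out$slope[i] <- fit$slope
    out$p_value[i] <- fit$p_value
    out$r_squared[i] <- fit$r_squared
  }
  p <- out$p_value
  if (p_adjust == "BH") p[keep] <- stats::p.adjust(p[keep], method = "BH")
  sig <- keep & !is.na(p) & p < alpha & out$slope != 0
  out$direction[sig] <- ifelse(out$slope[sig] > 0, "positive", "negative")
  out$excluded_reason[keep & !sig] <- "nonsignificant"
  out
}

#' Select the four response groups by total abundance
#'
#' Within each (domain x direction) stratum, taxa are ranked by total
#' abundance (descending; ties broken by taxon id) and the top `n_bac`
#' bacteria / `n_arch` archaea are labelled `pos-bac`, `neg-bac`, `pos-arch`
#' or `neg-arch`.  Strata smaller than the quota are kept whole with a
#' warning.
#'
#' @param assignments output of [classify_taxa()]
#' @param n_bac taxa kept per bacterial group (default 200)
#' @param n_arch taxa kept per archaeal group (default 50)
#' @return `assignments` with added columns `group` (`pos-bac`, `neg-bac`,
#'   `pos-arch`, `neg-arch` or `none`) and `rank_within_group`; unselected
#'   significant taxa get `excluded_reason = "not_selected"`.
#' @export
select_response_groups <- function(assignments, n_bac = 200L, n_arch = 50L) {
  out <- assignments
  out$group <- "none"
  out$rank_within_group <- NA_integer_
  for (dom in c("bacteria", "archaea")) {
    quota <- if (dom == "bacteria") n_bac else n_arch
    for (dir in c("positive", "negative")) {
      idx <- which(out$domain == dom & out$direction == dir)
      if (!length(idx)) next
      ord <- idx[order(-out$total_abundance[idx], out$taxon_id[idx])]
      if (length(ord) < quota)
        warning(sprintf("stratum %s/%s has %d candidates (< %d); keeping all",
                        dom, dir, length(ord), quota))
      sel <- ord[seq_len(min(quota, length(ord)))]
      lab <- paste0(ifelse(dir == "positive", "pos-", "neg-"),
                    ifelse(dom == "bacteria", "bac", "arch"))
      out$group[sel] <- lab
      out$rank_within_group[sel] <- seq_along(sel)
      drop <- setdiff(ord, sel)
      out$excluded_reason[drop] <- "not_selected"
    }
  }
  out
}

#' Validate groups against published salt-tolerant genera
#'
#' A taxon matches if its genus equals a reference pattern or starts with it
#' (prefix patterns such as `"Halo"` match `"Halobacterium"`).  Taxa without a
#' genus are excluded from the denominator.
#'
#' @param groups output of [select_response_groups()]
#' @param taxa taxon metadata table (with `taxon_id`, `genus`)
#' @param refs reference sets (needs non-empty `salt_tolerant_genera`)
#' @return data.frame per group: `group`, `n_genus_identified`, `n_matching`,
#'   `fraction` (NA for empty groups)
#' @export
reference_validation <- function(groups, taxa, refs) {
  pats <- refs$salt_tolerant_genera
  if (!length(pats)) stop("empty salt-tolerant reference list")
  genus <- taxa$genus[match(groups$taxon_id, taxa$taxon_id)]
  labs <- c("pos-bac", "neg-bac", "pos-arch", "neg-arch")
  res <- lapply(labs, function(g) {
    gen <- genus[groups$group == g]
    gen <- gen[!is.na(gen)]
    if (!length(gen))
      return(data.frame(group = g, n_genus_identified = 0L, n_matching = 0L,
                        fraction = NA_real_, stringsAsFactors = FALSE))
    hit <- vapply(gen, function(x) any(startsWith(x, pats)), logical(1))
    data.frame(group = g, n_genus_identified = length(gen),
               n_matching = sum(hit), fraction = sum(hit) / length(gen),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Group-level abundance trend along the gradient
#'
#' Sums member-taxon abundances per sample (absolute mode) or divides the sum
#' by the per-sample total across all taxa (relative mode), then fits the same
#' OLS as [taxon_ols()].
#'
#' @param groups output of [select_response_groups()]
#' @param dataset an [ht_dataset()]
#' @param mode `"absolute"` or `"relative"`
#' @return data.frame per group with the per-group fit plus `mode`
#' @export
group_trend <- function(groups, dataset, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  ec <- dataset$samples$ec
  tot_per_sample <- colSums(dataset$abundance)
  labs <- setdiff(unique(groups$group), "none")
  if (!length(labs)) stop("no non-empty groups to fit")
  res <- lapply(sort(labs), function(g) {
    ids <- groups$taxon_id[groups$group == g]
    y <- colSums(dataset$abundance[ids, , drop = FALSE])
    use <- rep(TRUE, length(y))
    if (mode == "relative") {
      use <- tot_per_sample > 0
      if (!all(use)) warning(sum(!use), " sample(s) with zero total abundance dropped")
      y <- y[use] / tot_per_sample[use]
    }
    fit <- taxon_ols(y, ec[use])
    data.frame(group = g, mode = mode, n_taxa = length(ids),
               slope = fit$slope, intercept = fit$intercept,
               p_value = fit$p_value, r_squared = fit$r_squared,
               n_used = fit$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
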