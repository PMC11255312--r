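#' Unpaired two-sided Mann-Whitney U test
#'
#' U is computed from midrank sums.  The two-sided p-value is exact by
#' enumeration of all label assignments when `n_a + n_b <= 12` and the pooled
#' data contain no ties; otherwise a normal approximation with tie correction
#' and continuity correction is used.  The exact two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` under the permutation null.
#'
#' @param a,b numeric samples (each non-empty)
#' @param exact_max maximum pooled size for the exact enumeration (default 12)
#' @return list of class `ht_mwu`: `u` (statistic for sample `a`), `u_b`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, `p_value`, `method`
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values in input; drop them first")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n_a + n_b <= exact_max) {
    # exact: U-distribution over all C(n_a+n_b, n_a) labelings
    combs <- utils::combn(n_a + n_b, n_a)
    rr <- rank(pooled)
    us <- apply(combs, 2, function(ix) sum(rr[ix]) - n_a * (n_a + 1) / 2)
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    n <- n_a + n_b
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) { p <- 1 } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(u = u, u_b = n_a * n_b - u, n_a = n_a, n_b = n_b,
                 median_a = stats::median(a), median_b = stats::median(b),
                 p_value = p, method = method),
            class = "ht_mwu")
}

#' @export
print.ht_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), medians %.4g vs %.4g, p = %.4g [%s]\n",
              x$u, x$n_a, x$n_b, x$median_a, x$median_b, x$p_value, x$method))
  invisible(x)
}

#' Genome-size contrasts between and within response groups
#'
#' Emits Mann-Whitney contrasts of genome size (Mb) for
#' (i) pos-bac vs neg-bac and pos-arch vs neg-arch,
#' (ii) the two bacterial groups restricted to a shared phylum (controls for
#' phylogenetic composition), and
#' (iii) each archaeal group against the reference genome-size distribution of
#' its phylum.  Taxa without genome sizes are dropped and counted; a side with
#' fewer than 3 sized taxa skips that contrast with a warning.
#'
#' @param groups output of [select_response_groups()]
#' @param taxa taxon metadata table
#' @param refs reference sets with `reference_genomes` keyed by phylum
#' @param shared_phylum phylum used for the within-phylum bacterial contrast
#'   (default `"Proteobacteria"`)
#' @return data.frame with one row per contrast: `label`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `n_dropped`, `median_a`, `median_b`, `u`,
#'   `p_value`, `significant`
#' @export
genome_size_contrasts <- function(groups, taxa, refs,
                                  shared_phylum = "Proteobacteria") {
  gs_of <- function(ids) {
    v <- taxa$genome_size_mb[match(ids, taxa$taxon_id)]
    list(x = v[!is.na(v)], dropped = sum(is.na(v)))
  }
  ids_of <- function(g, phylum = NULL) {
    ids <- groups$taxon_id[groups$group == g]
    if (!is.null(phylum)) {
      ph <- taxa$phylum[match(ids, taxa$taxon_id)]
      ids <- ids[!is.na(ph) & ph == phylum]
    }
    ids
  }
  row_of <- function(label, ga, gb, xa, xb, dropped) {
    if (length(xa) < 3L || length(xb) < 3L) {
      warning("contrast '", label, "' skipped: fewer than 3 sized taxa on one side")
      return(NULL)
    }
    t <- mann_whitney(xa, xb)
    data.frame(label = label, group_a = ga, group_b = gb,
               n_a = t$n_a, n_b = t$n_b, n_dropped = dropped,
               median_a = t$median_a, median_b = t$median_b,
               u = t$u, p_value = t$p_value,
               significant = t$p_value < 0.05, stringsAsFactors = FALSE)
  }
  out <- list()
  for (pair in list(c("pos-bac", "neg-bac"), c("pos-arch", "neg-arch"))) {
    a <- gs_of(ids_of(pair[1])); b <- gs_of(ids_of(pair[2]))
    out[[length(out) + 1L]] <- row_of(paste(pair, collapse = " vs "),
                                      pair[1], pair[2], a$x, b$x,
                                      a$dropped + b$dropped)
  }
  known_phyla <- unique(stats::na.omit(taxa$phylum))
  if (!shared_phylum %in% known_phyla)
    stop("unknown phylum: ", shared_phylum)
  a <- gs_of(ids_of("pos-bac", shared_phylum))
  b <- gs_of(ids_of("neg-bac", shared_phylum))
  out[[length(out) + 1L]] <- row_of(
    paste0("pos-bac vs neg-bac within ", shared_phylum),
    "pos-bac", "neg-bac", a$x, b$x, a$dropped + b$dropped)
  for (g in c("pos-arch", "neg-arch")) {
    ids <- ids_of(g)
    if (!length(ids)) next
    ph <- names(sort(table(taxa$phylum[match(ids, taxa$taxon_id)]),
                     decreasing = TRUE))[1]
    ref <- refs$reference_genomes[[ph]]
    if (is.null(ref)) {
      warning("no reference genome-size distribution for phylum ", ph)
      next
    }
    a <- gs_of(ids)
    out[[length(out) + 1L]] <- row_of(paste0(g, " vs all ", ph),
                                      g, paste0("ref:", ph), a$x, ref,
                                      a$dropped)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First-order partial correlation controlling one covariate
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with the
#' two-sided p-value from a t statistic on `n - 3` degrees of freedom.  The
#' result equals the Pearson correlation of the OLS residuals of `x ~ z` and
#' `y ~ z`.  Degenerate inputs (`|r_xz| = 1` or `|r_yz| = 1`) give `NA` with a
#' warning.
#'
#' @param x,y variables of interest
#' @param control the controlled covariate (EC in the salinity analysis)
#' @return list with `r_partial`, `p_value`, `n`
#' @export
partial_corr <- function(x, y, control) {
  n <- length(x)
  if (length(y) != n || length(control) != n) stop("inputs must be aligned")
  if (n < 4L) stop("partial correlation needs >= 4 observations")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, control)
  ryz <- stats::cor(y, control)
  if (any(!is.finite(c(rxy, rxz, ryz))) ||
      abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    warning("partial correlation undefined (a variable is collinear with the control)")
    return(list(r_partial = NA_real_, p_value = NA_real_, n = n))
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  list(r_partial = r, p_value = p, n = n)
}

#' Differential biomarker pathways between two groups
#'
#' A pathway is selected when the Mann-Whitney test of its per-taxon NACG
#' values between the two groups has `p < alpha` AND the absolute difference
#' of group means exceeds `diff_threshold` (default 0.001).  With
#' `diff_threshold = 0` the rule reduces to significance alone; with an
#' infinite threshold nothing is selected.
#'
#' @param nacg_a,nacg_b taxa x pathway NACG matrices for the two groups
#'   (shared columns)
#' @param diff_threshold minimum absolute difference of group means
#' @param alpha significance level
#' @return data.frame per pathway: `pathway`, `mean_a`, `mean_b`, `diff`,
#'   `p_value`, `selected`, `direction` (`"up_in_a"`/`"up_in_b"`/`"none"`)
#' @export
biomarker_pathways <- function(nacg_a, nacg_b, diff_threshold = 0.001,
                               alpha = 0.05) {
  common <- intersect(colnames(nacg_a), colnames(nacg_b))
  if (!length(common)) stop("no shared pathway columns")
  res <- lapply(common, function(p) {
    xa <- nacg_a[, p]; xb <- nacg_b[, p]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    t <- mann_whitney(xa, xb)
    d <- mean(xa) - mean(xb)
    sel <- t$p_value < alpha && abs(d) > diff_threshold
    data.frame(pathway = p, mean_a = mean(xa), mean_b = mean(xb), diff = d,
               p_value = t$p_value, selected = sel,
               direction = if (!sel) "none" else
                 if (d > 0) "up_in_a" else "up_in_b",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Agglomerative hierarchical clustering with deterministic tie-breaks
#'
#' Average-linkage (UPGMA) agglomeration on Euclidean row distances.  At each
#' step the pair with minimal linkage distance merges; exact ties resolve to
#' the pair earliest in (row-index, row-index) order, so the result is fully
#' deterministic.  The returned leaf order places, at every merge, the
#' earlier-created cluster on the left (input order for singletons).
#'
#' @param m numeric matrix with >= 2 rows and no missing values
#' @return list with `order` (leaf indices), `labels`, `merges` (data.frame
#'   `a`, `b`, `height`; negative entries are leaves, positive entries earlier
#'   merges, as in [stats::hclust()])
#' @export
hcluster_order <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  bad <- which(!apply(m, 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop("rows with missing values: ",
         paste(if (!is.null(rownames(m))) rownames(m)[bad] else bad,
               collapse = ", "))
  d <- as.matrix(stats::dist(m))
  # active clusters: id (negative leaf / positive merge), members, creation order
  clus <- lapply(seq_len(n), function(i) list(id = -i, members = i))
  merges <- data.frame(a = integer(), b = integer(), height = numeric())
  leaf_order <- as.list(seq_len(n))
  order_of <- as.list(seq_len(n))   # leaf sequences per active cluster
  step <- 0L
  while (length(clus) > 1L) {
    best <- NULL
    for (i in seq_len(length(clus) - 1L)) {
      for (j in (i + 1L):length(clus)) {
        h <- mean(d[clus[[i]]$members, clus[[j]]$members])
        if (is.null(best) || h < best$h - 1e-12) best <- list(i = i, j = j, h = h)
      }
    }
    step <- step + 1L
    i <- best$i; j <- best$j
    merges <- rbind(merges, data.frame(a = clus[[i]]$id, b = clus[[j]]$id,
                                       height = best$h))
    new <- list(id = step, members = c(clus[[i]]$members, clus[[j]]$members))
    order_of[[i]] <- c(order_of[[i]], order_of[[j]])
    clus[[i]] <- new
    clus[[j]] <- NULL
    order_of[[j]] <- NULL
  }
  list(order = order_of[[1]],
       labels = if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(n)),
       merges = merges)
}
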