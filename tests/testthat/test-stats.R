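test_that("Mann-Whitney matches hand-computed exact cases", {
  t1 <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(t1$u, 0)
  expect_equal(t1$p_value, 1 / 3, tolerance = 1e-12)   # 2/6 labelings as extreme
  expect_identical(t1$method, "exact")
  # identical samples: U = n^2/2, p near 1
  t2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t2$u, 4.5)
  expect_gt(t2$p_value, 0.9)
  expect_error(mann_whitney(numeric(), 1), "non-empty")
  # one-sided statistics sum to n_a * n_b
  set.seed(1)
  a <- rnorm(8); b <- rnorm(11)
  t3 <- mann_whitney(a, b)
  expect_equal(t3$u + t3$u_b, 8 * 11)
})

test_that("exact p equals full enumeration for small untied samples", {
  enum_p <- function(a, b) {
    # independent brute-force oracle
    pooled <- c(a, b); na <- length(a)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    cs <- utils::combn(length(pooled), na)
    us <- apply(cs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(42)
  for (case in 1:100) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    x <- sample(seq_len(50), na + nb)   # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    t <- mann_whitney(a, b)
    expect_identical(t$method, "exact")
    expect_lt(abs(t$p_value - enum_p(a, b)), 1e-12)
  }
})

test_that("MWU is invariant under strictly monotone transforms", {
  set.seed(3)
  a <- rexp(15); b <- rexp(20) * 1.5
  t1 <- mann_whitney(a, b)
  t2 <- mann_whitney(log(a), log(b))
  t3 <- mann_whitney(a^3, b^3)
  expect_identical(t1$u, t2$u)
  expect_identical(t1$u, t3$u)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
})

test_that("genome-size contrasts compare groups, phyla, and references", {
  set.seed(8)
  n <- 50
  taxa <- data.frame(
    taxon_id = sprintf("T%03d", 1:(2 * n + 20)),
    domain = c(rep("bacteria", 2 * n), rep("archaea", 20)),
    phylum = c(rep("Proteobacteria", 2 * n), rep("Euryarchaeota", 10),
               rep("Thaumarchaeota", 10)),
    genus = NA,
    genome_size_mb = c(rlnorm(n, log(3), 0.2), rlnorm(n, log(4.5), 0.2),
                       rlnorm(10, log(3.7), 0.2), rlnorm(10, log(1.6), 0.2)),
    stringsAsFactors = FALSE)
  groups <- data.frame(taxon_id = taxa$taxon_id,
                       group = c(rep("pos-bac", n), rep("neg-bac", n),
                                 rep("pos-arch", 10), rep("neg-arch", 10)),
                       stringsAsFactors = FALSE)
  refs <- list(reference_genomes = list(Euryarchaeota = rlnorm(300, log(2.49), 0.3),
                                        Thaumarchaeota = rlnorm(300, log(1.36), 0.2)))
  res <- genome_size_contrasts(groups, taxa, refs)
  bac <- res[res$label == "pos-bac vs neg-bac", ]
  expect_lt(bac$median_a, bac$median_b)     # streamlined positive responders
  expect_true(bac$significant)
  expect_true("pos-arch vs all Euryarchaeota" %in% res$label)
  expect_true(any(grepl("within Proteobacteria", res$label)))
  expect_error(genome_size_contrasts(groups, taxa, refs, shared_phylum = "Nope"),
               "unknown phylum")
  # fewer than 3 sized taxa on one side -> skipped with a warning
  taxa2 <- taxa
  taxa2$genome_size_mb[taxa2$taxon_id %in%
                         groups$taxon_id[groups$group == "pos-arch"][1:8]] <- NA
  w2 <- testthat::capture_warnings(genome_size_contrasts(groups, taxa2, refs))
  expect_true(any(grepl("skipped", w2)))
})

test_that("lognormal separation is detected and the null is calibrated", {
  set.seed(12)
  hits <- 0
  for (r in 1:100) {
    a <- rlnorm(50, log(3), 0.3); b <- rlnorm(50, log(4.5), 0.3)
    t <- mann_whitney(a, b)
    hits <- hits + (t$p_value < 0.05 && t$median_a < t$median_b)
  }
  expect_gte(hits, 95)
  # identical distributions: rejection rate near alpha
  set.seed(13)
  rej <- mean(vapply(1:1000, function(i)
    mann_whitney(rnorm(20), rnorm(20))$p_value < 0.05, logical(1)))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("partial correlation agrees with its two formulations", {
  # reduction: both variables orthogonal to the control
  set.seed(5)
  z <- rnorm(200)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  x <- x - lm(x ~ z)$fitted; y <- y - lm(y ~ z)$fitted
  pc <- partial_corr(x, y, z)
  expect_equal(pc$r_partial, cor(x, y), tolerance = 1e-10)
  # x identical to the control -> missing with warning
  expect_warning(out <- partial_corr(z, y, z), "undefined")
  expect_true(is.na(out$r_partial))
  expect_error(partial_corr(1:3, 1:3, 1:3), ">= 4")
  # recursion equals residual-correlation on random triples
  set.seed(6)
  for (r in 1:100) {
    n <- sample(10:40, 1)
    z <- rnorm(n); x <- rnorm(n, 0.4 * z); y <- rnorm(n, -0.3 * z + 0.2 * x)
    pc <- partial_corr(x, y, z)
    rr <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
    expect_lt(abs(pc$r_partial - rr), 1e-10)
  }
})

test_that("the biomarker rule is the conjunction of its two clauses", {
  set.seed(10)
  # large difference but nonsignificant (tiny groups, huge variance)
  a <- matrix(rnorm(3 * 1, 10, 20), 3, 1, dimnames = list(NULL, "P1"))
  b <- matrix(rnorm(3 * 1, 0, 20), 3, 1, dimnames = list(NULL, "P1"))
  r1 <- biomarker_pathways(a, b)
  expect_false(r1$selected)
  # significant but below the difference threshold
  a2 <- matrix(rep(c(0.0105, 0.0106, 0.0107, 0.0108), 3), 12, 1,
               dimnames = list(NULL, "P1"))
  b2 <- matrix(rep(c(0.0100, 0.0101, 0.0102, 0.0103), 3), 12, 1,
               dimnames = list(NULL, "P1"))
  r2 <- biomarker_pathways(a2, b2)
  expect_lt(r2$p_value, 0.05)
  expect_false(r2$selected)           # |diff| = 0.0005 <= 0.001
  # threshold 0 reduces to significance alone; infinite selects nothing
  r3 <- biomarker_pathways(a2, b2, diff_threshold = 0)
  expect_true(r3$selected)
  r4 <- biomarker_pathways(a2, b2, diff_threshold = Inf)
  expect_false(r4$selected)
  # noiseless planted pair: exactly the differential pathways selected
  set.seed(11)
  pr <- simulate_group_profiles(30, 30, n_pathways = 66, diff_idx = 1:6,
                                delta = 0.01, noise_sd = 0)
  bm <- biomarker_pathways(pr$a, pr$b)
  expect_setequal(bm$pathway[bm$selected], pr$differential)
  expect_true(all(bm$direction[bm$selected] == "up_in_a"))
})

test_that("hierarchical clustering is deterministic and matches brute force", {
  # two identical rows merge first at height zero
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 9))
  hc <- hcluster_order(m)
  expect_equal(hc$merges$height[1], 0)
  expect_setequal(c(hc$merges$a[1], hc$merges$b[1]), c(-1L, -2L))
  # three collinear points at 0, 1, 10: first merge is {0, 1}
  m2 <- matrix(c(0, 1, 10), 3, 1)
  hc2 <- hcluster_order(m2)
  expect_setequal(c(hc2$merges$a[1], hc2$merges$b[1]), c(-1L, -2L))
  expect_error(hcluster_order(rbind(c(1, NA), c(1, 2))), "missing")
  # independent O(n^3) agglomerator as oracle
  brute <- function(m) {
    d <- as.matrix(stats::dist(m))
    groups <- lapply(seq_len(nrow(m)), identity)
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (j <= i) next
        h <- mean(d[groups[[i]], groups[[j]], drop = FALSE])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
      heights <- c(heights, best[1])
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    heights
  }
  set.seed(20)
  r <- matrix(rnorm(20 * 4), 20, 4)
  expect_equal(hcluster_order(r)$merges$height, brute(r), tolerance = 1e-10)
})
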