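test_that("class_mean implements the piecewise-linear response forms", {
  # continuity at the breakpoint
  expect_identical(class_mean(4, "threshold_pos",
                              list(intercept = 2, slope = 3, psi = 4)), 2)
  expect_identical(class_mean(0, "linear_neg", list(intercept = 5, slope = -1)), 5)
  expect_identical(class_mean(6, "threshold_pos",
                              list(intercept = 2, slope = 3, psi = 4)), 8)
  expect_identical(class_mean(3, "null", list(intercept = 7, slope = 0)), 7)
  # floor at zero
  expect_identical(class_mean(10, "linear_neg", list(intercept = 5, slope = -1)), 0)
  expect_error(class_mean(1, "sigmoid", list(intercept = 1, slope = 1)),
               "unknown response class")
})

test_that("noiseless limit reproduces the class means exactly", {
  cfg <- synth_config(
    counts = list(bacteria = c(linear_pos = 2L, linear_neg = 0L,
                               threshold_pos = 0L, threshold_neg = 0L, null = 0L),
                  archaea = c(linear_pos = 0L, linear_neg = 0L,
                              threshold_pos = 0L, threshold_neg = 0L, null = 0L)),
    class_params = list(
      linear_pos = list(intercept = c(10, 10), slope = c(2, 2)),
      linear_neg = list(intercept = c(1, 1), slope = c(-1, -1)),
      threshold_pos = list(intercept = c(1, 1), slope = c(1, 1), psi = 4.2),
      threshold_neg = list(intercept = c(1, 1), slope = c(-1, -1), psi = 3.4),
      null = list(intercept = c(1, 1), slope = c(0, 0))),
    abundance_noise = "none", gene_noise_sdlog = 0, seed = 9)
  gen <- generate_dataset(cfg)
  ec <- gen$dataset$samples$ec
  for (tx in rownames(gen$dataset$abundance))
    expect_equal(unname(gen$dataset$abundance[tx, ]), 10 + 2 * ec,
                 tolerance = 1e-12)
})

test_that("same seed gives byte-identical output files", {
  cfg <- synth_config(seed = 77, counts = list(
    bacteria = c(linear_pos = 5L, linear_neg = 5L, threshold_pos = 0L,
                 threshold_neg = 0L, null = 5L),
    archaea = c(linear_pos = 0L, linear_neg = 0L, threshold_pos = 5L,
                threshold_neg = 5L, null = 0L)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg)$dataset, d1)
  write_dataset(generate_dataset(cfg)$dataset, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("inconsistent slope/intercept raises a config error", {
  cfg <- synth_config(
    counts = list(bacteria = c(linear_pos = 0L, linear_neg = 1L,
                               threshold_pos = 0L, threshold_neg = 0L, null = 0L),
                  archaea = c(linear_pos = 0L, linear_neg = 0L,
                              threshold_pos = 0L, threshold_neg = 0L, null = 0L)),
    class_params = list(
      linear_pos = list(intercept = c(1, 1), slope = c(1, 1)),
      linear_neg = list(intercept = c(-5, -5), slope = c(-1, -1)),  # always < 0
      threshold_pos = list(intercept = c(1, 1), slope = c(1, 1), psi = 4.2),
      threshold_neg = list(intercept = c(1, 1), slope = c(-1, -1), psi = 3.4),
      null = list(intercept = c(1, 1), slope = c(0, 0))),
    seed = 1)
  expect_error(generate_dataset(cfg), "config error")
})

test_that("ground-truth class balance matches the requested counts", {
  cfg <- synth_config(seed = 5)
  gen <- generate_dataset(cfg)
  tab <- table(gen$truth$taxa$domain, gen$truth$taxa$class)
  for (dom in c("bacteria", "archaea"))
    for (cls in names(cfg$counts[[dom]])) {
      want <- cfg$counts[[dom]][[cls]]
      got <- if (cls %in% colnames(tab)) tab[dom, cls] else 0L
      expect_equal(unname(got), unname(want),
                   label = paste(dom, cls))
    }
  # every taxon has exactly one ground-truth record
  expect_identical(sort(gen$truth$taxa$taxon_id),
                   sort(rownames(gen$dataset$abundance)))
})

test_that("large-sample threshold class shows flat-then-linear mean", {
  # planted psi = 4.2, zero slope below, recovered by two-piece OLS
  cfg <- synth_config(
    n_samples = 10000L,
    counts = list(bacteria = c(linear_pos = 0L, linear_neg = 0L,
                               threshold_pos = 1L, threshold_neg = 0L, null = 0L),
                  archaea = c(linear_pos = 0L, linear_neg = 0L,
                              threshold_pos = 0L, threshold_neg = 0L, null = 0L)),
    class_params = list(
      linear_pos = list(intercept = c(1, 1), slope = c(1, 1)),
      linear_neg = list(intercept = c(1, 1), slope = c(-0.01, -0.01)),
      threshold_pos = list(intercept = c(20, 20), slope = c(12, 12), psi = 4.2),
      threshold_neg = list(intercept = c(1, 1), slope = c(-0.01, -0.01), psi = 3.4),
      null = list(intercept = c(1, 1), slope = c(0, 0))),
    background_gene_prob = 0,
    completeness = list(
      salt_resistance = c(pos_bac = 0, neg_bac = 0, pos_arch = 0, neg_arch = 0,
                          null_bac = 0, null_arch = 0),
      c_fixation = c(pos_bac = 0, neg_bac = 0, pos_arch = 0, neg_arch = 0,
                     null_bac = 0, null_arch = 0),
      cazyme = c(pos_bac = 0, neg_bac = 0, pos_arch = 0, neg_arch = 0,
                 null_bac = 0, null_arch = 0)),
    incomplete_presence_prob = 0,
    seed = 21)
  gen <- generate_dataset(cfg)
  ec <- gen$dataset$samples$ec
  y <- as.numeric(gen$dataset$abundance[1, ])
  left <- ec <= 4.2; right <- !left
  fl <- stats::lm(y[left] ~ ec[left])
  fr <- stats::lm(y[right] ~ ec[right])
  # flat below the break (noise floor: OLS slope se here is ~0.08)
  expect_lt(abs(stats::coef(fl)[2]), 0.3)
  expect_lt(abs(stats::coef(fl)[2]), abs(stats::coef(fr)[2]) / 20)
  expect_equal(unname(stats::coef(fr)[2]), 12, tolerance = 0.02)  # planted slope
})

test_that("planted copy numbers and mechanisms are internally consistent", {
  gen <- generate_dataset(noiseless_config(seed = 13))
  tr <- gen$truth
  # genes of absent mechanisms never receive copies
  mech_genes <- gen$dataset$catalog$mechanisms
  absent <- tr$mechanisms[!tr$mechanisms$present, ]
  for (i in seq_len(min(nrow(absent), 50))) {
    genes_i <- mech_genes$gene_id[mech_genes$mechanism_id == absent$mechanism_id[i]]
    cp <- tr$copies[tr$copies$taxon_id == absent$taxon_id[i] &
                      tr$copies$gene_id %in% genes_i, ]
    expect_identical(nrow(cp), 0L)
  }
  # planted c-acquisition copy fraction equals the group target
  cacq <- category_genes(gen$dataset$catalog, "total_c_acquisition")
  for (tx in sample(tr$taxa$taxon_id, 10)) {
    cp <- tr$copies[tr$copies$taxon_id == tx, ]
    if (!any(cp$gene_id %in% cacq) || all(cp$gene_id %in% cacq)) next
    frac <- sum(cp$copies[cp$gene_id %in% cacq]) / sum(cp$copies)
    want <- tr$c_acq_fraction[[tr$taxa$group[tr$taxa$taxon_id == tx]]]
    expect_equal(frac, unname(want), tolerance = 1e-12)
  }
})

test_that("pathway/profile simulators plant what they claim", {
  set.seed(1)
  ec <- sort(runif(37, 0.14, 13.65))
  sim <- simulate_pathway_matrix(ec, n_pathways = 20, n_signal = 3,
                                 noise_sd = 0)
  expect_identical(sim$signal, c("P001", "P002", "P003"))
  # noiseless signal columns are exactly linear in ec
  for (j in 1:3)
    expect_equal(unname(abs(cor(sim$x[, j], ec))), 1, tolerance = 1e-12)
  expect_equal(apply(sim$x[, 4:20], 2, sd), rep(0, 17), ignore_attr = TRUE)
  pr <- simulate_group_profiles(5, 7, n_pathways = 10, diff_idx = 2:3,
                                delta = 0.01, noise_sd = 0)
  expect_equal(colMeans(pr$a)[2:3] - colMeans(pr$b)[2:3], c(P002 = 0.01, P003 = 0.01))
  expect_equal(unname(colMeans(pr$a)[-(2:3)] - colMeans(pr$b)[-(2:3)]),
               rep(0, 8))
})
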