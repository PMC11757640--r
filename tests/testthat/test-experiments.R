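test_that("replicate archives are reproducible and flag failures", {
  a1 <- run_replicates("BP", 2, base_seed = 50)
  a2 <- run_replicates("BP", 2, base_seed = 50)
  expect_identical(
    lapply(a1$runs, function(r) params_to_vector(r$params)),
    lapply(a2$runs, function(r) params_to_vector(r$params))
  )
  expect_equal(vapply(a1$runs, `[[`, integer(1), "seed"), c(50L, 51L))
  # a hopeless budget yields flagged, archived, non-perfect runs
  a3 <- run_replicates("BP", 2, base_seed = 1,
                       config = bp_config(max_epochs = 3))
  expect_false(any(vapply(a3$runs, `[[`, logical(1), "perfect")))
  expect_length(perfect_networks(a3), 0)
  # every archived perfect network re-evaluates to a = 24
  d <- fixture_data()
  for (run in perfect_networks(a1)) {
    expect_equal(evaluate_network(run$params, d)$a, 24L)
  }
})

test_that("paired scans pair TE and importance on identical draws", {
  arch <- fixture_bp_archive()
  sw <- noise_sweep(levels = c(0, 1, 2), repeats = 2)
  paired <- te_importance_scan(arch, sizes = c(2, 5),
                               count_per_size = 4, sweep = sw,
                               seed = 7)
  n_perfect <- length(perfect_networks(arch))
  expect_equal(nrow(paired), n_perfect * 2 * 4)
  expect_true(all(c("te_bits", "importance") %in% names(paired)))
  # disjointness of every sampled pair
  for (i in seq_len(nrow(paired))) {
    S <- as.integer(strsplit(paired$source_nodes[i], ";")[[1]])
    expect_false(paired$target_node[i] %in% S)
    expect_length(S, paired$set_size[i])
  }
  # pairing integrity: TE-only scan with the same seed draws the same
  # subsets
  te_only <- te_importance_scan(arch, sizes = c(2, 5),
                                count_per_size = 4, seed = 7,
                                compute_importance = FALSE)
  expect_equal(te_only$source_nodes, paired$source_nodes)
  expect_equal(te_only$te_bits, paired$te_bits)
  expect_identical(paired,
                   te_importance_scan(arch, sizes = c(2, 5),
                                      count_per_size = 4, sweep = sw,
                                      seed = 7))
})

test_that("correlation_by_size recovers known dependence structures", {
  # perfectly monotone pairs
  d_mono <- data.frame(set_size = 1, te_bits = 1:40,
                       importance = (1:40)^2)
  out <- correlation_by_size(d_mono)
  expect_equal(out$rho, 1)
  expect_lt(out$p_value, 1e-6)
  # independent pairs: small rho, large p
  set.seed(10)
  d_ind <- data.frame(set_size = 2, te_bits = rnorm(1000),
                      importance = rnorm(1000))
  out2 <- correlation_by_size(d_ind)
  expect_lt(abs(out2$rho), 0.1)
  expect_gt(out2$p_value, 0.05)
  # degenerate column reported as NA
  d_deg <- data.frame(set_size = 3, te_bits = rep(1, 10),
                      importance = 1:10)
  expect_true(is.na(correlation_by_size(d_deg)$rho))
  # bonferroni column bounded by 1
  both <- correlation_by_size(rbind(d_mono, d_ind))
  expect_true(all(both$p_bonferroni <= 1))
  expect_equal(both$p_bonferroni,
               pmin(both$p_value * 2, 1))
})

test_that("set-size curves aggregate means and locate the TE peak", {
  arch <- fixture_bp_archive()
  prof <- te_importance_scan(arch, sizes = 1:15, count_per_size = 30,
                             seed = 2, compute_importance = FALSE)
  curves <- set_size_curves(prof)
  expect_equal(nrow(curves), 15)
  expect_equal(curves$set_size, 1:15)
  # plug-in TE grows with the source set on average (small slack for
  # subset-sampling noise)
  expect_true(all(diff(curves$mean_te) > -0.01))
  expect_gt(cor(curves$set_size, curves$mean_te, method = "spearman"),
            0.95)
  peak <- attr(curves, "peak_te_per_node")
  expect_equal(unname(peak["BP"]), te_peak_size(prof, "BP"))
  expect_true(peak["BP"] %in% 1:15)
})

test_that("weight reports compare distributions between methods", {
  fake_archive <- function(method, mats) {
    runs <- lapply(mats, function(m) {
      p <- rnn_params(matrix(0, 16, 4), m, matrix(0, 8, 16),
                      numeric(16), numeric(8))
      list(params = p, perfect = TRUE)
    })
    structure(list(method = method, runs = runs),
              class = "replicate_archive")
  }
  m1 <- matrix(rnorm(256), 16, 16)
  # identical pooled samples: KS statistic 0
  rep_same <- weight_distribution_report(fake_archive("GA", list(m1)),
                                         fake_archive("BP", list(m1)))
  expect_equal(rep_same$ks_statistic, 0)
  # disjoint supports: KS statistic 1
  m2 <- matrix(rnorm(256) + 100, 16, 16)
  rep_disj <- weight_distribution_report(fake_archive("GA", list(m1)),
                                         fake_archive("BP", list(m2)))
  expect_equal(rep_disj$ks_statistic, 1)
  expect_lt(rep_disj$ks_p_value, 1e-10)
  # rank curves are sorted and one per network
  expect_true(all(tapply(rep_same$rank_curves$weight,
                         rep_same$rank_curves$method,
                         function(w) !is.unsorted(w))))
  # real archives differ but overlap
  arch_ga <- fixture_ga_archive()
  arch_bp <- fixture_bp_archive()
  repr <- weight_distribution_report(arch_ga, arch_bp)
  expect_gt(repr$ks_statistic, 0)
  expect_lt(repr$ks_statistic, 1)
})

test_that("build_report writes figures, tables and a manifest", {
  arch <- fixture_bp_archive()
  sw <- noise_sweep(levels = c(0, 2), repeats = 2)
  paired <- te_importance_scan(arch, sizes = c(1, 2),
                               count_per_size = 3, sweep = sw,
                               seed = 4)
  wrep <- weight_distribution_report(fixture_ga_archive(), arch)
  out <- file.path(tempdir(), "rnnflow-report-test")
  manifest <- build_report(out, paired, wrep, seed = 4)
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(file.exists(file.path(out, "paired_scan.tsv")))
  expect_true(file.exists(file.path(out, "set_size_curves.tsv")))
  expect_true(file.exists(file.path(out, "te_vs_importance.pdf")))
  expect_equal(manifest$n_rows_paired, nrow(paired))
  back <- read.table(file.path(out, "paired_scan.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(back), nrow(paired))
  expect_error(build_report(out, paired[0, ], wrep), "empty")
  unlink(out, recursive = TRUE)
})
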