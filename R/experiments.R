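#' Train replicate networks
#'
#' Runs `n_replicates` independent training runs (seeds `base_seed`,
#' `base_seed + 1`, ...) with the given trainer configuration.
#' Replicates that never reach 24/24 within budget are archived but
#' flagged, and downstream analyses use only the perfect ones.
#'
#' @param method `"GA"` or `"BP"`.
#' @param n_replicates Number of replicates.
#' @param base_seed Seed of the first replicate.
#' @param config A [ga_config()] or [bp_config()]; its `seed` field is
#'   overridden per replicate. Defaults to the method's standard
#'   configuration.
#' @return Object of class `replicate_archive`: list with `method` and
#'   `runs` (a list of `training_run`s, each carrying its `seed`).
#' @export
run_replicates <- function(method = c("GA", "BP"), n_replicates,
                           base_seed, config = NULL) {
  method <- match.arg(method)
  if (is.null(config)) {
    config <- if (method == "GA") ga_config() else bp_config()
  }
  data <- acp_dataset()
  runs <- lapply(seq_len(n_replicates), function(i) {
    config$seed <- as.integer(base_seed + i - 1L)
    run <- if (method == "GA") {
      evolve(config, data)
    } else {
      train_bp(config, data)
    }
    run$seed <- config$seed
    run
  })
  structure(list(method = method, runs = runs),
            class = "replicate_archive")
}

#' @export
print.replicate_archive <- function(x, ...) {
  np <- sum(vapply(x$runs, `[[`, logical(1), "perfect"))
  cat(sprintf("%s replicate archive: %d runs, %d perfect\n",
              x$method, length(x$runs), np))
  invisible(x)
}

#' Extract the perfect networks of an archive
#'
#' @param archive A [run_replicates()] archive.
#' @return List of `training_run`s whose terminal network classifies
#'   all 24 episodes correctly.
#' @export
perfect_networks <- function(archive) {
  stopifnot(inherits(archive, "replicate_archive"))
  Filter(function(r) isTRUE(r$perfect), archive$runs)
}

#' Paired transfer-entropy / importance scan
#'
#' For every perfect network in the archive and every source-set size,
#' samples random (S, j) pairs and computes both the set transfer
#' entropy of the binarized recurrent trace and (optionally) the
#' noise-perturbation importance of the same weight group, on the same
#' pair draws, guaranteeing the pairing of the two measures.
#'
#' @param archive A [run_replicates()] archive with at least one
#'   perfect network.
#' @param sizes Source-set sizes (default 1..15).
#' @param count_per_size Pairs per size per network.
#' @param sweep A [noise_sweep()] for the importance half; ignored
#'   when `compute_importance = FALSE`.
#' @param seed Integer master seed; per-network substreams are derived
#'   from it.
#' @param compute_importance Set `FALSE` to scan transfer entropy only
#'   (much faster; used when only the information side is needed).
#' @return Data frame with one row per (network, pair): `network_id`,
#'   `method`, `seed`, `set_size`, `source_nodes`, `target_node`,
#'   `te_bits`, `te_per_node`, and when importance is computed,
#'   `mean_rel_perf` and `importance`.
#' @export
te_importance_scan <- function(archive, sizes = 1:15,
                               count_per_size = 100,
                               sweep = noise_sweep(), seed = 1L,
                               compute_importance = TRUE) {
  perfect <- perfect_networks(archive)
  if (length(perfect) == 0) {
    stop("te_importance_scan: archive contains no perfect network")
  }
  data <- acp_dataset()
  out <- do.call(rbind, lapply(seq_along(perfect), function(ni) {
    run <- perfect[[ni]]
    bt <- binarize(record_traces(run$params, data))
    sub_seed <- (as.integer(seed) * 1000L + ni) %% .Machine$integer.max
    # all subsets are drawn before any importance computation so that
    # scans with and without the importance half sample identical
    # pairs under the same seed
    pairs_by_size <- with_seed(sub_seed, lapply(sizes, function(sz) {
      sample_pairs(sz, count_per_size)
    }))
    do.call(rbind, lapply(seq_along(sizes), function(si) {
      sz <- sizes[si]
      pairs <- pairs_by_size[[si]]
      te <- vapply(pairs, function(p) te_for_pair(bt, p), numeric(1))
      block <- data.frame(
        network_id = ni, method = archive$method,
        seed = run$seed, set_size = sz,
        source_nodes = vapply(pairs, function(p) {
          paste(p$S, collapse = ";")
        }, character(1)),
        target_node = vapply(pairs, function(p) p$j, integer(1)),
        te_bits = te, te_per_node = te / sz
      )
      if (compute_importance) {
        imp_seed <- (sub_seed + 7L * si) %% .Machine$integer.max
        imp <- set_importance_for_pairs(run$params, pairs, sweep,
                                        data, seed = imp_seed)
        block$mean_rel_perf <- imp$mean_rel_perf
        block$importance <- imp$importance
      }
      block
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Spearman correlation between transfer entropy and importance
#'
#' Within each source-set size, rank-correlates `te_bits` against
#' `importance` across all sampled subsets (pooled over networks),
#' two-sided, without assuming normality of either axis. Raw p-values
#' are reported alongside a Bonferroni-adjusted column for
#' transparency.
#'
#' @param paired A [te_importance_scan()] table containing an
#'   `importance` column.
#' @return Data frame per size: `set_size`, `n`, `rho`, `p_value`,
#'   `p_bonferroni`. Sizes with a constant column yield `NA` rho.
#' @export
correlation_by_size <- function(paired) {
  stopifnot(all(c("set_size", "te_bits", "importance") %in%
                  names(paired)))
  sizes <- sort(unique(paired$set_size))
  out <- do.call(rbind, lapply(sizes, function(sz) {
    d <- paired[paired$set_size == sz, ]
    if (nrow(d) < 3 || sd(d$te_bits) == 0 || sd(d$importance) == 0) {
      return(data.frame(set_size = sz, n = nrow(d), rho = NA_real_,
                        p_value = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(d$te_bits, d$importance, method = "spearman",
               exact = FALSE)
    )
    data.frame(set_size = sz, n = nrow(d),
               rho = unname(ct$estimate), p_value = ct$p.value)
  }))
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out
}

#' Per-size means of transfer entropy and importance
#'
#' Aggregates a paired scan into per-set-size means with standard
#' errors (across all subsets and networks) and reports, per method,
#' the set size at which the mean per-node transfer entropy peaks.
#'
#' @param paired A [te_importance_scan()] table (one or both methods).
#' @return Data frame per (method, set_size) with `mean_te`, `se_te`,
#'   `mean_te_per_node`, `se_te_per_node`, and when available
#'   `mean_importance`, `se_importance`; attribute `peak_te_per_node`
#'   is a named integer vector of the argmax size per method.
#' @export
set_size_curves <- function(paired) {
  se <- function(x) sd(x) / sqrt(length(x))
  groups <- split(paired, list(paired$method, paired$set_size),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(d) {
    row <- data.frame(
      method = d$method[1], set_size = d$set_size[1],
      n = nrow(d),
      mean_te = mean(d$te_bits), se_te = se(d$te_bits),
      mean_te_per_node = mean(d$te_per_node),
      se_te_per_node = se(d$te_per_node)
    )
    if ("importance" %in% names(d)) {
      row$mean_importance <- mean(d$importance)
      row$se_importance <- se(d$importance)
    }
    row
  }))
  out <- out[order(out$method, out$set_size), ]
  rownames(out) <- NULL
  peaks <- vapply(split(out, out$method), function(d) {
    as.integer(d$set_size[which.max(d$mean_te_per_node)])
  }, integer(1))
  attr(out, "peak_te_per_node") <- peaks
  out
}

#' Set size with maximal per-node transfer entropy
#'
#' @param paired A [te_importance_scan()] table.
#' @param method Optional method filter (`"GA"` or `"BP"`).
#' @return Integer set size at which the mean `te_per_node` is
#'   maximal.
#' @export
te_peak_size <- function(paired, method = NULL) {
  if (!is.null(method)) paired <- paired[paired$method == method, ]
  if (nrow(paired) == 0) stop("te_peak_size: no rows after filtering")
  m <- tapply(paired$te_per_node, paired$set_size, mean)
  as.integer(names(m)[which.max(m)])
}

#' Compare recurrent-weight distributions between methods
#'
#' Pools the recurrent matrix `M` of every perfect network per method,
#' compares the two pooled samples with a two-sample
#' Kolmogorov-Smirnov test, and builds per-network rank-sorted weight
#' curves.
#'
#' @param archive_ga,archive_bp [run_replicates()] archives for the
#'   two methods (order free; methods are read from the archives).
#' @param all_weights Pool every parameter rather than only `M`.
#' @return Object of class `weight_report`: list with `weights` (long
#'   data frame `method`, `network_id`, `weight`), `ks_statistic`,
#'   `ks_p_value`, and `rank_curves` (`method`, `network_id`, `rank`,
#'   `weight`).
#' @export
weight_distribution_report <- function(archive_ga, archive_bp,
                                       all_weights = FALSE) {
  pool <- function(archive) {
    perfect <- perfect_networks(archive)
    if (length(perfect) == 0) {
      stop("weight_distribution_report: archive for ", archive$method,
           " contains no perfect network")
    }
    do.call(rbind, lapply(seq_along(perfect), function(i) {
      p <- perfect[[i]]$params
      w <- if (all_weights) params_to_vector(p) else as.vector(p$M)
      data.frame(method = archive$method, network_id = i, weight = w)
    }))
  }
  weights <- rbind(pool(archive_ga), pool(archive_bp))
  methods <- unique(weights$method)
  if (length(methods) != 2) {
    stop("weight_distribution_report: need archives of two methods")
  }
  ks <- suppressWarnings(ks.test(
    weights$weight[weights$method == methods[1]],
    weights$weight[weights$method == methods[2]]
  ))
  rank_curves <- do.call(rbind, lapply(
    split(weights, list(weights$method, weights$network_id),
          drop = TRUE),
    function(d) {
      data.frame(method = d$method[1], network_id = d$network_id[1],
                 rank = seq_len(nrow(d)), weight = sort(d$weight))
    }
  ))
  rownames(rank_curves) <- NULL
  structure(
    list(weights = weights, ks_statistic = unname(ks$statistic),
         ks_p_value = ks$p.value, rank_curves = rank_curves),
    class = "weight_report"
  )
}

#' @export
print.weight_report <- function(x, ...) {
  cat(sprintf(
    "Weight distribution report: %d pooled weights, KS D = %.4f (p = %.4g)\n",
    nrow(x$weights), x$ks_statistic, x$ks_p_value
  ))
  invisible(x)
}
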