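#' Noise sweep schedule
#'
#' The importance of a weight group is measured by sweeping the upper
#' bound `r` of the one-sided uniform perturbation over 21 levels from
#' 0 (no perturbation) to 4.0 in steps of 0.2, with several repeated
#' evaluations per level.
#'
#' @param levels Strictly increasing vector of upper bounds; the first
#'   must be exactly 0.
#' @param repeats Evaluations per level.
#' @return A `noise_sweep` list.
#' @export
noise_sweep <- function(levels = seq(0, 4, by = 0.2), repeats = 10L) {
  stopifnot(levels[1] == 0, all(diff(levels) > 0), repeats >= 1)
  structure(list(levels = as.numeric(levels),
                 repeats = as.integer(repeats)),
            class = "noise_sweep")
}

# internal: matrix [levels x repeats] of perturbed fitness w-tilde
noisy_w_matrix <- function(params, targets, levels, repeats, data,
                           sharing = "independent") {
  targets <- matrix(as.integer(targets), ncol = 2)
  cpp_noise_sweep_w(
    params_to_vector(params), input_cube(data), data$targets,
    targets[, 1] - 1L, targets[, 2] - 1L,
    as.numeric(levels), as.integer(repeats), sharing == "shared"
  )
}

#' Mean relative performance under weight noise
#'
#' Evaluates the network `repeats` times on the full episode set while
#' the targeted entries of `M` are shifted by fresh `U[0, r]` draws at
#' every update, and returns the mean of the perturbed fitness
#' relative to the unperturbed fitness, `mean(w-tilde / w0)`.
#'
#' @param params An `rnn_params`.
#' @param targets Two-column matrix of 1-based `(row, col)` indices
#'   into `M` (see [noise_spec()]).
#' @param r Upper bound of the uniform offset.
#' @param repeats Number of repeated evaluations.
#' @param data An [acp_dataset()].
#' @param seed Optional integer seed.
#' @param sharing `"independent"` (default) or `"shared"` offsets.
#' @return Mean relative performance (1 when `r = 0` or `targets` is
#'   empty).
#' @export
perturbed_performance <- function(params, targets, r, repeats, data,
                                  seed = NULL,
                                  sharing = "independent") {
  stopifnot(r >= 0)
  targets <- matrix(as.integer(targets), ncol = 2)
  w0 <- evaluate_network(params, data)$w
  if (w0 <= 0) {
    stop("perturbed_performance: unperturbed fitness w0 <= 0; ",
         "relative performance is undefined for this network")
  }
  if (r == 0 || nrow(targets) == 0) return(1)
  wt <- with_seed(seed, noisy_w_matrix(params, targets, r, repeats,
                                       data, sharing))
  mean(wt / w0)
}

#' Importance of a weight group
#'
#' Sweeps the noise bound over all levels of a [noise_sweep()],
#' recording the mean relative performance `Wbar(r)` at each level;
#' the scalar `Wbar` averages uniformly over levels and repeats, and
#' the importance is `I = 1 - Wbar`. An unimportant weight leaves
#' performance untouched (`I` near 0); a crucial one collapses it
#' (`I` near 1).
#'
#' @inheritParams perturbed_performance
#' @param sweep A [noise_sweep()].
#' @return Object of class `importance_record`: list with `levels`,
#'   `rel_perf` (mean relative performance per level), `W_bar`, `I`,
#'   `targets`.
#' @export
importance <- function(params, targets, sweep, data, seed = NULL,
                       sharing = "independent") {
  stopifnot(inherits(sweep, "noise_sweep"))
  targets <- matrix(as.integer(targets), ncol = 2)
  w0 <- evaluate_network(params, data)$w
  if (w0 <= 0) {
    stop("importance: unperturbed fitness w0 <= 0; ",
         "relative performance is undefined for this network")
  }
  if (nrow(targets) == 0) {
    rel <- rep(1, length(sweep$levels))
  } else {
    wt <- with_seed(seed, noisy_w_matrix(params, targets,
                                         sweep$levels, sweep$repeats,
                                         data, sharing))
    rel <- rowMeans(wt) / w0
    rel[sweep$levels == 0] <- 1  # r = 0 is exact, not sampled
  }
  W_bar <- mean(rel)
  structure(
    list(levels = sweep$levels, rel_perf = rel, W_bar = W_bar,
         I = 1 - W_bar, targets = targets),
    class = "importance_record"
  )
}

#' @export
print.importance_record <- function(x, ...) {
  cat(sprintf(
    "Importance of %d weight(s): I = %.4f (mean rel. perf. %.4f over %d noise levels)\n",
    nrow(x$targets), x$I, x$W_bar, length(x$levels)
  ))
  invisible(x)
}

#' Single-weight importance matrix
#'
#' Runs [importance()] for every singleton entry of the 16 x 16
#' recurrent matrix.
#'
#' @inheritParams importance
#' @return 16 x 16 matrix of importance values `I[i, j]` for the
#'   weight from node `j` onto node `i`, with attribute `curves` (an
#'   array `[16, 16, n_levels]` of per-level mean relative
#'   performance).
#' @export
importance_matrix <- function(params, sweep, data, seed = NULL) {
  stopifnot(inherits(sweep, "noise_sweep"))
  w0 <- evaluate_network(params, data)$w
  if (w0 <= 0) {
    stop("importance_matrix: unperturbed fitness w0 <= 0; ",
         "relative performance is undefined for this network")
  }
  res <- matrix(NA_real_, N_HID, N_HID)
  curves <- array(NA_real_, c(N_HID, N_HID, length(sweep$levels)))
  with_seed(seed, {
    for (i in seq_len(N_HID)) {
      for (j in seq_len(N_HID)) {
        rec <- importance(params, cbind(i, j), sweep, data)
        res[i, j] <- rec$I
        curves[i, j, ] <- rec$rel_perf
      }
    }
  })
  attr(res, "curves") <- curves
  res
}

#' Set importance for sampled source/target pairs
#'
#' For each pair (S, j) all weights from the nodes of S onto j --
#' row `j`, columns `S` of `M` -- are perturbed simultaneously under
#' the same noise regime, and the group importance is recorded. Using
#' the same pairs that fed the transfer-entropy computation guarantees
#' the TE/importance pairing of the scans.
#'
#' @param params An `rnn_params`.
#' @param pairs List of [st_pair()]s (e.g. from [sample_pairs()]).
#' @param sweep A [noise_sweep()].
#' @param data An [acp_dataset()].
#' @param seed Optional integer seed.
#' @param sharing `"independent"` (default) or `"shared"`.
#' @return Data frame aligned one-to-one with `pairs`: `set_size`,
#'   `source_nodes`, `target_node`, `mean_rel_perf`, `importance`.
#' @export
set_importance_for_pairs <- function(params, pairs, sweep, data,
                                     seed = NULL,
                                     sharing = "independent") {
  stopifnot(all(vapply(pairs, inherits, logical(1), "st_pair")))
  with_seed(seed, do.call(rbind, lapply(pairs, function(p) {
    rec <- importance(params, cbind(p$j, p$S), sweep, data,
                      sharing = sharing)
    data.frame(
      set_size = length(p$S),
      source_nodes = paste(p$S, collapse = ";"),
      target_node = p$j,
      mean_rel_perf = rec$W_bar,
      importance = rec$I
    )
  })))
}
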