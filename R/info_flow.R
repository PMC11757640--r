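#' Binarize a recorded state trace at the per-node median
#'
#' Each node's median is taken over all 96 recorded states (24
#' episodes x 4 timesteps pooled); a state strictly above the median
#' becomes 1, anything at or below becomes 0. For continuous
#' activations this makes each node's marginal entropy (nearly)
#' maximal. A node whose recorded series is constant binarizes to all
#' zeros and is flagged as degenerate.
#'
#' @param trace A [record_traces()] object.
#' @return Object of class `binary_trace`: list with `bits` (integer
#'   array `[24, 4, 16]`), `medians` (length 16), `degenerate`
#'   (logical 16), and the binarized transition endpoints `from`, `to`
#'   (72 x 16 integer matrices) with `episode` indices.
#' @export
binarize <- function(trace) {
  stopifnot(inherits(trace, "state_trace"))
  d <- dim(trace$states)
  flat <- matrix(trace$states, d[1] * d[2], d[3])  # 96 x 16
  medians <- apply(flat, 2, median)
  degenerate <- apply(flat, 2, function(s) max(s) == min(s))
  bits <- array(0L, d)
  for (j in seq_len(d[3])) {
    bits[, , j] <- (trace$states[, , j] > medians[j]) * 1L
  }
  from <- (trace$from > rep(medians, each = nrow(trace$from))) * 1L
  to <- (trace$to > rep(medians, each = nrow(trace$to))) * 1L
  structure(
    list(bits = bits, medians = medians, degenerate = degenerate,
         from = from, to = to, episode = trace$episode),
    class = "binary_trace"
  )
}

#' Source set / target node pair
#'
#' A transfer-entropy measurement runs from a nonempty set `S` of 1 to
#' 15 recurrent nodes to a single target node `j` not contained in
#' `S`; source and target must be disjoint and nonempty.
#'
#' @param S Integer vector of source node indices (1-based, 1..16).
#' @param j Single target node index, not in `S`.
#' @return Object of class `st_pair`.
#' @export
st_pair <- function(S, j) {
  S <- sort(unique(as.integer(S)))
  j <- as.integer(j)
  if (length(S) < 1 || length(S) > N_HID - 1) {
    stop("st_pair: source set must contain 1..15 nodes")
  }
  if (any(S < 1) || any(S > N_HID) || j < 1 || j > N_HID) {
    stop("st_pair: node indices must lie in 1..16")
  }
  if (j %in% S) stop("st_pair: source set and target must be disjoint")
  structure(list(S = S, j = j), class = "st_pair")
}

#' Empirical joint distribution over a transition triple
#'
#' Plug-in frequencies of the triple (target next state, target
#' current state, joint source state) over the 72 within-episode
#' transitions of a binarized trace. The joint source state of `k`
#' nodes is encoded as an integer 0..2^k - 1 (first source node =
#' least significant bit).
#'
#' @param bt A [binarize()]d trace.
#' @param pair An [st_pair()].
#' @return Data frame of class `te_table` with columns `x_next`,
#'   `x_self` (0/1), `s` (source code), `count` and `p`; probabilities
#'   sum to 1.
#' @export
joint_distribution <- function(bt, pair) {
  stopifnot(inherits(bt, "binary_trace"), inherits(pair, "st_pair"))
  k <- length(pair$S)
  s_code <- as.vector(
    bt$from[, pair$S, drop = FALSE] %*% 2^(seq_len(k) - 1)
  )
  x_self <- bt$from[, pair$j]
  x_next <- bt$to[, pair$j]
  key <- paste(x_next, x_self, s_code)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  out <- data.frame(
    x_next = as.integer(parts[, 1]),
    x_self = as.integer(parts[, 2]),
    s = as.numeric(parts[, 3]),
    count = as.integer(tab)
  )
  out$p <- out$count / sum(out$count)
  out <- out[order(out$x_next, out$x_self, out$s), ]
  rownames(out) <- NULL
  class(out) <- c("te_table", "data.frame")
  out
}

#' Plug-in transfer entropy from a probability table
#'
#' Evaluates, in bits, the Markovian (history length 1) transfer
#' entropy
#' `TE = sum p(x', x, s) log2[ p(x' | x, s) / p(x' | x) ]`
#' with the convention `0 log 0 = 0`. Cells with zero probability
#' contribute nothing; conditionals are formed from the table's own
#' marginals, so the estimate is the plug-in (maximum-likelihood)
#' value with no bias correction.
#'
#' @param table A [joint_distribution()] table (or any data frame with
#'   columns `x_next`, `x_self`, `s`, `p` summing to 1).
#' @return Nonnegative transfer entropy in bits.
#' @export
transfer_entropy <- function(table) {
  stopifnot(all(c("x_next", "x_self", "s", "p") %in% names(table)))
  if (abs(sum(table$p) - 1) > 1e-9) {
    stop("transfer_entropy: probabilities do not sum to 1")
  }
  tb <- table[table$p > 0, , drop = FALSE]
  # marginals by aggregation over the table itself
  key_xs <- paste(tb$x_self, tb$s)
  p_xs <- tapply(tb$p, key_xs, sum)  # p(x_t, s_t)
  p_x <- tapply(tb$p, tb$x_self, sum)  # p(x_t)
  key_nx <- paste(tb$x_next, tb$x_self)
  p_nx <- tapply(tb$p, key_nx, sum)  # p(x_{t+1}, x_t)
  cond_full <- tb$p / p_xs[key_xs]
  cond_self <- p_nx[key_nx] / p_x[as.character(tb$x_self)]
  te <- sum(tb$p * log2(cond_full / cond_self))
  max(te, 0)
}

#' Transfer entropy for a source/target pair
#'
#' Computes the same plug-in value as [transfer_entropy()] applied to
#' [joint_distribution()], through a vectorized counting path (joint
#' states encoded as integers and tabulated) that makes large scans
#' cheap.
#'
#' @inheritParams joint_distribution
#' @return Transfer entropy in bits.
#' @export
te_for_pair <- function(bt, pair) {
  stopifnot(inherits(bt, "binary_trace"), inherits(pair, "st_pair"))
  k <- length(pair$S)
  s_code <- as.integer(
    bt$from[, pair$S, drop = FALSE] %*% 2^(seq_len(k) - 1)
  )
  # cell index: s + 2^k * x_self + 2^(k+1) * x_next
  key <- 1L + s_code + bitwShiftL(bt$from[, pair$j], k) +
    bitwShiftL(bt$to[, pair$j], k + 1L)
  counts <- array(tabulate(key, nbins = 2^(k + 2)), c(2^k, 2, 2))
  N <- sum(counts)
  n_xs <- counts[, , 1] + counts[, , 2]          # (s, x_self)
  n_xx <- apply(counts, c(2, 3), sum)            # (x_self, x_next)
  n_x <- rowSums(n_xx)                           # (x_self)
  te <- 0
  for (x1 in 1:2) {
    cell <- counts[, , x1]                       # (s, x_self)
    pos <- cell > 0
    if (!any(pos)) next
    cond_full <- cell[pos] / n_xs[pos]
    cond_self <- (n_xx[, x1] / n_x)[col(cell)[pos]]
    te <- te + sum(cell[pos] / N * log2(cond_full / cond_self))
  }
  max(te, 0)
}

#' Sample random source-set / target pairs
#'
#' `S` is drawn uniformly without replacement from the 16 recurrent
#' nodes; the target is drawn uniformly from the remaining nodes.
#' Duplicate pairs across draws are permitted.
#'
#' @param set_size Size of the source set, 1..15.
#' @param count Number of pairs to draw.
#' @param seed Optional integer seed (the caller's RNG stream is left
#'   untouched if given).
#' @return List of `count` [st_pair()] objects.
#' @export
sample_pairs <- function(set_size, count, seed = NULL) {
  set_size <- as.integer(set_size)
  if (set_size < 1 || set_size > N_HID - 1) {
    stop("sample_pairs: set_size must lie in 1..15")
  }
  with_seed(seed, lapply(seq_len(count), function(i) {
    S <- resample(seq_len(N_HID), set_size)
    j <- resample(setdiff(seq_len(N_HID), S), 1)
    st_pair(S, j)
  }))
}

#' Transfer-entropy profile across source-set sizes
#'
#' Binarizes a trace once, then for every requested set size samples
#' random pairs and computes the set transfer entropy and its
#' per-source-node normalization `TE / |S|`.
#'
#' @param trace A [record_traces()] object or an already
#'   [binarize()]d trace.
#' @param sizes Source-set sizes to profile (default 1..15).
#' @param count_per_size Pairs sampled per size.
#' @param seed Optional integer seed for the pair sampling.
#' @return Data frame with one row per sampled pair: `set_size`,
#'   `source_nodes` (semicolon-joined 1-based indices),
#'   `target_node`, `te_bits`, `te_per_node`.
#' @export
te_profile <- function(trace, sizes = 1:15, count_per_size = 100,
                       seed = NULL) {
  bt <- if (inherits(trace, "binary_trace")) trace else binarize(trace)
  with_seed(seed, do.call(rbind, lapply(sizes, function(sz) {
    pairs <- sample_pairs(sz, count_per_size)
    te <- vapply(pairs, function(p) te_for_pair(bt, p), numeric(1))
    data.frame(
      set_size = sz,
      source_nodes = vapply(pairs, function(p) {
        paste(p$S, collapse = ";")
      }, character(1)),
      target_node = vapply(pairs, function(p) p$j, integer(1)),
      te_bits = te, te_per_node = te / sz
    )
  })))
}
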