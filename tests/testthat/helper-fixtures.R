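# Shared fixtures. Everything is generated in code; the trained
# archives are computed lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_data <- function() cached("data", acp_dataset())

with_seed_helper <- function(seed, code) rnnflow:::with_seed(seed, code)

# a quickly trained perfect network (BP converges in well under a
# second), for tests that need realistic trained dynamics
fixture_perfect_net <- function() {
  cached("perfect_net", {
    run <- train_bp(bp_config(seed = 42), fixture_data())
    stopifnot(run$perfect)
    run$params
  })
}

# desk-scale replicate archives (10 runs) at the study conditions,
# keyed by method and base seed
fixture_archive <- function(method, base_seed = 1) {
  cached(paste0("archive_", method, "_", base_seed),
         run_replicates(method, 10, base_seed = base_seed))
}
fixture_ga_archive <- function() fixture_archive("GA", 1)
fixture_bp_archive <- function() fixture_archive("BP", 1)

# build a synthetic state_trace with record_traces' conventions from a
# states array [episodes, timesteps, nodes]
synthetic_trace <- function(states) {
  n <- dim(states)[1]
  tt <- dim(states)[2]
  from <- do.call(rbind, lapply(seq_len(n),
                                function(e) states[e, 1:(tt - 1), ]))
  to <- do.call(rbind, lapply(seq_len(n),
                              function(e) states[e, 2:tt, ]))
  structure(
    list(states = states, from = from, to = to,
         episode = rep(seq_len(n), each = tt - 1)),
    class = "state_trace"
  )
}

# a synthetic binary_trace directly from 0/1 transition matrices
synthetic_binary_trace <- function(from, to) {
  structure(
    list(bits = NULL, medians = rep(0.5, ncol(from)),
         degenerate = rep(FALSE, ncol(from)),
         from = from, to = to,
         episode = seq_len(nrow(from))),
    class = "binary_trace"
  )
}

# Independent brute-force transfer entropy: enumerates every joint
# state of (target next, target now, source set now) and sums the
# log-ratio term by term from raw sample frequencies. Used only as an
# oracle; shares no code with transfer_entropy().
oracle_te <- function(bt, S, j) {
  xs <- bt$from[, j]
  xn <- bt$to[, j]
  smat <- bt$from[, S, drop = FALSE]
  k <- length(S)
  te <- 0
  for (xnext in 0:1) {
    for (xself in 0:1) {
      for (scode in 0:(2^k - 1)) {
        sbits <- as.integer(intToBits(scode))[seq_len(k)]
        sel <- apply(smat, 1, function(r) all(r == sbits))
        p_xyz <- mean(xn == xnext & xs == xself & sel)
        if (p_xyz == 0) next
        p_xz <- mean(xs == xself & sel)
        p_xy <- mean(xn == xnext & xs == xself)
        p_x <- mean(xs == xself)
        te <- te + p_xyz * log2((p_xyz / p_xz) / (p_xy / p_x))
      }
    }
  }
  te
}
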