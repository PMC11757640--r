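#' Construct the parameter set of the 4-16-8 Elman network
#'
#' The network has 4 sensor inputs, a fully connected recurrent layer
#' of 16 tanh nodes whose previous activations feed back through the
#' 16 x 16 recurrent weight matrix `M`, and 8 tanh output nodes, one
#' per stimulus category. Recurrent and output nodes carry biases;
#' sensors do not.
#'
#' @param W_in 16 x 4 input-to-recurrent weight matrix.
#' @param M 16 x 16 recurrent weight matrix, entry `M[i, j]` being the
#'   weight from node `j` onto node `i` (row = target, column =
#'   source).
#' @param W_out 8 x 16 recurrent-to-output weight matrix.
#' @param b_h Length-16 recurrent bias vector.
#' @param b_o Length-8 output bias vector.
#' @return An object of class `rnn_params`.
#' @export
rnn_params <- function(W_in, M, W_out, b_h, b_o) {
  stopifnot(
    is.matrix(W_in), all(dim(W_in) == c(N_HID, N_IN)),
    is.matrix(M), all(dim(M) == c(N_HID, N_HID)),
    is.matrix(W_out), all(dim(W_out) == c(N_OUT, N_HID)),
    length(b_h) == N_HID, length(b_o) == N_OUT
  )
  vals <- c(W_in, M, W_out, b_h, b_o)
  if (!all(is.finite(vals))) stop("rnn_params: non-finite entries")
  structure(
    list(W_in = W_in, M = M, W_out = W_out,
         b_h = as.numeric(b_h), b_o = as.numeric(b_o)),
    class = "rnn_params"
  )
}

#' @export
print.rnn_params <- function(x, ...) {
  cat("Elman RNN parameters (4-16-8),", N_PAR, "values\n")
  cat(sprintf("  |W_in| max %.3f, |M| max %.3f, |W_out| max %.3f\n",
              max(abs(x$W_in)), max(abs(x$M)), max(abs(x$W_out))))
  invisible(x)
}

#' Randomly initialize a network
#'
#' Weights are drawn from zero-mean Gaussians with fan-in-scaled
#' standard deviations; biases start at zero. `"kaiming"` uses
#' `sd = sqrt(2 / fan_in)`; `"xavier"` uses
#' `sd = sqrt(2 / (fan_in + fan_out))`.
#'
#' @param seed Integer seed; the draw is deterministic given the seed
#'   and does not disturb the caller's RNG stream. `NULL` draws from
#'   the ambient stream.
#' @param scheme `"kaiming"` (default) or `"xavier"`.
#' @return An `rnn_params` object.
#' @export
#' @examples
#' p <- init_network(seed = 1)
#' sd(p$M)  # close to sqrt(2/16)
init_network <- function(seed = NULL, scheme = c("kaiming", "xavier")) {
  scheme <- match.arg(scheme)
  sds <- switch(scheme,
    kaiming = c(sqrt(2 / N_IN), sqrt(2 / N_HID), sqrt(2 / N_HID)),
    xavier = c(sqrt(2 / (N_IN + N_HID)), sqrt(2 / (N_HID + N_HID)),
               sqrt(2 / (N_HID + N_OUT)))
  )
  with_seed(seed, rnn_params(
    W_in = matrix(rnorm(N_HID * N_IN, 0, sds[1]), N_HID, N_IN),
    M = matrix(rnorm(N_HID * N_HID, 0, sds[2]), N_HID, N_HID),
    W_out = matrix(rnorm(N_OUT * N_HID, 0, sds[3]), N_OUT, N_HID),
    b_h = numeric(N_HID), b_o = numeric(N_OUT)
  ))
}

#' Flatten network parameters to a genome vector (and back)
#'
#' The flat layout is `c(W_in, M, W_out, b_h, b_o)` with each matrix
#' in R's column-major order: 472 values in all. This is the genome
#' representation the genetic algorithm mutates and the layout the
#' text serialization and the compiled evaluation kernels share.
#'
#' @param params An `rnn_params` object.
#' @return `params_to_vector`: numeric vector of length 472.
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "rnn_params"))
  c(params$W_in, params$M, params$W_out, params$b_h, params$b_o)
}

#' @rdname params_to_vector
#' @param v Numeric vector of length 472.
#' @return `vector_to_params`: the corresponding `rnn_params`.
#' @export
vector_to_params <- function(v) {
  stopifnot(length(v) == N_PAR)
  i1 <- N_HID * N_IN
  i2 <- i1 + N_HID * N_HID
  i3 <- i2 + N_OUT * N_HID
  i4 <- i3 + N_HID
  rnn_params(
    W_in = matrix(v[seq_len(i1)], N_HID, N_IN),
    M = matrix(v[(i1 + 1):i2], N_HID, N_HID),
    W_out = matrix(v[(i2 + 1):i3], N_OUT, N_HID),
    b_h = v[(i3 + 1):i4], b_o = v[(i4 + 1):N_PAR]
  )
}

#' Specify one-sided uniform noise on recurrent weights
#'
#' During a perturbed computation every targeted entry of `M` is
#' shifted, at every update of every episode, by a fresh draw from
#' `U[0, r]`. With `sharing = "shared"` all targeted weights receive
#' one common draw per update instead of independent draws.
#'
#' @param targets Two-column integer matrix of 1-based `(row, col)`
#'   coordinates into `M` (row = receiving node, col = sending node).
#'   A pair (source set S, target node j) therefore maps to rows `j`,
#'   columns `S`.
#' @param r Upper bound of the uniform offset; `r = 0` disables the
#'   perturbation.
#' @param sharing `"independent"` (default) or `"shared"`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(targets, r,
                       sharing = c("independent", "shared")) {
  sharing <- match.arg(sharing)
  targets <- matrix(as.integer(targets), ncol = 2)
  stopifnot(r >= 0, is.finite(r))
  if (nrow(targets) > 0) {
    stopifnot(all(targets >= 1L), all(targets <= N_HID))
  }
  structure(list(targets = targets, r = r, sharing = sharing),
            class = "noise_spec")
}

# internal: M with fresh offsets applied (one step() update)
perturb_M <- function(M, noise) {
  if (is.null(noise) || noise$r == 0 || nrow(noise$targets) == 0) {
    return(M)
  }
  k <- nrow(noise$targets)
  u <- if (noise$sharing == "shared") {
    rep(runif(1, 0, noise$r), k)
  } else {
    runif(k, 0, noise$r)
  }
  M[noise$targets] <- M[noise$targets] + u
  M
}

#' Advance the network by one timestep
#'
#' `h = tanh(W_in x + M h_prev + b_h)`, `y = tanh(W_out h + b_o)`.
#' If a [noise_spec()] is supplied, the targeted entries of `M` are
#' shifted by freshly drawn offsets for this update only; `params` is
#' never modified.
#'
#' @param params An `rnn_params`.
#' @param h_prev Length-16 previous recurrent state.
#' @param x Length-4 sensor input.
#' @param noise Optional [noise_spec()].
#' @return List with `h` (length 16) and `y` (length 8).
#' @export
rnn_step <- function(params, h_prev, x, noise = NULL) {
  stopifnot(length(h_prev) == N_HID, length(x) == N_IN)
  if (!all(is.finite(h_prev)) || !all(is.finite(x))) {
    stop("rnn_step: non-finite inputs")
  }
  M <- perturb_M(params$M, noise)
  h <- tanh(drop(params$W_in %*% x + M %*% h_prev) + params$b_h)
  y <- tanh(drop(params$W_out %*% h) + params$b_o)
  list(h = h, y = y)
}

#' Run the network over one episode
#'
#' The recurrent state starts at the zero vector, the four retina rows
#' are fed in one per timestep, and the classification is read out at
#' the final timestep (the only point at which all three temporal
#' placements have completed).
#'
#' @param params An `rnn_params`.
#' @param episode An [make_episode()] object.
#' @param noise Optional [noise_spec()]; offsets are redrawn at every
#'   timestep.
#' @return List with `trace` (4 x 16 matrix of recurrent states, row
#'   t+1 = state after timestep t) and `y_final` (length-8 output at
#'   t = 3).
#' @export
run_episode <- function(params, episode, noise = NULL) {
  stopifnot(inherits(episode, "acp_episode"))
  h <- numeric(N_HID)
  trace <- matrix(NA_real_, 4, N_HID)
  y <- numeric(N_OUT)
  for (t in 1:4) {
    s <- rnn_step(params, h, episode$frames[t, ], noise)
    h <- s$h
    y <- s$y
    trace[t, ] <- h
  }
  list(trace = trace, y_final = y)
}

#' Read a class out of the output layer
#'
#' @param y_final Length-8 output vector.
#' @return Integer label 0..7: the index of the maximal output, ties
#'   broken toward the lowest index.
#' @export
classify <- function(y_final) {
  stopifnot(length(y_final) == N_OUT, all(is.finite(y_final)))
  as.integer(which.max(y_final) - 1L)
}

#' Evaluate a network on an episode set
#'
#' Computes the squared error `E = sum(D^2)` of the difference
#' `D = O - A` between the matrix `O` of final-timestep outputs and
#' the dataset's target matrix `A` (see [acp_dataset()]), the
#' normalized fitness `w = 1 - E / (n m)`, the number of correctly
#' classified episodes `a`, and the selection fitness `W = 1.5^(w a)`
#' used by the genetic algorithm. `W` is strictly positive for any
#' finite network, so roulette-wheel selection is always well defined.
#'
#' @param params An `rnn_params`.
#' @param data An [acp_dataset()].
#' @param noise Optional [noise_spec()]; with noise the episodes are
#'   run sequentially with fresh offsets at every update.
#' @return Object of class `rnn_performance`: list with `E`, `w`, `a`,
#'   `W` and `outputs` (the n x 8 matrix `O`).
#' @export
#' @examples
#' d <- acp_dataset()
#' evaluate_network(init_network(1), d)
evaluate_network <- function(params, data, noise = NULL) {
  stopifnot(inherits(params, "rnn_params"), inherits(data, "acp_set"))
  if (data$n < 1) stop("evaluate_network: empty dataset")
  if (is.null(noise) || noise$r == 0 || nrow(noise$targets) == 0) {
    H <- matrix(0, N_HID, data$n)
    for (t in 1:4) {
      H <- tanh(params$W_in %*% data$inputs[t, , ] + params$M %*% H +
                  params$b_h)
    }
    O <- t(tanh(params$W_out %*% H + params$b_o))
  } else {
    O <- t(vapply(
      data$episodes,
      function(ep) run_episode(params, ep, noise)$y_final,
      numeric(N_OUT)
    ))
  }
  perf_from_outputs(O, data)
}

# internal: fold an output matrix into the performance record
perf_from_outputs <- function(O, data) {
  D <- O - data$targets
  E <- sum(D * D)
  w <- 1 - E / (data$n * data$m)
  pred <- max.col(O, ties.method = "first") - 1L
  a <- sum(pred == data$labels)
  structure(
    list(E = E, w = w, a = as.integer(a), W = 1.5^(w * a), outputs = O),
    class = "rnn_performance"
  )
}

#' @export
print.rnn_performance <- function(x, ...) {
  cat(sprintf(
    "RNN performance: E = %.4f, w = %.4f, a = %d/24, W = %.4f\n",
    x$E, x$w, x$a, x$W
  ))
  invisible(x)
}

#' Record recurrent-state traces over the full episode set
#'
#' Runs all 24 episodes noise-free, stacking the post-activation
#' recurrent states and the 72 within-episode state transitions
#' (t to t+1 for t = 0, 1, 2). The pre-episode zero state is not a
#' sample, and no transition spans two episodes.
#'
#' @param params An `rnn_params`.
#' @param data An [acp_dataset()].
#' @return Object of class `state_trace`: list with `states`
#'   (array `[24 episodes, 4 timesteps, 16 nodes]`), `from` and `to`
#'   (72 x 16 matrices of transition endpoints) and `episode`
#'   (length-72 episode index of each transition).
#' @export
record_traces <- function(params, data) {
  stopifnot(inherits(params, "rnn_params"), inherits(data, "acp_set"))
  states <- array(NA_real_, c(data$n, 4, N_HID))
  H <- matrix(0, N_HID, data$n)
  for (t in 1:4) {
    H <- tanh(params$W_in %*% data$inputs[t, , ] + params$M %*% H +
                params$b_h)
    states[, t, ] <- t(H)
  }
  idx <- rep(seq_len(data$n), each = 3)
  from <- do.call(rbind, lapply(seq_len(data$n),
                                function(e) states[e, 1:3, ]))
  to <- do.call(rbind, lapply(seq_len(data$n),
                              function(e) states[e, 2:4, ]))
  structure(
    list(states = states, from = from, to = to, episode = idx),
    class = "state_trace"
  )
}

#' Write network parameters to a plain-text file (and read back)
#'
#' One value per line at full precision, preceded by a header line
#' `rnnflow-params 4 16 8`. Matrices are stored row-major in the order
#' `W_in`, `M`, `W_out`, `b_h`, `b_o`, so files are portable and
#' bit-stable across platforms.
#'
#' @param params An `rnn_params`.
#' @param path File path.
#' @return `write_rnn_params`: `path`, invisibly.
#' @export
write_rnn_params <- function(params, path) {
  stopifnot(inherits(params, "rnn_params"))
  vals <- c(t(params$W_in), t(params$M), t(params$W_out),
            params$b_h, params$b_o)
  writeLines(
    c(sprintf("rnnflow-params %d %d %d", N_IN, N_HID, N_OUT),
      formatC(vals, format = "g", digits = 17)),
    path
  )
  invisible(path)
}

#' @rdname write_rnn_params
#' @return `read_rnn_params`: the `rnn_params` stored at `path`.
#' @export
read_rnn_params <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "rnnflow-params")) {
    stop("read_rnn_params: not a parameter file: ", path)
  }
  v <- as.numeric(lines[-1])
  if (length(v) != N_PAR) {
    stop("read_rnn_params: expected ", N_PAR, " values, got ", length(v))
  }
  i1 <- N_HID * N_IN
  i2 <- i1 + N_HID * N_HID
  i3 <- i2 + N_OUT * N_HID
  i4 <- i3 + N_HID
  rnn_params(
    W_in = matrix(v[seq_len(i1)], N_HID, N_IN, byrow = TRUE),
    M = matrix(v[(i1 + 1):i2], N_HID, N_HID, byrow = TRUE),
    W_out = matrix(v[(i2 + 1):i3], N_OUT, N_HID, byrow = TRUE),
    b_h = v[(i3 + 1):i4], b_o = v[(i4 + 1):N_PAR]
  )
}
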