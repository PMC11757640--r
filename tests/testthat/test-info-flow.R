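test_that("median binarization uses the strictly-above tie rule", {
  # 1 episode, 3 timesteps, 2 nodes; node 1 has median 0.5
  states <- array(0, c(2, 3, 2))
  states[1, , 1] <- c(0.1, 0.5, 0.9)
  states[2, , 1] <- c(0.5, 0.5, 0.5)
  states[1, , 2] <- c(0.3, 0.3, 0.3)  # constant node
  states[2, , 2] <- c(0.3, 0.3, 0.3)
  bt <- binarize(synthetic_trace(states))
  expect_equal(bt$bits[1, , 1], c(0L, 0L, 1L))  # value == median -> 0
  expect_equal(bt$bits[, , 2], matrix(0L, 2, 3))
  expect_true(bt$degenerate[2])
  expect_false(bt$degenerate[1])
})

test_that("continuous traces binarize to a near-maximal-entropy split", {
  set.seed(10)
  for (rep in 1:5) {
    states <- array(runif(24 * 4 * 16, -1, 1), c(24, 4, 16))
    bt <- binarize(synthetic_trace(states))
    ones <- colSums(matrix(bt$bits, 96, 16))
    expect_true(all(ones %in% c(47, 48)))
  }
})

test_that("pairs must be disjoint, nonempty and within the layer", {
  expect_error(st_pair(integer(0), 3))
  expect_error(st_pair(1:16, 3), "1..15")
  expect_error(st_pair(c(2, 5), 5), "disjoint")
  expect_error(st_pair(c(0, 2), 5), "1..16")
  p <- st_pair(c(5, 2), 7)
  expect_equal(p$S, c(2L, 5L))
  expect_equal(p$j, 7L)
})

test_that("joint distributions are normalized with bounded support", {
  d <- fixture_data()
  bt <- binarize(record_traces(fixture_perfect_net(), d))
  tab1 <- joint_distribution(bt, st_pair(3, 7))
  expect_lte(nrow(tab1), 8)
  expect_equal(sum(tab1$p), 1, tolerance = 1e-12)
  expect_equal(sum(tab1$count), 72)
  tab3 <- joint_distribution(bt, st_pair(c(1, 4, 9), 12))
  expect_lte(nrow(tab3), 2^5)
  expect_equal(sum(tab3$p), 1, tolerance = 1e-12)
  # all-zero bits collapse to a single cell
  bt0 <- synthetic_binary_trace(matrix(0L, 10, 16), matrix(0L, 10, 16))
  tab0 <- joint_distribution(bt0, st_pair(1, 2))
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$p, 1)
})

test_that("transfer entropy of crafted distributions is exact", {
  # target's next state copies a fair-coin source; own state independent
  copy_tab <- expand.grid(x_next = 0:1, x_self = 0:1, s = 0:1)
  copy_tab$p <- ifelse(copy_tab$x_next == copy_tab$s, 0.25, 0)
  expect_equal(transfer_entropy(copy_tab), 1)
  # next state depends only on own state: zero transfer
  ind_tab <- expand.grid(x_next = 0:1, x_self = 0:1, s = 0:1)
  ind_tab$p <- with(ind_tab, ifelse(x_next == x_self, 0.2, 0.05))
  expect_equal(transfer_entropy(ind_tab), 0)
  expect_error(transfer_entropy(transform(copy_tab, p = p * 2)),
               "sum")
})

test_that("XOR sources are invisible pairwise but fully visible jointly", {
  # nodes: 1 and 2 are the XOR inputs, 3 is the target; all 8 joint
  # states of (in1, in2, target-now) equally frequent
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  from <- matrix(0L, 8, 16)
  from[, 1:3] <- g
  to <- matrix(0L, 8, 16)
  to[, 3] <- bitwXor(g[, 1], g[, 2])
  bt <- synthetic_binary_trace(from, to)
  expect_equal(te_for_pair(bt, st_pair(1, 3)), 0)
  expect_equal(te_for_pair(bt, st_pair(2, 3)), 0)
  expect_equal(te_for_pair(bt, st_pair(c(1, 2), 3)), 1)
})

test_that("plug-in TE agrees with the brute-force oracle", {
  d <- fixture_data()
  bt <- binarize(record_traces(fixture_perfect_net(), d))
  set.seed(77)
  for (sz in 1:4) {
    for (rep in 1:5) {
      S <- sample(16, sz)
      j <- sample(setdiff(1:16, S), 1)
      pair <- st_pair(S, j)
      expect_equal(te_for_pair(bt, pair),
                   max(oracle_te(bt, sort(S), j), 0),
                   tolerance = 1e-12)
      # the fast counting path and the table path are the same measure
      expect_equal(te_for_pair(bt, pair),
                   transfer_entropy(joint_distribution(bt, pair)),
                   tolerance = 1e-12)
    }
  }
  # and on random binary traces, which have no task structure
  from <- matrix(rbinom(72 * 16, 1, 0.5), 72, 16)
  to <- matrix(rbinom(72 * 16, 1, 0.5), 72, 16)
  btr <- synthetic_binary_trace(from, to)
  for (sz in 1:4) {
    S <- sample(16, sz)
    j <- sample(setdiff(1:16, S), 1)
    expect_equal(te_for_pair(btr, st_pair(S, j)),
                 max(oracle_te(btr, sort(S), j), 0),
                 tolerance = 1e-12)
  }
})

test_that("TE is monotone under source-set refinement", {
  d <- fixture_data()
  bt <- binarize(record_traces(fixture_perfect_net(), d))
  set.seed(42)
  for (rep in 1:20) {
    j <- sample(16, 1)
    rest <- setdiff(1:16, j)
    S_small <- sample(rest, sample(1:6, 1))
    extra <- sample(setdiff(rest, S_small), sample(1:4, 1))
    S_big <- c(S_small, extra)
    expect_lte(te_for_pair(bt, st_pair(S_small, j)),
               te_for_pair(bt, st_pair(S_big, j)) + 1e-12)
  }
})

test_that("TE never exceeds the target's conditional entropy", {
  d <- fixture_data()
  bt <- binarize(record_traces(fixture_perfect_net(), d))
  cond_entropy <- function(bt, j) {
    x <- bt$from[, j]
    y <- bt$to[, j]
    h <- 0
    for (a in 0:1) for (b in 0:1) {
      pxy <- mean(x == a & y == b)
      if (pxy > 0) h <- h - pxy * log2(pxy / mean(x == a))
    }
    h
  }
  set.seed(8)
  for (rep in 1:20) {
    sz <- sample(1:15, 1)
    S <- sample(16, sz)
    rest <- setdiff(1:16, S)
    j <- rest[sample.int(length(rest), 1)]
    expect_lte(te_for_pair(bt, st_pair(S, j)),
               cond_entropy(bt, j) + 1e-12)
  }
})

test_that("plug-in bias on independent uniform traces is small but positive", {
  set.seed(123)
  te <- replicate(1000, {
    from <- matrix(rbinom(72 * 2, 1, 0.5), 72, 2)
    to <- matrix(rbinom(72 * 2, 1, 0.5), 72, 2)
    te_for_pair(synthetic_binary_trace(cbind(from, matrix(0L, 72, 14)),
                                       cbind(to, matrix(0L, 72, 14))),
                st_pair(1, 2))
  })
  expect_gt(mean(te), 0)
  expect_lt(mean(te), 0.15)
})

test_that("pair sampling respects sizes, counts and disjointness", {
  pairs <- sample_pairs(15, 30, seed = 5)
  expect_length(pairs, 30)
  for (p in pairs) {
    expect_length(p$S, 15)
    expect_false(p$j %in% p$S)
    expect_equal(sort(c(p$S, p$j)), 1:16)
  }
  expect_identical(sample_pairs(4, 10, seed = 9),
                   sample_pairs(4, 10, seed = 9))
  expect_error(sample_pairs(16, 5), "1..15")
  expect_error(sample_pairs(0, 5), "1..15")
})

test_that("te_profile covers the requested grid with nonnegative TE", {
  d <- fixture_data()
  tr <- record_traces(fixture_perfect_net(), d)
  prof <- te_profile(tr, sizes = c(1, 3, 15), count_per_size = 20,
                     seed = 3)
  expect_equal(nrow(prof), 60)
  expect_true(all(prof$te_bits >= 0))
  expect_equal(prof$te_per_node, prof$te_bits / prof$set_size)
  expect_equal(as.integer(table(prof$set_size)), rep(20L, 3))
})
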