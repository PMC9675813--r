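test_that("hand-evaluated 3x3 fixture truth table is reproduced exactly", {
  net <- make_fixture_net()
  ds <- manual_defects(net, cbind(2L, 2L))

  # input (0,1,1): healthy layers hand-evaluated node by node
  pat_h <- propagate(net, NULL, c(0, 1, 1))
  expect_equal(unclass(pat_h),
               matrix(c(0L, 1L, 1L,   # layer 1
                        0L, 1L, 1L,   # layer 2: (2,2)=OR((2,1),(1,1))=1
                        0L, 1L, 1L),  # layer 3: (2,3)=AND((2,2),(3,2))=1
                      nrow = 3),
               ignore_attr = TRUE)
  # defect at (2,2) silences the AND at (2,3)
  pat_d <- propagate(net, ds, c(0, 1, 1))
  expect_equal(unclass(pat_d),
               matrix(c(0L, 1L, 1L,
                        0L, 0L, 1L,
                        0L, 0L, 1L), nrow = 3),
               ignore_attr = TRUE)
  expect_identical(output_vector(pat_h), c(0L, 1L, 1L))
  expect_identical(output_vector(pat_d), c(0L, 0L, 1L))
  expect_identical(classify_step(output_vector(pat_h), output_vector(pat_d)), "B")

  # remaining hand-computed corners of the truth table
  expect_identical(output_vector(propagate(net, ds, c(1, 1, 1))), c(1L, 0L, 1L))
  expect_identical(output_vector(propagate(net, NULL, c(1, 1, 1))), c(1L, 1L, 1L))
  expect_identical(output_vector(propagate(net, NULL, c(1, 0, 0))), c(1L, 0L, 0L))
  expect_identical(output_vector(propagate(net, ds, c(1, 0, 0))), c(1L, 0L, 0L))
  expect_identical(output_vector(propagate(net, NULL, c(0, 1, 0))), c(0L, 0L, 0L))
})

test_that("all-zero input deactivates everything; all-ones with D=0 activates everything", {
  for (s in 1:20) {
    net <- rand_net(s)
    set.seed(s)
    ds <- place_defects(net, sample(0:6, 1), runif(1), seed = s)
    expect_true(all(propagate(net, ds, rep(0, net$H)) == 0L))
    expect_true(all(propagate(net, NULL, rep(1, net$H)) == 1L))
  }
})

test_that("b=0, D=0 networks are the identity map regardless of gates", {
  for (s in 1:30) {
    set.seed(s)
    net <- build_lattice(sample(3:12, 1), sample(3:12, 1), runif(1), b = 0,
                         seed = s)
    for (r in 1:10) {
      input <- rand_input(net$H)
      expect_identical(output_vector(propagate(net, NULL, input)), input)
    }
  }
})

test_that("propagation matches the naive per-node oracle on random networks", {
  for (s in 1:30) {
    net <- rand_net(s)
    set.seed(s + 7)
    ds <- place_defects(net, sample(0:8, 1), runif(1), seed = s)
    for (r in 1:5) {
      input <- rand_input(net$H, p = runif(1))
      expect_equal(unclass(propagate(net, ds, input)),
                   oracle_propagate(net, ds, input),
                   ignore_attr = TRUE)
    }
  }
})

test_that("defect outputs are a subset of healthy outputs and never stronger", {
  for (s in 1:100) {
    net <- rand_net(s)
    set.seed(s + 31)
    ds <- place_defects(net, sample(1:8, 1), runif(1), seed = s)
    for (r in 1:3) {
      input <- rand_input(net$H, p = runif(1))
      out_h <- output_vector(propagate(net, NULL, input))
      out_d <- output_vector(propagate(net, ds, input))
      expect_true(all(out_d <= out_h))
      expect_lte(output_strength(out_d), output_strength(out_h))
    }
  }
})

test_that("the healthy AND/OR circuit is monotone in its inputs", {
  for (s in 1:50) {
    net <- rand_net(s)
    set.seed(s + 63)
    v <- rand_input(net$H, p = 0.7)
    u <- as.integer(v & rand_input(net$H, p = 0.6)) # u <= v componentwise
    pat_u <- propagate(net, NULL, u)
    pat_v <- propagate(net, NULL, v)
    expect_true(all(pat_u <= pat_v))
  }
})

test_that("propagation is deterministic and validates its input", {
  net <- rand_net(1)
  ds <- place_defects(net, 3, 0.5, seed = 2)
  input <- rand_input(net$H)
  expect_identical(propagate(net, ds, input), propagate(net, ds, input))
  expect_error(propagate(net, ds, c(0, 1)), "length")
  expect_error(propagate(net, NULL, c(rep(0, net$H - 1), 2)), "binary")
})

test_that("output strength counts ones like a naive popcount", {
  expect_identical(output_strength(c(0, 0, 0)), 0L)
  expect_identical(output_strength(c(1, 1, 1, 1)), 4L)
  set.seed(99)
  for (r in 1:50) {
    v <- rand_input(sample(1:30, 1), p = runif(1))
    count <- 0L
    for (x in v) if (x == 1L) count <- count + 1L # naive loop oracle
    expect_identical(output_strength(v), count)
  }
})
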