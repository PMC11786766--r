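test_that("activation has the specified shape", {
  expect_equal(activation(0), 0)
  expect_equal(activation(2), 1)
  expect_equal(activation(c(2.5, 10, 1e6)), c(1, 1, 1))
  expect_equal(activation(-2, leak = 0.01), -0.02)
  # monotone over a dense sweep
  x <- sort(runif(10000, -5, 5))
  expect_true(all(diff(activation(x)) >= 0))
  # Lipschitz constant at most 1
  expect_lte(max(abs(diff(activation(x)) / diff(x))), 1 + 1e-9)
})

test_that("embed_input places targets at their node positions", {
  sc <- scaffold_network(nodes = c("n1", "t1", "n2", "t2", "n3"),
                         edges = data.frame(source = "n1", target = "n2",
                                            sign = 1),
                         input_nodes = c("t1", "t2"),
                         output_nodes = "n3")
  yin <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  emb <- embed_input(yin, sc)
  expect_equal(dim(emb), c(2, 5))
  expect_equal(emb[, "t1"], yin[, "t1"])
  expect_equal(emb[, "t2"], yin[, "t2"])
  expect_equal(unname(emb[, c("n1", "n2", "n3")]), matrix(0, 2, 3))
  expect_error(embed_input(matrix(0, 1, 1, dimnames = list("a", "zz")), sc),
               "not in scaffold")
  expect_equal(unname(embed_input(yin * 0, sc)), matrix(0, 2, 5))
})

chain_scaffold <- function(last_sign = 1) {
  scaffold_network(
    nodes = c("in1", "a", "tf1"),
    edges = data.frame(source = c("in1", "a"), target = c("a", "tf1"),
                       sign = c(1, last_sign), stimulation = c(1, (last_sign+1)/2),
                       inhibition = c(0, (1-last_sign)/2), provenance = "fix",
                       flagged = FALSE),
    input_nodes = "in1", output_nodes = "tf1")
}

test_that("steady state matches a long scalar-chain iteration oracle", {
  sc <- chain_scaffold()
  p <- signaling_params(sc, seed = 1)
  emb <- embed_input(matrix(0.8, 1, 1, dimnames = list("s", "in1")), sc)
  st <- steady_state(p, emb)
  expect_true(all(st$converged))
  # scalar oracle: iterate the same map 200 times element by element
  w <- softplus(p$raw_weights) * p$signs
  a <- c(0, 0, 0)
  for (k in 1:200) {
    u <- c(0.8, w[1] * a[1], w[2] * a[2]) + p$bias
    a <- activation(u, p$leak)
  }
  expect_equal(unname(st$node_activity[1, ]), a, tolerance = 1e-5)
  expect_gt(st$tf_activity[1, "tf1"], 0)
})

test_that("zero input and zero bias give the zero fixed point", {
  sc <- chain_scaffold()
  p <- signaling_params(sc, seed = 2)
  emb <- embed_input(matrix(0, 1, 1, dimnames = list("s", "in1")), sc)
  st <- steady_state(p, emb)
  expect_equal(unname(st$node_activity), matrix(0, 1, 3))
})

test_that("an inhibitory final edge lowers TF activity versus activating", {
  p_act <- signaling_params(chain_scaffold(1), seed = 3)
  p_inh <- signaling_params(chain_scaffold(-1), seed = 3)
  p_act$bias <- p_inh$bias <- c(0, 0.1, 0.5) # positive upstream bias
  emb <- embed_input(matrix(1, 1, 1, dimnames = list("s", "in1")),
                     chain_scaffold(1))
  tf_act <- steady_state(p_act, emb)$tf_activity[1, 1]
  tf_inh <- steady_state(p_inh, emb)$tf_activity[1, 1]
  expect_lt(tf_inh, tf_act)
})

test_that("steady state is independent of batch composition", {
  sc <- make_scaffold(15, 40, 3, 3, seed = 5)
  p <- signaling_params(sc, seed = 5)
  yin <- matrix(runif(6), 2, 3,
                dimnames = list(c("a", "b"), sc$input_nodes))
  emb <- embed_input(yin, sc)
  st_batch <- steady_state(p, emb)
  st_solo <- steady_state(p, emb[1, , drop = FALSE])
  # decoupled up to the convergence tolerance (stopping depends on the batch)
  expect_equal(st_solo$node_activity[1, ], st_batch$node_activity[1, ],
               tolerance = 1e-4)
})

test_that("regularization terms behave as penalties should", {
  sc <- make_scaffold(12, 30, 2, 3, seed = 6)
  drug_mask <- matrix(1, 2, 2, dimnames = list(c("d1", "d2"), sc$input_nodes))
  dp <- drug_layer_params(drug_mask, seed = 1)
  dp$A <- dp$mask * 0 # zero drug weights
  sp <- signaling_params(sc, seed = 6)
  sp$raw_weights[] <- -50 # softplus(-50) ~ 0: zero edge weights
  r0 <- regularization_terms(sp, dp)
  expect_lt(r0$l2_signaling, 1e-20)
  expect_equal(r0$l2_a, 0)

  # L2 homogeneity: doubling the weights quadruples the L2 term
  sp1 <- signaling_params(sc, seed = 7)
  w1 <- softplus(sp1$raw_weights)
  sp2 <- sp1; sp2$raw_weights <- log(expm1(2 * w1))
  r1 <- regularization_terms(sp1, dp)
  r2 <- regularization_terms(sp2, dp)
  expect_equal(r2$l2_signaling / r1$l2_signaling, 4, tolerance = 1e-6)
})

test_that("spectral surrogate tracks the dense eigenvalue oracle", {
  for (seed in 1:5) {
    sc <- make_scaffold(20, 60, 3, 4, seed = seed)
    p <- signaling_params(sc, seed = seed)
    W <- netDTI:::weight_matrix(p)
    fp <- rep(netDTI:::activation_grad(0.5, p$leak), 20)
    est <- netDTI:::spectral_surrogate(W, fp, n_iter = 200)$rho
    oracle <- max(abs(eigen(W * rep(fp, each = 20),
                            only.values = TRUE)$values))
    if (oracle > 1e-6) expect_lt(abs(est - oracle) / oracle, 0.1)
  }
})

test_that("contractive networks converge for every seed", {
  for (seed in 1:50) {
    sc <- make_scaffold(12, 30, 2, 3, seed = seed)
    p <- signaling_params(sc, seed = seed)
    W <- netDTI:::weight_matrix(p)
    rho <- netDTI:::spectral_surrogate(W, rep(1, 12), n_iter = 100)$rho
    if (rho >= 1) next # only the contractive regime is asserted
    yin <- matrix(runif(2 * 2), 2, 2, dimnames = list(c("a", "b"),
                                                      sc$input_nodes))
    st <- steady_state(p, embed_input(yin, sc))
    expect_true(all(st$converged))
  }
})
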