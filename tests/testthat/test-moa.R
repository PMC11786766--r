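make_calls <- function(mat_list, drugs, targets) {
  lapply(mat_list, function(v) {
    matrix(v, length(drugs), length(targets),
           dimnames = list(drugs, targets))
  })
}

test_that("consensus targets use an inclusive frequency threshold", {
  drugs <- "d1"; targets <- paste0("t", 1:3)
  calls <- make_calls(list(c(1, 1, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0),
                           c(1, 1, 1)), drugs, targets)
  ct <- consensus_targets(calls, "d1", source_freq_thresh = 0.6)
  expect_equal(unname(ct["t1"]), 0.8)
  expect_true("t2" %in% names(ct))   # 3/5 = 0.6 kept (inclusive)
  expect_false("t3" %in% names(ct))
  # frequencies equal the brute-force count over models
  set.seed(2)
  rnd <- make_calls(replicate(7, rbinom(3, 1, 0.5), simplify = FALSE),
                    drugs, targets)
  ct_all <- consensus_targets(rnd, "d1", source_freq_thresh = 0)
  brute <- Reduce(`+`, lapply(rnd, function(m) m["d1", ])) / 7
  expect_equal(ct_all, brute[brute >= 0])
})

test_that("an over-strict threshold reproduces the empty-target error", {
  drugs <- "d1"; targets <- c("t1", "t2")
  calls <- make_calls(list(c(1, 0), c(0, 1)), drugs, targets)
  expect_error(consensus_targets(calls, "d1", source_freq_thresh = 1),
               "No inferred drug`s targets kept!", fixed = TRUE)
})

test_that("sign filtering selects inhibitory or activating targets", {
  drugs <- "d1"; targets <- c("t1", "t2")
  calls <- make_calls(list(c(1, 1), c(1, 1)), drugs, targets)
  scores <- make_calls(list(c(-2, 1.5), c(-1, 0.5)), drugs, targets)
  inh <- consensus_targets(calls, "d1", 0.6, "inhibit", scores)
  act <- consensus_targets(calls, "d1", 0.6, "activate", scores)
  expect_equal(names(inh), "t1")
  expect_equal(names(act), "t2")
})

test_that("edge frequencies count supra-threshold signal flux across models", {
  fx <- small_trained_fixture()
  ef <- edge_frequencies(fx$ens, fx$X, rownames(fx$X)[1])
  expect_true(all(ef$frequency >= 0 & ef$frequency <= 1))
  # manual recount for one model
  b <- fx$ens[[1]]
  pred <- predict_model(b, fx$X[1, , drop = FALSE])
  a <- pred$node_activity[1, ]
  w <- netDTI:::edge_weights(b$sig)
  manual <- as.numeric(abs(a[b$sig$src_idx] * w) > 1e-3)
  counted <- vapply(fx$ens, function(bb) {
    pr <- predict_model(bb, fx$X[1, , drop = FALSE])
    aa <- pr$node_activity[1, ]
    as.numeric(abs(aa[bb$sig$src_idx] * netDTI:::edge_weights(bb$sig)) > 1e-3)
  }, numeric(nrow(ef)))
  expect_equal(ef$frequency, rowMeans(counted))
  expect_equal(manual, counted[, 1])
  # an edge whose weight is zero in every model has frequency zero
  ens0 <- lapply(fx$ens, function(bb) {
    bb$sig$raw_weights[1] <- -50
    bb
  })
  ef0 <- edge_frequencies(ens0, fx$X, rownames(fx$X)[1])
  expect_equal(ef0$frequency[1], 0)
})

# hand-built 6-node scaffold with two alternative paths from the drug target
# to the TF: src -> a -> tf (frequency sum 1.8) and src -> b -> tf (1.2)
two_path_fixture <- function(f_high = 0.9, f_low = 0.6) {
  edges <- data.frame(
    source = c("src", "a", "src", "b", "x"),
    target = c("a", "tf", "b", "tf", "tf"),
    sign = c(1, 1, 1, -1, 1),
    stringsAsFactors = FALSE
  )
  sc <- scaffold_network(nodes = c("src", "a", "b", "tf", "x"),
                         edges = edges, input_nodes = "src",
                         output_nodes = "tf")
  ef <- data.frame(edges[, c("source", "target", "sign")],
                   frequency = c(f_high, f_high, f_low, f_low, 0.2),
                   stringsAsFactors = FALSE)
  attr(ef, "node_activity") <- setNames(rep(0.5, 5), sc$nodes)
  list(scaffold = sc, ef = ef)
}

test_that("subnetwork keeps high-frequency edges and reconnects by best path", {
  fx <- two_path_fixture()
  targets <- c(src = 0.8)
  moa <- build_subnetwork(fx$scaffold, targets, "tf", fx$ef,
                          edge_thresh_init = 0.5)
  # full net: all edges >= 0.5; no path additions needed
  expect_equal(sum(moa$full$edges$added_by_path), 0)
  expect_setequal(paste(moa$short$edges$source, moa$short$edges$target),
                  c("src a", "a tf")) # the 1.8 > 1.2 path
  roles <- setNames(moa$full$nodes$role, moa$full$nodes$node)
  expect_equal(unname(roles["src"]), "source")
  expect_equal(unname(roles["tf"]), "target")
  expect_equal(unname(roles["a"]), "mid_node")
})

test_that("disconnected targets are reconnected with flagged edges", {
  fx <- two_path_fixture(f_high = 0.3, f_low = 0.2) # all below the filter
  moa <- build_subnetwork(fx$scaffold, c(src = 0.9), "tf", fx$ef,
                          edge_thresh_init = 0.5)
  expect_true(all(moa$full$edges$added_by_path))
  # connectivity post-condition: every source reaches the TF
  g <- igraph::graph_from_data_frame(moa$full$edges[, 1:2])
  expect_true("tf" %in% names(igraph::subcomponent(g, "src", mode = "out")))
})

test_that("chosen paths match exhaustive enumeration on small scaffolds", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep_ in 1:8) {
    n <- 7
    nodes <- c("src", paste0("m", 1:(n - 2)), "tf")
    # random DAG edges forward through the node order
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) edges <- rbind(edges, c(nodes[i], nodes[j]))
    }
    if (is.null(edges)) next
    ef <- data.frame(source = edges[, 1], target = edges[, 2], sign = 1,
                     frequency = round(runif(nrow(edges)), 3),
                     stringsAsFactors = FALSE)
    attr(ef, "node_activity") <- setNames(rep(0.5, n), nodes)
    sc <- scaffold_network(nodes = nodes, edges = ef[, c("source", "target", "sign")],
                           input_nodes = "src", output_nodes = "tf")
    # exhaustive enumeration of simple paths by summed frequency
    g <- igraph::graph_from_data_frame(ef[, 1:2], vertices = nodes)
    paths <- tryCatch(igraph::all_simple_paths(g, "src", "tf", mode = "out"),
                      error = function(e) list())
    if (length(paths) == 0) next
    best_sum <- max(vapply(paths, function(p) {
      nm <- names(p)
      sum(vapply(seq_len(length(nm) - 1), function(k) {
        ef$frequency[ef$source == nm[k] & ef$target == nm[k + 1]]
      }, numeric(1)))
    }, numeric(1)))
    moa <- build_subnetwork(sc, c(src = 1), "tf", ef, edge_thresh_init = 2)
    got_sum <- sum(moa$short$edges$frequency)
    expect_equal(got_sum, best_sum, tolerance = 1e-9)
  }
})

test_that("zero threshold keeps exactly the positive-frequency edges", {
  fx <- two_path_fixture()
  ef <- fx$ef
  ef$frequency[5] <- 0
  attr(ef, "node_activity") <- attr(fx$ef, "node_activity")
  moa <- build_subnetwork(fx$scaffold, c(src = 1), "tf", ef,
                          edge_thresh_init = 0)
  expect_equal(nrow(moa$full$edges), 4) # the zero-frequency edge is excluded
  expect_true(all(moa$full$edges$frequency > 0))
})

test_that("the sign report reflects planted interaction signs", {
  fx <- small_trained_fixture()
  pl <- fx$gt$planted[1, ]
  rep_ <- suppressWarnings(
    sign_report(fx$ens, fx$X, rownames(fx$X)[1], pl$drug, pl$target))
  expect_equal(rep_$sign, pl$sign)
  expect_true(is.finite(rep_$activity))
  # consistency: activity equals the ensemble-mean steady state at the node
  acts <- vapply(fx$ens, function(b) {
    predict_model(b, fx$X[1, , drop = FALSE])$node_activity[1, pl$target]
  }, numeric(1))
  expect_equal(rep_$activity, mean(acts))
  # a node outside the modelled target space is flagged with score zero
  mid <- setdiff(fx$gt$scaffold$nodes,
                 c(fx$gt$targets, fx$gt$scaffold$output_nodes))[1]
  rep0 <- suppressWarnings(
    sign_report(fx$ens, fx$X, rownames(fx$X)[1], pl$drug, mid))
  expect_equal(rep0$score, 0)
  expect_true(rep0$flagged)
})

test_that("MoA exports are written with the expected naming pattern", {
  fx <- two_path_fixture()
  moa <- build_subnetwork(fx$scaffold, c(src = 0.8), "tf", fx$ef, 0.5)
  d <- withr::local_tempdir()
  paths <- write_moa_network(moa, d, "CellX", "drugA", "TF1")
  expect_true(file.exists(file.path(
    d, "CellX_drugA_TF1_moa_model_ensembleFiltered.csv")))
  expect_true(file.exists(file.path(
    d, "CellX_drugA_TF1_moa_short_model_ensembled.csv")))
  nd <- read.csv(paths$nodes)
  expect_setequal(colnames(nd), c("node", "gene", "role", "activity"))
})
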