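test_that("build_graph parses structures into hydrogen-suppressed graphs", {
  g <- build_graph("C", "methane")
  expect_equal(length(g$atoms), 1L)
  expect_equal(g$atoms, "C")
  expect_equal(g$chi, 2.55)
  expect_equal(nrow(g$bonds), 0L)

  b <- build_graph("c1ccccc1", "benzene")
  expect_equal(length(b$atoms), 6L)
  expect_equal(nrow(b$bonds), 6L)
  deg <- tabulate(c(b$bonds), nbins = 6L)
  expect_equal(deg, rep(2L, 6L))  # a 6-cycle

  p <- build_graph("C#CCN", "propargylamine")
  expect_equal(length(p$atoms), 4L)
  expect_equal(nrow(p$bonds), 3L)
  expect_equal(sort(tabulate(c(p$bonds), nbins = 4L)), c(1L, 1L, 2L, 2L))
  expect_setequal(p$atoms, c("C", "C", "C", "N"))
})

test_that("build_graph rejects unparsable SMILES with a named error", {
  expect_error(build_graph("not a smiles(("), "not a smiles",
               class = "alma_parse_error")
})

test_that("disconnected structures keep the largest component by default", {
  salt <- build_graph("CCO.[Na+]")
  expect_equal(sort(salt$atoms), c("C", "C", "O"))
  all_frag <- build_graph("CCO.[Na+]", keep = "all")
  expect_equal(length(all_frag$atoms), 4L)
  # descriptor computation must not crash on the disconnected graph
  P <- transition_matrix(all_frag)
  expect_equal(rowSums(P), rep(1, 4L))
  expect_true(is.finite(entropy_theta(all_frag, 5)))
})

test_that("transition matrix follows the closed-neighborhood chi rule", {
  single <- build_graph("C")
  expect_equal(transition_matrix(single), matrix(1, 1, 1))

  benzene <- build_graph("c1ccccc1")
  P <- transition_matrix(benzene)
  expect_equal(sort(unique(round(as.numeric(P), 12))), c(0, round(1 / 3, 12)))

  cn <- build_graph("CN")
  P2 <- transition_matrix(cn)
  expect_equal(P2[1, ], c(2.55, 3.04) / 5.59, tolerance = 1e-12)
  expect_equal(P2[2, ], c(2.55, 3.04) / 5.59, tolerance = 1e-12)
})

test_that("self-loops can be disabled, isolated atoms keep theirs", {
  benzene <- build_graph("c1ccccc1")
  P <- transition_matrix(benzene, self_loops = FALSE)
  expect_equal(diag(P), rep(0, 6))
  expect_equal(rowSums(P), rep(1, 6))
  single <- build_graph("C")
  expect_equal(transition_matrix(single, self_loops = FALSE),
               matrix(1, 1, 1))
})

test_that("markov profiles are proper distributions with bounded entropy", {
  for (g in fixture_graphs()) {
    prof <- markov_profile(g, k_max = 5L)
    n <- length(g$atoms)
    expect_equal(rowSums(prof$transition), rep(1, n), tolerance = 1e-12)
    for (p in prof$step_distributions) {
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
    expect_true(all(prof$entropies >= 0))
    expect_true(all(prof$entropies <= log2(n) + 1e-12))
  }
})

test_that("uniform-weight vertex-transitive graphs reach the entropy bound", {
  for (smi in c("c1ccccc1", "C1CCCCC1")) {
    g <- build_graph(smi)
    prof <- markov_profile(g, k_max = 5L)
    expect_equal(unname(prof$entropies), rep(log2(6), 6L),
                 tolerance = 1e-12)
  }
  single <- build_graph("C")
  expect_equal(unname(markov_profile(single, 5L)$entropies), rep(0, 6L))
})

test_that("matrix-power distributions equal brute-force walk enumeration", {
  for (g in fixture_graphs()) {
    if (length(g$atoms) > 6L) next
    prof <- markov_profile(g, k_max = 3L)
    for (k in 0:3) {
      expect_equal(prof$step_distributions[[k + 1L]],
                   oracle_step_dist(g, k), tolerance = 1e-10,
                   info = sprintf("%s k=%d", g$id, k))
    }
  }
})

test_that("a 3-atom path with distinct weights matches the walk oracle", {
  g <- make_graph(c("C", "N", "O"), c(1, 2, 2, 3))
  expect_equal(entropy_theta(g, 2), oracle_theta(g, 2), tolerance = 1e-10)
  expect_equal(entropy_theta(g, 2, self_loops = FALSE),
               oracle_theta(g, 2, self_loops = FALSE), tolerance = 1e-10)
})

test_that("entropies are invariant under atom relabeling", {
  g <- make_graph(c("C", "N", "O", "S", "C"),
                  c(1, 2, 2, 3, 3, 4, 4, 5, 2, 5))
  perm <- c(3L, 5L, 1L, 2L, 4L)  # new index of each old atom
  g2 <- make_graph(g$atoms[order(perm)],
                   c(apply(g$bonds, 1L, function(b) perm[b])))
  expect_equal(markov_profile(g, 5L)$entropies,
               markov_profile(g2, 5L)$entropies, tolerance = 1e-10)
})

test_that("connected graphs mix: theta_k > 0 once k reaches the diameter", {
  path4 <- build_graph("CCCN")  # diameter 3
  expect_gt(entropy_theta(path4, 3), 0)
  expect_gt(entropy_theta(path4, 5), 0)
})

test_that("negative entropy order is a domain error", {
  g <- build_graph("CC")
  expect_error(entropy_theta(g, -1), class = "alma_domain_error")
})

test_that("elements missing from the electronegativity table are flagged", {
  expect_error(pauling_chi(c("C", "Xx")), "Xx",
               class = "alma_config_error")
})

test_that("descriptor_block matches per-molecule computation and input order", {
  mols <- data.frame(
    compound_id = c("a", "b", "dup", "bad", "c"),
    smiles = c("C", "CCO", "CCO", "xx((", "C#CCN"),
    stringsAsFactors = FALSE)
  block <- descriptor_block(mols, k_max = 5L)
  expect_equal(block$compound_id, mols$compound_id)
  expect_equal(unlist(block[1, paste0("theta", 0:5)], use.names = FALSE),
               rep(0, 6))
  # duplicate SMILES give identical rows (descriptor is structure-pure)
  expect_equal(block[2, paste0("theta", 0:5)],
               block[3, paste0("theta", 0:5)], ignore_attr = TRUE)
  # the bad row carries an error, others are unaffected
  expect_false(is.na(block$error[4]))
  expect_true(all(is.na(block$error[-4])))
  expect_true(all(is.na(unlist(block[4, paste0("theta", 0:5)]))))
  # batch values agree with single-molecule calls
  for (i in c(1, 2, 5)) {
    g <- build_graph(mols$smiles[i])
    expect_equal(unlist(block[i, paste0("theta", 0:5)], use.names = FALSE),
                 unname(markov_profile(g, 5L)$entropies), tolerance = 1e-12)
  }
})
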