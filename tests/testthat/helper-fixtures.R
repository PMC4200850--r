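# Shared fixtures and independent oracles, built in code.

# Small molecules exercising paths, branches, rings, heteroatoms.
fixture_smiles <- c(
  methane = "C", ethane = "CC", ethanol = "CCO", dimethylsulfide = "CSC",
  propargylamine = "C#CCN", aminoethanol = "CC(N)O",
  cyclopropane = "C1CC1", benzene = "c1ccccc1"
)

fixture_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(names(fixture_smiles), function(nm)
        build_graph(fixture_smiles[[nm]], nm))
    cache
  }
})

# Construct an alma_graph directly (for permutation tests etc.).
make_graph <- function(symbols, bonds, id = "manual") {
  bonds <- matrix(as.integer(bonds), ncol = 2L, byrow = TRUE)
  structure(list(atoms = symbols, chi = unname(pauling_chi(symbols)),
                 bonds = bonds, id = id, smiles = NA_character_),
            class = "alma_graph")
}

# Independent oracle for the k-step distribution: enumerate every walk
# of length k, multiplying per-step probabilities computed directly
# from electronegativities and closed neighborhoods (no linear
# algebra).
oracle_step_dist <- function(graph, k, self_loops = TRUE) {
  n <- length(graph$atoms)
  nbhd <- lapply(seq_len(n), function(i) {
    nb <- integer(0)
    if (nrow(graph$bonds)) {
      nb <- c(graph$bonds[graph$bonds[, 1L] == i, 2L],
              graph$bonds[graph$bonds[, 2L] == i, 1L])
    }
    if (self_loops || length(nb) == 0L) nb <- c(nb, i)
    sort(unique(nb))
  })
  step_p <- function(i, j) {
    if (!(j %in% nbhd[[i]])) return(0)
    graph$chi[j] / sum(graph$chi[nbhd[[i]]])
  }
  p0 <- graph$chi / sum(graph$chi)
  out <- numeric(n)
  recurse <- function(node, prob, depth) {
    if (depth == k) {
      out[node] <<- out[node] + prob
      return(invisible())
    }
    for (j in nbhd[[node]])
      recurse(j, prob * step_p(node, j), depth + 1L)
  }
  for (s in seq_len(n)) recurse(s, p0[s], 0L)
  out
}

oracle_theta <- function(graph, k, self_loops = TRUE) {
  shannon_entropy(oracle_step_dist(graph, k, self_loops))
}

# Deterministic toy endpoint table: one condition value per class, four
# records, two active compounds with theta5 = 1 and 3.
toy_descriptors <- function() {
  data.frame(compound_id = c("c1", "c2", "c3", "c4"),
             theta5 = c(1, 3, 2, 2.5), stringsAsFactors = FALSE)
}

toy_records <- function() {
  data.frame(compound_id = c("c1", "c2", "c3", "c4"),
             smiles = "CC",
             curation_level = "expert",
             measure = "Ki (nM)", assay_id = "A1",
             organism = "hsa", target_id = "T1",
             label = c(1L, 1L, 0L, 0L), stringsAsFactors = FALSE)
}

# Stats table with one value per class and prescribed ma_values
# (mean_theta5 chosen so ma = p1 * mean_theta holds with p1 = 1).
toy_stats <- function(ma = c(sx = 1, au = 1, ot = 1, te = 1),
                      values = c(sx = "Ki (nM)", au = "A1",
                                 ot = "hsa", te = "T1")) {
  data.frame(condition_class = names(ma),
             condition_value = unname(values[names(ma)]),
             n = 1L, n1 = 1L, p1 = 1,
             mean_theta5 = unname(ma), ma_value = unname(ma),
             stringsAsFactors = FALSE)
}

# Small generator config for fast tests.
small_config <- function(...) {
  synth_config(n_compounds = 120L, n_records = 400L, n_measures = 8L,
               n_assays = 30L, n_organisms = 4L, n_targets = 12L, ...)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

extdata <- function(file) {
  system.file("extdata", file, package = "almanet", mustWork = TRUE)
}
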