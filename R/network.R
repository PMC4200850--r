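# Tripartite drug-target-assay networks. Node ids are namespaced with
# "d:", "t:", "a:" prefixes so a string reused as both target and assay
# id cannot collide. Exactly three arc classes exist: drug->target,
# drug->assay, target->assay.

.arc_classes <- c("drug->target", "drug->assay", "target->assay")

.make_network <- function(drug, target, assay, path_only = FALSE) {
  d <- paste0("d:", as.character(drug))
  t <- paste0("t:", as.character(target))
  a <- paste0("a:", as.character(assay))
  arcs <- rbind(
    data.frame(from = d, to = t, arc_class = "drug->target",
               stringsAsFactors = FALSE),
    if (!path_only)
      data.frame(from = d, to = a, arc_class = "drug->assay",
                 stringsAsFactors = FALSE),
    data.frame(from = t, to = a, arc_class = "target->assay",
               stringsAsFactors = FALSE))
  arcs <- unique(arcs)
  nodes <- unique(data.frame(
    node_id = c(d, t, a),
    class = rep(c("drug", "target", "assay"), each = length(d)),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g), class = "alma_network")
}

.empty_network <- function() {
  g <- igraph::make_empty_graph(directed = TRUE)
  structure(list(graph = g), class = "alma_network")
}

#' Build the observed tripartite network
#'
#' Every record with an observed link (`label == 1`) contributes the
#' path drug -> target -> assay plus the drug -> assay shortcut (set
#' semantics, so duplicate records collapse). Records with `label == 0`
#' contribute nothing; an all-negative table yields an empty network.
#'
#' @param records Endpoint records with labels.
#' @param path_only If `TRUE`, omit the drug -> assay arc class and keep
#'   only the two-arc path.
#' @return An `alma_network` wrapping a directed [igraph] graph whose
#'   vertices carry a `class` attribute.
#' @export
build_observed <- function(records, path_only = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("compound_id", "target_id", "assay_id", "label")
  if (!all(need %in% names(records)))
    stop(alma_error(sprintf("records need columns: %s",
                            paste(need, collapse = ", "))))
  bad <- !nzchar(as.character(records$target_id)) |
    !nzchar(as.character(records$assay_id)) |
    is.na(records$target_id) | is.na(records$assay_id)
  if (any(bad))
    stop(alma_error(sprintf(
      "records with missing target/assay ids at row(s): %s",
      paste(utils::head(which(bad), 10L), collapse = ", "))))
  pos <- !is.na(records$label) & records$label == 1L
  if (!any(pos)) return(.empty_network())
  r <- records[pos, , drop = FALSE]
  .make_network(r$compound_id, r$target_id, r$assay_id, path_only)
}

#' Build a predicted tripartite network
#'
#' Identical construction to [build_observed()] with the observed label
#' replaced by the thresholded prediction `prob > cutoff` (strict, so a
#' probability exactly at the cutoff is excluded).
#'
#' @param predictions Prediction table from [predict_table()] (needs
#'   `compound_id`, `target_id`, `assay_id`, `prob`).
#' @param cutoff Probability threshold (default 0.5).
#' @inheritParams build_observed
#' @return An `alma_network`.
#' @export
build_predicted <- function(predictions, cutoff = 0.5, path_only = FALSE) {
  stopifnot(is.data.frame(predictions))
  if (!"prob" %in% names(predictions))
    stop(alma_error("predictions need a 'prob' column"))
  predictions$label <- as.integer(predictions$prob > cutoff)
  build_observed(predictions, path_only = path_only)
}

#' @export
print.alma_network <- function(x, ...) {
  cat(sprintf("<alma_network: %d nodes, %d arcs>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Per-node degrees and first-order Markov-Shannon entropy
#'
#' Degrees (`deg_in`, `deg_out`, `deg = deg_in + deg_out`) come from the
#' directed graph. The entropy is computed on the symmetrized graph
#' (arc directions removed, duplicates collapsed): with uniform node
#' weights, the self-loop walk matrix has row i equal to
#' `1 / (deg_i + 1)` on the closed neighborhood of i; starting from the
#' uniform distribution, the one-step occupancy of node j is
#' `pi_1(j) = (1/n) * sum_{i in N(j) u {j}} 1 / (deg_i + 1)` and the
#' node's entropy contribution is `Sh_1(j) = -pi_1(j) * log2 pi_1(j)`.
#' `pi_1` sums to 1 over the network.
#'
#' @param network An `alma_network`.
#' @return Data frame `node_id, class, deg_in, deg_out, deg, pi1, sh1`.
#' @export
node_entropy <- function(network) {
  stopifnot(inherits(network, "alma_network"))
  g <- network$graph
  n <- igraph::vcount(g)
  if (n == 0L)
    stop(alma_error("network is empty", class = "alma_domain_error"))
  und <- igraph::as_undirected(g, mode = "collapse")
  deg_sym <- igraph::degree(und)
  inv <- 1 / (deg_sym + 1)
  # pi1(j) = (1/n) * (inv_j + sum over symmetrized neighbors of inv_i)
  adj <- igraph::as_adj_list(und)
  pi1 <- vapply(seq_len(n), function(j)
    (inv[j] + sum(inv[as.integer(adj[[j]])])) / n, numeric(1L))
  data.frame(
    node_id = igraph::V(g)$name,
    class = igraph::V(g)$class,
    deg_in = as.integer(igraph::degree(g, mode = "in")),
    deg_out = as.integer(igraph::degree(g, mode = "out")),
    deg = as.integer(igraph::degree(g, mode = "all")),
    pi1 = pi1,
    sh1 = -pi1 * log2(pi1),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-class topology summary
#'
#' One row per node class (drug, target, assay) plus a Total row:
#' node count, mean first-order Markov-Shannon entropy, and median
#' degree, in-degree and out-degree.
#'
#' @param network An `alma_network`.
#' @return Data frame `class, n, mean_sh1, median_deg, median_deg_in,`
#'   `median_deg_out`.
#' @export
class_summary <- function(network) {
  ns <- node_entropy(network)
  groups <- c(list(Total = ns),
              split(ns, factor(ns$class, c("drug", "target", "assay"))))
  groups <- Filter(function(d) nrow(d) > 0, groups)
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    d <- groups[[nm]]
    data.frame(class = nm, n = nrow(d), mean_sh1 = mean(d$sh1),
               median_deg = stats::median(d$deg),
               median_deg_in = stats::median(d$deg_in),
               median_deg_out = stats::median(d$deg_out),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Network writers
#'
#' `write_network_graphml` writes GraphML (via igraph);
#' `write_edge_list` writes the arc table `source,target,arc_class`;
#' `write_node_stats` writes the per-node statistics CSV
#' `node_id,class,deg_in,deg_out,deg,sh1`.
#'
#' @param network An `alma_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "alma_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "alma_network"))
  el <- igraph::as_data_frame(network$graph, what = "edges")
  names(el) <- c("source", "target", "arc_class")
  utils::write.csv(el, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_node_stats <- function(network, path) {
  ns <- node_entropy(network)
  ns <- ns[, c("node_id", "class", "deg_in", "deg_out", "deg", "sh1")]
  ns$sh1 <- .fmt_num(ns$sh1)
  utils::write.csv(ns, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
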