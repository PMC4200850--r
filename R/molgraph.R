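# Convert SMILES to V2000 molblocks via Open Babel (ChemmineOB) and parse
# the atom/bond blocks. One batch call per input vector; molecules Open
# Babel rejects are simply absent from the output, so callers match on the
# title line to detect failures. Returns a named list of
# list(symbols=character, bonds=2-col integer matrix) or NULL for failures.
# Open Babel stops emitting molecules after a parse error, so anything
# missing from the batch output is retried one at a time; entries still
# missing after the retry are genuine parse failures.
.smiles_to_blocks <- function(smiles) {
  out <- .smiles_to_blocks_once(smiles)
  missing <- vapply(out, is.null, logical(1L))
  if (any(missing) && length(smiles) > 1L) {
    for (i in which(missing))
      out[i] <- .smiles_to_blocks_once(smiles[[i]])
  }
  out
}

.smiles_to_blocks_once <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  keys <- sprintf("m%06d", seq_along(smiles))
  src <- paste0(paste(smiles, keys, sep = "\t"), collapse = "\n")
  txt <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(src, "\n")))
  out <- stats::setNames(vector("list", length(smiles)), keys)
  if (!nzchar(txt)) return(out)
  for (mol in strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]) {
    lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
    lines <- lines[cumsum(nzchar(lines)) > 0 | nzchar(lines)]
    if (!length(lines)) next
    # leading blank lines were stripped with the molecule separator; the
    # title is the first non-empty line before the counts line
    first <- which(nzchar(lines))[1]
    key <- trimws(lines[first])
    counts <- lines[first + 3L]
    n_atoms <- as.integer(substr(counts, 1L, 3L))
    n_bonds <- as.integer(substr(counts, 4L, 6L))
    if (is.na(n_atoms)) next
    atom_lines <- lines[seq.int(first + 4L, length.out = n_atoms)]
    symbols <- trimws(substr(atom_lines, 32L, 34L))
    bonds <- matrix(integer(0), ncol = 2L)
    if (n_bonds > 0L) {
      bond_lines <- lines[seq.int(first + 4L + n_atoms, length.out = n_bonds)]
      bonds <- cbind(as.integer(substr(bond_lines, 1L, 3L)),
                     as.integer(substr(bond_lines, 4L, 6L)))
    }
    if (key %in% names(out))
      out[[key]] <- list(symbols = symbols, bonds = bonds)
  }
  out
}

# Label connected components by breadth-first search over the bond list.
.components <- function(n, bonds) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1L]; j <- bonds[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

.graph_from_blocks <- function(block, compound_id, smiles,
                               keep = c("largest", "all")) {
  keep <- match.arg(keep)
  symbols <- block$symbols
  bonds <- block$bonds
  # hydrogen suppression: drop explicit H (and isotope labels) unless the
  # molecule is a lone hydrogen species
  is_h <- symbols %in% c("H", "D", "T")
  if (any(!is_h) && any(is_h)) {
    keep_idx <- which(!is_h)
    remap <- integer(length(symbols))
    remap[keep_idx] <- seq_along(keep_idx)
    symbols <- symbols[keep_idx]
    if (nrow(bonds)) {
      ok <- !is_h[bonds[, 1L]] & !is_h[bonds[, 2L]]
      bonds <- bonds[ok, , drop = FALSE]
      bonds[] <- remap[bonds]
    }
  }
  bonds <- bonds[bonds[, 1L] != bonds[, 2L], , drop = FALSE]
  # collapse duplicate bond records (aromatic ring closures etc.)
  if (nrow(bonds)) {
    bonds <- cbind(pmin(bonds[, 1L], bonds[, 2L]),
                   pmax(bonds[, 1L], bonds[, 2L]))
    bonds <- unique(bonds)
  }
  if (keep == "largest" && length(symbols) > 1L) {
    comp <- .components(length(symbols), bonds)
    sizes <- tabulate(comp)
    if (max(comp) > 1L) {
      main <- which.max(sizes)          # ties: first (lowest atom index)
      keep_idx <- which(comp == main)
      remap <- integer(length(symbols))
      remap[keep_idx] <- seq_along(keep_idx)
      symbols <- symbols[keep_idx]
      ok <- comp[bonds[, 1L]] == main
      bonds <- bonds[ok, , drop = FALSE]
      bonds[] <- remap[bonds]
    }
  }
  structure(
    list(atoms = symbols, chi = unname(pauling_chi(symbols)),
         bonds = bonds, id = compound_id, smiles = smiles),
    class = "alma_graph")
}

#' Build a molecular graph from a SMILES string
#'
#' Parses a SMILES string (via Open Babel) into a hydrogen-suppressed
#' molecular graph whose nodes carry Pauling electronegativity weights.
#' Disconnected structures (salts, mixtures) keep the largest connected
#' component by default: a Markov chain never mixes across components, so
#' descriptors of the counter-ion would silently average in otherwise.
#'
#' @param smiles A single SMILES string.
#' @param compound_id Identifier attached to the graph (defaults to the
#'   SMILES itself).
#' @param keep `"largest"` (default) keeps only the largest connected
#'   component; `"all"` keeps every fragment.
#' @return An object of class `alma_graph` with fields `atoms` (element
#'   symbols), `chi` (electronegativities), `bonds` (2-column index
#'   matrix), `id` and `smiles`.
#' @examples
#' g <- build_graph("C#CCN", "propargylamine")
#' length(g$atoms)  # 4 heavy atoms
#' @export
build_graph <- function(smiles, compound_id = smiles,
                        keep = c("largest", "all")) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  blocks <- .smiles_to_blocks(smiles)
  block <- blocks[[1L]]
  if (is.null(block) || length(block$symbols) == 0L)
    stop(alma_error(sprintf("SMILES failed to parse: '%s'", smiles),
                    class = "alma_parse_error"))
  .graph_from_blocks(block, compound_id, smiles, keep = match.arg(keep))
}

#' @export
print.alma_graph <- function(x, ...) {
  cat(sprintf("<alma_graph '%s': %d atoms, %d bonds>\n",
              x$id, length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Electronegativity-weighted Markov transition matrix
#'
#' Entry (i, j) is the probability that a walker at atom i steps to atom j:
#' `chi_j / sum(chi_l)` over l in the closed neighborhood of i (neighbors
#' plus i itself). The self-loop keeps the chain well defined on single
#' atoms and isolated fragments; disable it with `self_loops = FALSE`
#' (isolated atoms then still retain their self-loop, as the walker has
#' nowhere else to go).
#'
#' @param graph An `alma_graph`.
#' @param self_loops Include the atom itself in its destination set
#'   (default `TRUE`).
#' @return A row-stochastic numeric matrix.
#' @export
transition_matrix <- function(graph, self_loops = TRUE) {
  stopifnot(inherits(graph, "alma_graph"))
  n <- length(graph$atoms)
  if (n == 0L)
    stop(alma_error("empty graph has no transition matrix",
                    class = "alma_domain_error"))
  A <- matrix(0, n, n)
  if (nrow(graph$bonds)) {
    A[graph$bonds] <- 1
    A[graph$bonds[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (self_loops) {
    diag(A) <- 1
  } else {
    # keep self-loops only where the atom is isolated
    iso <- rowSums(A) == 0
    diag(A)[iso] <- 1
  }
  W <- sweep(A, 2L, graph$chi, `*`)
  W / rowSums(W)
}

#' Markov-Shannon entropy profile of a molecular graph
#'
#' Computes the step distributions and entropies of the
#' electronegativity-weighted Markov chain on the molecular graph. The
#' order-0 distribution is `chi / sum(chi)`; the order-k distribution is
#' its image under k steps of the transition matrix. The order-k entropy
#' `theta_k` is the Shannon entropy of that distribution (base 2 by
#' default, so the values are in bits and bounded by `log2(n_atoms)`).
#'
#' @param graph An `alma_graph`.
#' @param k_max Highest order to compute (default 5).
#' @param base Logarithm base (default 2).
#' @param self_loops Passed to [transition_matrix()].
#' @return A list of class `markov_profile`: `transition` (the matrix),
#'   `step_distributions` (list of length `k_max + 1`, orders 0..k_max),
#'   `entropies` (numeric vector named `theta0`..`theta<k_max>`).
#' @export
markov_profile <- function(graph, k_max = 5L, base = 2, self_loops = TRUE) {
  stopifnot(inherits(graph, "alma_graph"), k_max >= 0L)
  P <- transition_matrix(graph, self_loops = self_loops)
  p <- graph$chi / sum(graph$chi)
  dists <- vector("list", k_max + 1L)
  dists[[1L]] <- p
  if (k_max > 0L) for (k in seq_len(k_max)) {
    p <- as.numeric(p %*% P)
    dists[[k + 1L]] <- p
  }
  ent <- vapply(dists, shannon_entropy, numeric(1L), base = base)
  names(ent) <- paste0("theta", 0:k_max)
  structure(list(transition = P, step_distributions = dists,
                 entropies = ent),
            class = "markov_profile")
}

#' Shannon entropy of a probability vector
#'
#' Zero probabilities contribute zero (the `0 * log 0` convention).
#'
#' @param p Non-negative numeric vector summing to 1.
#' @param base Logarithm base (default 2).
#' @return The entropy, a single number.
#' @export
shannon_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Markov-Shannon entropy of a single order
#'
#' @param graph An `alma_graph`.
#' @param k Order (non-negative integer).
#' @inheritParams markov_profile
#' @return `theta_k` in bits (for `base = 2`).
#' @export
entropy_theta <- function(graph, k, base = 2, self_loops = TRUE) {
  if (length(k) != 1L || is.na(k) || k < 0)
    stop(alma_error("entropy order k must be a non-negative integer",
                    class = "alma_domain_error"))
  unname(markov_profile(graph, k_max = as.integer(k), base = base,
                        self_loops = self_loops)$entropies[k + 1L])
}

#' Batch descriptor computation
#'
#' Computes `theta_0 .. theta_kmax` for a table of molecules. SMILES are
#' converted in one batch; per-molecule failures are reported in an
#' `error` column without aborting the rest of the batch. Rows are
#' returned in input order.
#'
#' @param molecules A data frame with columns `compound_id` and `smiles`
#'   (extra columns are ignored).
#' @param k_max Highest entropy order (default 5).
#' @inheritParams markov_profile
#' @param keep Component handling, passed to the graph builder.
#' @return A data frame with columns `compound_id`, `smiles`,
#'   `theta0`..`theta<k_max>` and `error` (`NA` on success).
#' @export
descriptor_block <- function(molecules, k_max = 5L, base = 2,
                             self_loops = TRUE, keep = "largest") {
  stopifnot(is.data.frame(molecules),
            all(c("compound_id", "smiles") %in% names(molecules)))
  if (nrow(molecules) == 0L)
    stop(alma_error("molecule list is empty", class = "alma_domain_error"))
  n <- nrow(molecules)
  theta <- matrix(NA_real_, n, k_max + 1L,
                  dimnames = list(NULL, paste0("theta", 0:k_max)))
  err <- rep(NA_character_, n)
  smi <- as.character(molecules$smiles)
  # descriptors are pure functions of structure: compute each distinct
  # SMILES once
  uniq <- !duplicated(smi)
  blocks <- .smiles_to_blocks(smi[uniq])
  names(blocks) <- smi[uniq]
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- smi[i]
    if (!is.null(cache[[s]])) {
      res <- cache[[s]]
    } else {
      res <- tryCatch({
        block <- blocks[[s]]
        if (is.null(block) || length(block$symbols) == 0L)
          stop(alma_error(sprintf("SMILES failed to parse: '%s'", s),
                          class = "alma_parse_error"))
        g <- .graph_from_blocks(block, molecules$compound_id[i], s,
                                keep = keep)
        list(theta = markov_profile(g, k_max = k_max, base = base,
                                    self_loops = self_loops)$entropies,
             error = NA_character_)
      }, error = function(e) list(theta = NULL,
                                  error = conditionMessage(e)))
      cache[[s]] <- res
    }
    if (!is.null(res$theta)) theta[i, ] <- res$theta
    err[i] <- res$error
  }
  out <- data.frame(compound_id = as.character(molecules$compound_id),
                    smiles = smi, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(theta))
  out$error <- err
  out
}
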