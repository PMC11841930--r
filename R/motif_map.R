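# Signature-motif extraction, clade tallies, and parsimony inference of
# motif substitution histories on a taxonomy.
#
# The 3-residue DNA-binding-domain signature (YDG in the IRF5/6 subfamily,
# with FDG/LDG/VDG variants in bird lineages) is located by lifting the
# reference motif coordinates, never by string search: a variant motif must
# still be found at the homologous position. Minimal substitution histories
# are computed by unweighted Sankoff dynamic programming, which generalizes
# Fitch/Hartigan parsimony to multifurcating trees and yields, besides the
# minimum change count, the per-node sets of states attainable in some
# optimal labeling and the number of optimal labelings (hence uniqueness).

DEFAULT_MOTIF_CLASSES <- c("YDG", "FDG", "LDG", "VDG")

#' Extract and classify a signature motif from a lifted window
#'
#' @param lifted A \code{lifted_region} (window of width 3).
#' @param classes Named motif classes; anything else is \code{"other"}.
#' @return A list of class \code{motif_assignment}: \code{seq_id},
#'   \code{motif}, \code{class_label}, \code{position}, \code{missing}.
#' @export
extract_signature <- function(lifted, classes = DEFAULT_MOTIF_CLASSES) {
  if (!identical(lifted$status, "complete") || nchar(lifted$subsequence) != 3L) {
    return(structure(list(seq_id = lifted$query_id, motif = lifted$subsequence,
                          class_label = "other", position = lifted$q_start,
                          missing = TRUE),
                     class = "motif_assignment"))
  }
  motif <- toupper(lifted$subsequence)
  structure(list(seq_id = lifted$query_id, motif = motif,
                 class_label = if (motif %in% classes) motif else "other",
                 position = lifted$q_start, missing = FALSE),
            class = "motif_assignment")
}

#' Classify signature motifs for a whole lifted-region table
#'
#' @param lifted_table Data.frame from [lift_regions_all()], optionally
#'   joined with metadata (a \code{species} column is carried through).
#' @param region_name Name of the signature region (default
#'   \code{"signature"}).
#' @param classes Named motif classes.
#' @return Data.frame with \code{seq_id}, \code{species} (if available),
#'   \code{motif}, \code{class_label}, \code{position}, \code{missing}.
#' @export
assign_signatures <- function(lifted_table, region_name = "signature",
                              classes = DEFAULT_MOTIF_CLASSES) {
  sel <- lifted_table[lifted_table$name == region_name, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    lr <- list(query_id = sel$query_id[i], q_start = sel$q_start[i],
               q_end = sel$q_end[i], status = sel$status[i],
               subsequence = sel$subsequence[i])
    a <- extract_signature(lr, classes)
    data.frame(seq_id = a$seq_id,
               species = if ("species" %in% names(sel)) sel$species[i] else NA_character_,
               motif = a$motif, class_label = a$class_label,
               position = a$position, missing = a$missing,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Tip labels under a node (the node itself if it is a tip).
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  children <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(children, tips_under, tree = tree))
}

node_number <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  NA_integer_
}

node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
  if (is.na(lab) || !nzchar(lab)) sprintf("node%d", node) else lab
}

#' Tally motif classes per clade
#'
#' Counts, for each requested clade, how many species carry each motif
#' class. Clades are named internal nodes of the taxonomy (or single tips);
#' nested clades are tallied independently, so a species contributes to its
#' own clade and to every requested ancestor clade.
#'
#' @param assignments Data.frame with \code{species} and \code{class_label}
#'   (e.g. from [assign_signatures()] joined with metadata).
#' @param tree Taxonomy ([ape::phylo]), leaves labeled by species.
#' @param clades Character vector of clade labels to tally.
#' @param classes Motif classes to report as columns (plus \code{other}).
#' @return Data.frame, one row per clade: \code{clade}, one count column per
#'   class, \code{other}, and \code{n_species}.
#' @export
tally_by_clade <- function(assignments, tree, clades,
                           classes = DEFAULT_MOTIF_CLASSES) {
  not_in_tree <- setdiff(unique(assignments$species), tree$tip.label)
  if (length(not_in_tree) > 0L) {
    stop(sprintf("species not in taxonomy: %s",
                 paste(not_in_tree, collapse = ", ")))
  }
  cols <- c(classes, "other")
  rows <- lapply(clades, function(cl) {
    node <- node_number(tree, cl)
    if (is.na(node)) stop(sprintf("clade label not found in taxonomy: %s", cl))
    members <- tips_under(tree, node)
    sel <- assignments[assignments$species %in% members, , drop = FALSE]
    counts <- table(factor(sel$class_label, levels = cols))
    out <- data.frame(clade = cl, stringsAsFactors = FALSE)
    for (cc in cols) out[[cc]] <- as.integer(counts[[cc]])
    out$n_species <- nrow(sel)
    out
  })
  do.call(rbind, rows)
}

#' Minimal substitution history of discrete states on a taxonomy
#'
#' Unweighted Sankoff parsimony on a rooted, possibly multifurcating tree:
#' computes the exact minimum number of state changes, the per-node sets of
#' states realized by at least one optimal labeling, one deterministic
#' optimal labeling with its transition branches, and whether the optimal
#' labeling is unique (by counting optimal labelings).
#'
#' The reported labeling keeps the parent state wherever optimal, pushing
#' unavoidable changes away from the root; remaining ties are broken
#' alphabetically.
#'
#' @param tree Rooted [ape::phylo] taxonomy (multifurcations allowed).
#' @param leaf_states Named character vector: tip label -> state.
#' @return An object of class \code{parsimony_result}: \code{min_changes},
#'   \code{transitions} (data.frame parent, child, from, to),
#'   \code{node_states} (the chosen labeling, named by node label),
#'   \code{candidate_sets} (list per node of states attainable in an optimal
#'   labeling), \code{is_unique}, \code{n_optimal_labelings}.
#' @export
parsimony_states <- function(tree, leaf_states) {
  ntip <- length(tree$tip.label)
  unlabeled <- setdiff(tree$tip.label, names(leaf_states))
  if (length(unlabeled) > 0L) {
    stop(sprintf("leaf state missing for: %s", paste(unlabeled, collapse = ", ")))
  }
  states <- sort(unique(as.character(leaf_states[tree$tip.label])))
  S <- length(states)
  N <- ntip + tree$Nnode
  root <- ntip + 1L

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge

  up <- matrix(Inf, nrow = N, ncol = S, dimnames = list(NULL, states))
  ways <- matrix(0, nrow = N, ncol = S, dimnames = list(NULL, states))
  for (i in seq_len(ntip)) {
    s <- as.character(leaf_states[[tree$tip.label[i]]])
    up[i, s] <- 0
    ways[i, s] <- 1
  }
  internal <- unique(edges[, 1])
  up[internal, ] <- 0
  ways[internal, ] <- 1

  # child's contribution to parent state s: min over child states t of
  # up[child, t] + [s != t]; contrib is cached for the down pass.
  contrib <- vector("list", N)
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    m <- min(up[child, ])
    cc <- pmin(up[child, ], m + 1)
    contrib[[child]] <- cc
    up[parent, ] <- up[parent, ] + cc
    # labeling counts: ways over child states achieving the contribution
    w <- vapply(seq_len(S), function(s) {
      cost_t <- up[child, ] + as.numeric(seq_len(S) != s)
      sum(ways[child, cost_t == cc[s]])
    }, numeric(1))
    ways[parent, ] <- ways[parent, ] * w
  }

  min_changes <- min(up[root, ])
  n_optimal <- sum(ways[root, up[root, ] == min_changes])

  # Down pass: down[v, s] = best cost of the rest of the tree given state s
  # at v; combined with up[v, s] it gives the per-node candidate sets.
  down <- matrix(Inf, nrow = N, ncol = S)
  down[root, ] <- 0
  for (k in rev(seq_len(nrow(edges)))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    A <- down[parent, ] + up[parent, ] - contrib[[child]]
    down[child, ] <- pmin(A, min(A) + 1)
  }
  candidate_sets <- lapply(seq_len(N), function(v) {
    states[abs(up[v, ] + down[v, ] - min_changes) < 1e-9]
  })
  names(candidate_sets) <- vapply(seq_len(N), function(v) node_label(tree, v),
                                  character(1))

  # One deterministic optimal labeling: root takes the alphabetically first
  # optimal state; children keep the parent state whenever optimal.
  assign <- character(N)
  root_opts <- states[up[root, ] == min_changes]
  assign[root] <- root_opts[1]
  for (k in rev(seq_len(nrow(edges)))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    ps <- assign[parent]
    cc_target <- contrib[[child]][match(ps, states)]
    opts <- states[(up[child, ] + as.integer(states != ps)) == cc_target]
    assign[child] <- if (ps %in% opts) ps else opts[1]
  }

  trans <- list()
  for (k in rev(seq_len(nrow(edges)))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    if (assign[parent] != assign[child]) {
      trans[[length(trans) + 1L]] <- data.frame(
        parent = node_label(tree, parent), child = node_label(tree, child),
        from = assign[parent], to = assign[child], stringsAsFactors = FALSE)
    }
  }
  transitions <- if (length(trans) > 0L) do.call(rbind, trans) else
    data.frame(parent = character(), child = character(),
               from = character(), to = character(), stringsAsFactors = FALSE)

  node_states <- assign
  names(node_states) <- vapply(seq_len(N), function(v) node_label(tree, v),
                               character(1))

  structure(list(min_changes = as.integer(min_changes),
                 transitions = transitions,
                 node_states = node_states,
                 candidate_sets = candidate_sets,
                 is_unique = n_optimal == 1,
                 n_optimal_labelings = n_optimal),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("parsimony_result: %d change(s), %s optimal labeling(s)\n",
              x$min_changes, format(x$n_optimal_labelings)))
  if (nrow(x$transitions) > 0L) {
    for (i in seq_len(nrow(x$transitions))) {
      cat(sprintf("  %s -> %s : %s -> %s\n",
                  x$transitions$parent[i], x$transitions$child[i],
                  x$transitions$from[i], x$transitions$to[i]))
    }
  }
  invisible(x)
}
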