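# Seeded ortholog-family simulator.
#
# Families are evolved root-to-leaves along a given taxonomy under a simple
# per-site replacement process: each site draws a Poisson number of events
# per branch (rate x branch length) and an event resamples the residue
# within the site's allowed set. Annotated windows carry per-position
# constraints - fixed residues (never substitute), hydrophobic anchors
# (resample within {L,I,V,F,M}), or slowed free sites - which produces the
# conservation structure the analysis assumes: strongly conserved anchored
# windows in a variable background. Indels are placed only outside windows,
# so planted window coordinates stay recoverable ground truth. Motif
# transitions (e.g. YDG -> FDG on the branch into a named clade) are applied
# deterministically on their branches and inherited below.

#' Build a simulation configuration
#'
#' @param tree [ape::phylo] with branch lengths (substitutions/site) and
#'   labeled internal nodes, or a newick string.
#' @param root_length Ungapped root sequence length.
#' @param windows List of window definitions: each a list with \code{name},
#'   \code{start}, \code{end}, \code{template} (root residues, width
#'   end-start+1) and \code{constraints} (character vector per position:
#'   \code{"fixed"}, \code{"hydro"}, or \code{"slow"}).
#' @param transitions List of planted motif transitions: each a list with
#'   \code{child} (node or tip label; the transition happens on the branch
#'   into it), \code{window}, \code{to} (replacement motif).
#' @param subfamily Family label (e.g. \code{"IRF5"}).
#' @param clade_map Named character vector: species -> taxon group.
#' @param rates Per-category substitution rate multipliers.
#' @param subst_rate Global substitution rate scale.
#' @param indel_rate Indel events per free site per unit branch length.
#' @param indel_max_len Maximum indel length.
#' @param composition Residue sampling weights for free sites (default
#'   uniform over the 20 residues).
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(tree, root_length, windows, transitions = list(),
                       subfamily = "FAM", clade_map = NULL,
                       rates = c(free = 1.0, slow = 0.2, hydro = 0.25, fixed = 0),
                       subst_rate = 1.0, indel_rate = 0.004, indel_max_len = 4L,
                       composition = NULL, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  starts <- vapply(windows, function(w) w$start, numeric(1))
  ends <- vapply(windows, function(w) w$end, numeric(1))
  if (length(windows) > 1L) {
    ord <- order(starts)
    if (any(starts[ord][-1] <= ends[ord][-length(ord)])) {
      stop("windows overlap")
    }
  }
  for (w in windows) {
    width <- w$end - w$start + 1L
    if (nchar(w$template) != width || length(w$constraints) != width) {
      stop(sprintf("window %s: template/constraints must have width %d",
                   w$name, width))
    }
  }
  known <- c(tree$tip.label, tree$node.label)
  for (tr in transitions) {
    if (!(tr$child %in% known)) {
      stop(sprintf("transition references unknown node '%s'", tr$child))
    }
    w <- Filter(function(x) x$name == tr$window, windows)
    if (length(w) == 0L) stop(sprintf("transition references unknown window '%s'", tr$window))
    if (nchar(tr$to) != (w[[1]]$end - w[[1]]$start + 1L)) {
      stop(sprintf("transition motif '%s' incompatible with window width", tr$to))
    }
  }
  if (is.null(composition)) composition <- stats::setNames(rep(1 / 20, 20), AA20)
  structure(list(tree = tree, root_length = as.integer(root_length),
                 windows = windows, transitions = transitions,
                 subfamily = subfamily, clade_map = clade_map,
                 rates = rates, subst_rate = subst_rate,
                 indel_rate = indel_rate, indel_max_len = as.integer(indel_max_len),
                 composition = composition, seed = as.integer(seed)),
            class = "sim_config")
}

# Site categories: 0 free background; per-window constraint codes.
build_root_state <- function(config) {
  n <- config$root_length
  chars <- sample(names(config$composition), n, replace = TRUE,
                  prob = config$composition)
  winid <- integer(n)
  category <- rep("free", n)
  for (k in seq_along(config$windows)) {
    w <- config$windows[[k]]
    idx <- w$start:w$end
    if (max(idx) > n) stop(sprintf("window %s exceeds root length", w$name))
    chars[idx] <- seq_chars(w$template)
    winid[idx] <- k
    category[idx] <- w$constraints
  }
  list(chars = chars, winid = winid, category = category)
}

resample_site <- function(current, category, composition) {
  pool <- switch(category,
                 hydro = HYDROPHOBIC,
                 names(composition))
  pool <- setdiff(pool, current)
  if (length(pool) == 0L) return(current)
  sample(pool, 1L)
}

evolve_branch <- function(state, brlen, config, child_label) {
  chars <- state$chars; winid <- state$winid; category <- state$category
  n <- length(chars)
  rate <- unname(config$rates[category]) * config$subst_rate
  events <- stats::rpois(n, rate * brlen)
  for (i in which(events > 0L)) {
    for (e in seq_len(events[i])) {
      chars[i] <- resample_site(chars[i], category[i], config$composition)
    }
  }
  applied <- list()
  for (tr in config$transitions) {
    if (identical(tr$child, child_label)) {
      k <- which(vapply(config$windows, function(w) w$name == tr$window, logical(1)))
      idx <- which(winid == k)
      from <- paste(chars[idx], collapse = "")
      chars[idx] <- seq_chars(tr$to)
      applied[[length(applied) + 1L]] <- list(child = child_label,
                                              window = tr$window,
                                              from = from, to = tr$to)
    }
  }
  free_idx <- which(winid == 0L)
  n_ind <- stats::rpois(1L, config$indel_rate * brlen * length(free_idx))
  for (e in seq_len(n_ind)) {
    free_idx <- which(winid == 0L)
    if (length(free_idx) < 2L) break
    type <- sample(c("ins", "del"), 1L)
    len <- sample.int(config$indel_max_len, 1L)
    at <- sample(free_idx, 1L)
    if (type == "del") {
      run <- at
      while (length(run) < len && (at + length(run)) <= length(winid) &&
             winid[at + length(run)] == 0L) {
        run <- c(run, at + length(run))
      }
      keep <- setdiff(seq_along(chars), run)
      chars <- chars[keep]; winid <- winid[keep]; category <- category[keep]
    } else {
      ins <- sample(names(config$composition), len, replace = TRUE,
                    prob = config$composition)
      chars <- append(chars, ins, after = at)
      winid <- append(winid, integer(len), after = at)
      category <- append(category, rep("free", len), after = at)
    }
  }
  list(state = list(chars = chars, winid = winid, category = category),
       applied = applied)
}

#' Simulate one ortholog family along a taxonomy
#'
#' @param config A \code{sim_config}.
#' @return A list with \code{records} (data.frame of protein records with
#'   species/taxon_group/subfamily columns) and \code{truth} (class
#'   \code{synthetic_truth}: per-leaf true window coordinates after indels,
#'   per-branch applied transitions, the root sequence, and the seed).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  root_state <- build_root_state(config)

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  blens <- po$edge.length %||% rep(0, nrow(edges))
  preorder <- rev(seq_len(nrow(edges)))

  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- root_state
  applied_all <- list()
  for (k in preorder) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    res <- evolve_branch(states[[parent]], blens[k], config,
                         node_label(tree, child))
    states[[child]] <- res$state
    applied_all <- c(applied_all, res$applied)
  }

  species <- tree$tip.label
  ids <- paste(config$subfamily, species, sep = "_")
  seqs <- character(ntip)
  window_truth <- list()
  for (i in seq_len(ntip)) {
    st <- states[[i]]
    seqs[i] <- paste(st$chars, collapse = "")
    wt <- lapply(seq_along(config$windows), function(k) {
      idx <- which(st$winid == k)
      list(name = config$windows[[k]]$name,
           start = min(idx), end = max(idx),
           sequence = paste(st$chars[idx], collapse = ""))
    })
    names(wt) <- vapply(config$windows, function(w) w$name, character(1))
    window_truth[[species[i]]] <- wt
  }
  groups <- if (!is.null(config$clade_map)) {
    unname(config$clade_map[species])
  } else rep(NA_character_, ntip)
  records <- data.frame(id = ids, sequence = seqs, description = "",
                        species = species, taxon_group = groups,
                        subfamily = config$subfamily, accession = "",
                        stringsAsFactors = FALSE)
  truth <- structure(list(schema_version = 1L,
                          subfamily = config$subfamily,
                          windows = window_truth,
                          transitions = applied_all,
                          root_sequence = paste(root_state$chars, collapse = ""),
                          seed = config$seed),
                     class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' Write a simulated family to disk as a loadable fixture
#'
#' Emits FASTA, metadata TSV, the taxonomy as newick, and the ground truth
#' as versioned JSON, all readable back through the package's own readers.
#'
#' @param records Records data.frame from [simulate_family()].
#' @param truth \code{synthetic_truth} from [simulate_family()].
#' @param tree The taxonomy used.
#' @param outdir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
emit_fixture <- function(records, truth, tree, outdir) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create directory %s", outdir))
  paths <- c(fasta = file.path(outdir, "family.fasta"),
             metadata = file.path(outdir, "metadata.tsv"),
             tree = file.path(outdir, "tree.nwk"),
             truth = file.path(outdir, "truth.json"))
  write_fasta(records, paths[["fasta"]])
  write_tsv(data.frame(seq_id = records$id, species = records$species,
                       taxon_group = records$taxon_group,
                       subfamily = records$subfamily,
                       accession = records$accession,
                       stringsAsFactors = FALSE),
            paths[["metadata"]])
  ape::write.tree(tree, paths[["tree"]])
  jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a truth JSON written by [emit_fixture()]
#' @param path Path to \code{truth.json}.
#' @return A \code{synthetic_truth} list.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = FALSE)
  tr$schema_version <- as.integer(tr$schema_version)
  tr$seed <- as.integer(tr$seed)
  structure(tr, class = "synthetic_truth")
}

# newick builder for one rake clade
clade_newick <- function(tips, tip_len, label, stem_len) {
  sprintf("(%s)%s:%g",
          paste(sprintf("%s:%g", tips, tip_len), collapse = ","),
          label, stem_len)
}

sp_names <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))

# Default jawed-vertebrate-shaped taxonomy: 30 species in 5 labeled groups.
# Each clade on whose stem a motif transition is planted (Neoaves,
# Passeriformes, Passeridae) has the derived state witnessed by at least two
# child lineages, so the planted history is the unique most-parsimonious
# labeling and transition recovery is well-posed. Neoaves and Passeriformes
# are multifurcating, exercising the polytomy-capable parsimony.
default_taxonomy <- function() {
  shark <- sp_names("shark", 4); mam <- sp_names("mammal", 6)
  ratite <- sp_names("ratite", 3); fowl <- sp_names("fowl", 4)
  neo <- sp_names("neoave", 7); pass <- sp_names("passerine", 3)
  spar <- sp_names("sparrow", 3)
  nwk <- sprintf(
    "(%s,(%s,(%s,(%s,(%s,%s,(%s,%s:0.09,%s)Passeriformes:0.06)Neoaves:0.08)Neognathae:0.05)Aves:0.15)Osteichthyes:0.1)Gnathostomata;",
    clade_newick(shark, 0.08, "Chondrichthyes", 0.25),
    clade_newick(mam, 0.04, "Mammalia", 0.2),
    clade_newick(ratite, 0.06, "Palaeognathae", 0.12),
    clade_newick(fowl, 0.05, "Galloanserae", 0.1),
    clade_newick(neo[1:4], 0.05, "NeoavesA", 0.06),
    clade_newick(neo[5:7], 0.05, "NeoavesB", 0.06),
    clade_newick(pass[1:2], 0.04, "PasserinesA", 0.05),
    pass[3],
    clade_newick(spar, 0.03, "Passeridae", 0.05))
  tree <- ape::read.tree(text = nwk)
  clade_map <- c(stats::setNames(rep("Chondrichthyes", 4), shark),
                 stats::setNames(rep("Mammalia", 6), mam),
                 stats::setNames(rep("Palaeognathae", 3), ratite),
                 stats::setNames(rep("Galloanserae", 4), fowl),
                 stats::setNames(rep("Neoaves", 13), c(neo, pass, spar)))
  list(tree = tree, clade_map = clade_map)
}

nes_window_def <- function(start = 150L) {
  # 12-residue window; hydrophobic anchors at offsets 2, 5, 8, 10 so every
  # descendant window contains a consensus match (spacers 2,2 then X then
  # anchor 4).
  list(name = "NES", start = start, end = start + 11L,
       template = "ALDALSALQLDE",
       constraints = c("slow", "hydro", "slow", "slow", "hydro", "slow",
                       "slow", "hydro", "slow", "hydro", "slow", "slow"))
}

srr_window_def <- function(start = 447L) {
  # Serine-rich 22-mer, invariant across the family (the within-mammal
  # identity observed in real data, taken to its simple limit).
  list(name = "SRR", start = start, end = start + 21L,
       template = "SSSESSSLSSSNSSGSSSESDS",
       constraints = rep("fixed", 22L))
}

signature_window_def <- function(start = 60L, template = "YDG") {
  list(name = "signature", start = start, end = start + 2L,
       template = template, constraints = rep("fixed", 3L))
}

irf5_transitions <- function() {
  list(list(child = "Neoaves", window = "signature", to = "FDG"),
       list(child = "Passeriformes", window = "signature", to = "LDG"),
       list(child = "Passeridae", window = "signature", to = "VDG"))
}

#' Default two-family synthetic fixture
#'
#' Thirty species in five labeled taxon groups (cartilaginous fishes,
#' mammals, palaeognaths, galloanserans, neoavians), one IRF5-like family
#' carrying NES + SRR + signature windows with the nested
#' YDG -> FDG -> LDG -> VDG transitions planted on the neoavian,
#' passeriform and passerid stem branches, and one IRF6-like family whose
#' signature never changes.
#'
#' @param seed Integer seed.
#' @param indel_rate Indel rate (set 0 for indel-free families).
#' @return A list: \code{records} (both families), \code{metadata},
#'   \code{tree}, \code{configs}, \code{truths} (per family), and
#'   \code{regions} - region annotations on the family reference records
#'   (the first mammal of each family), derived from the reference leaf's
#'   true window coordinates.
#' @export
default_fixture <- function(seed = 1L, indel_rate = 0.004) {
  tax <- default_taxonomy()
  cfg5 <- sim_config(tax$tree, root_length = 500L,
                     windows = list(signature_window_def(60L),
                                    nes_window_def(150L),
                                    srr_window_def(447L)),
                     transitions = irf5_transitions(),
                     subfamily = "IRF5", clade_map = tax$clade_map,
                     indel_rate = indel_rate, seed = seed)
  cfg6 <- sim_config(tax$tree, root_length = 480L,
                     windows = list(signature_window_def(60L)),
                     transitions = list(),
                     subfamily = "IRF6", clade_map = tax$clade_map,
                     indel_rate = indel_rate, seed = seed + 1L)
  fam5 <- simulate_family(cfg5)
  fam6 <- simulate_family(cfg6)
  records <- rbind(fam5$records, fam6$records)
  metadata <- data.frame(seq_id = records$id, species = records$species,
                         taxon_group = records$taxon_group,
                         subfamily = records$subfamily,
                         accession = records$accession,
                         stringsAsFactors = FALSE)
  ref_species <- "mammal_01"
  regions <- list(
    IRF5 = lapply(fam5$truth$windows[[ref_species]], function(w) {
      region_annotation(w$name, paste("IRF5", ref_species, sep = "_"),
                        w$start, w$end)
    }),
    IRF6 = lapply(fam6$truth$windows[[ref_species]], function(w) {
      region_annotation(w$name, paste("IRF6", ref_species, sep = "_"),
                        w$start, w$end)
    }))
  list(records = records, metadata = metadata, tree = tax$tree,
       configs = list(IRF5 = cfg5, IRF6 = cfg6),
       truths = list(IRF5 = fam5$truth, IRF6 = fam6$truth),
       reference_ids = c(IRF5 = paste("IRF5", ref_species, sep = "_"),
                         IRF6 = paste("IRF6", ref_species, sep = "_")),
       regions = regions)
}

#' Bird signature-motif fixture (58 species)
#'
#' A bird taxonomy with 58 species across Palaeognathae, Galloanserae,
#' other Neoaves, other Passeriformes and Passeridae - the species count of
#' the avian signature-motif survey - with the nested YDG -> FDG -> LDG ->
#' VDG transitions planted in the IRF5-like family and a fully conserved
#' YDG in the IRF6-like family.
#'
#' @param seed Integer seed.
#' @return Same shape as [default_fixture()] (no SRR/NES windows; shorter
#'   sequences), plus \code{clades}, the clade labels to tally.
#' @export
bird_motif_fixture <- function(seed = 1L) {
  ratite <- sp_names("ratite", 4); fowl <- sp_names("fowl", 6)
  neo <- sp_names("neoave", 28); pass <- sp_names("passerine", 15)
  spar <- sp_names("sparrow", 5)
  nwk <- sprintf(
    "(%s,(%s,(%s,%s,(%s,%s,%s)Passeriformes:0.06)Neoaves:0.08)Neognathae:0.05)Aves;",
    clade_newick(ratite, 0.06, "Palaeognathae", 0.12),
    clade_newick(fowl, 0.05, "Galloanserae", 0.1),
    clade_newick(neo[1:15], 0.05, "NeoavesA", 0.06),
    clade_newick(neo[16:28], 0.05, "NeoavesB", 0.06),
    clade_newick(pass[1:8], 0.04, "PasserinesA", 0.05),
    clade_newick(pass[9:15], 0.04, "PasserinesB", 0.05),
    clade_newick(spar, 0.03, "Passeridae", 0.05))
  tree <- ape::read.tree(text = nwk)
  clade_map <- c(stats::setNames(rep("Palaeognathae", length(ratite)), ratite),
                 stats::setNames(rep("Galloanserae", length(fowl)), fowl),
                 stats::setNames(rep("Neoaves", length(c(neo, pass, spar))),
                                 c(neo, pass, spar)))
  cfg5 <- sim_config(tree, root_length = 200L,
                     windows = list(signature_window_def(60L)),
                     transitions = irf5_transitions(),
                     subfamily = "IRF5", clade_map = clade_map, seed = seed)
  cfg6 <- sim_config(tree, root_length = 200L,
                     windows = list(signature_window_def(60L)),
                     transitions = list(),
                     subfamily = "IRF6", clade_map = clade_map, seed = seed + 1L)
  fam5 <- simulate_family(cfg5)
  fam6 <- simulate_family(cfg6)
  records <- rbind(fam5$records, fam6$records)
  metadata <- data.frame(seq_id = records$id, species = records$species,
                         taxon_group = records$taxon_group,
                         subfamily = records$subfamily,
                         accession = records$accession,
                         stringsAsFactors = FALSE)
  ref_species <- tree$tip.label[1]
  regions <- list(
    IRF5 = lapply(fam5$truth$windows[[ref_species]], function(w) {
      region_annotation(w$name, paste("IRF5", ref_species, sep = "_"),
                        w$start, w$end)
    }),
    IRF6 = lapply(fam6$truth$windows[[ref_species]], function(w) {
      region_annotation(w$name, paste("IRF6", ref_species, sep = "_"),
                        w$start, w$end)
    }))
  list(records = records, metadata = metadata, tree = tree,
       configs = list(IRF5 = cfg5, IRF6 = cfg6),
       truths = list(IRF5 = fam5$truth, IRF6 = fam6$truth),
       reference_ids = c(IRF5 = paste("IRF5", ref_species, sep = "_"),
                         IRF6 = paste("IRF6", ref_species, sep = "_")),
       regions = regions,
       clades = c("Aves", "Palaeognathae", "Galloanserae", "Neoaves",
                  "Passeriformes", "Passeridae"))
}

#' Synthetic stand-in STAT2/IRF9 sequence pairs for interface checks
#'
#' Constructed sequences, not database records: a STAT2-like reference with
#' phenylalanine at position 174 and an IRF9-like reference with the groove
#' residues L274/A276/F283/Q285, plus query pairs at increasing divergence
#' that keep the five interface residues intact - a nearly identical
#' "human-like" pair and two strongly diverged "cartilaginous-fish-like"
#' pairs, one carrying an ambiguous X away from the interface and a short
#' insertion, so coordinate lifting is actually exercised. Use these to
#' test the interface-conservation machinery when real accession records
#' are not available.
#'
#' @param seed Integer seed for the deterministic construction.
#' @return A list with \code{refs} (named list role -> record) and
#'   \code{queries} (named list of named lists role -> record).
#' @export
synthetic_interface_pairs <- function(seed = 1711L) {
  set.seed(seed)
  interface <- list(STAT2 = c(`174` = "F"),
                    IRF9 = c(`274` = "L", `276` = "A", `283` = "F", `285` = "Q"))
  make_ref <- function(len, sites) {
    ch <- sample(AA20, len, replace = TRUE)
    ch[as.integer(names(sites))] <- unname(sites)
    paste(ch, collapse = "")
  }
  diverge <- function(sequence, prop, protect, x_at = NULL, insert_at = NULL) {
    ch <- seq_chars(sequence)
    free <- setdiff(seq_along(ch), protect)
    mut <- sample(free, round(prop * length(free)))
    ch[mut] <- vapply(ch[mut], function(cur) sample(setdiff(AA20, cur), 1L),
                      character(1))
    if (!is.null(x_at)) ch[x_at] <- "X"
    if (!is.null(insert_at)) {
      ch <- append(ch, sample(AA20, 3L, replace = TRUE), after = insert_at)
    }
    paste(ch, collapse = "")
  }
  stat2 <- make_ref(320L, interface$STAT2)
  irf9 <- make_ref(400L, interface$IRF9)
  p_stat2 <- as.integer(names(interface$STAT2))
  p_irf9 <- as.integer(names(interface$IRF9))
  refs <- list(STAT2 = list(id = "STAT2_ref", sequence = stat2),
               IRF9 = list(id = "IRF9_ref", sequence = irf9))
  queries <- list(
    human_like = list(
      STAT2 = list(id = "STAT2_human_like",
                   sequence = diverge(stat2, 0.02, p_stat2)),
      IRF9 = list(id = "IRF9_human_like",
                  sequence = diverge(irf9, 0.02, p_irf9))),
    stingray_like = list(
      STAT2 = list(id = "STAT2_stingray_like",
                   sequence = diverge(stat2, 0.25, p_stat2)),
      IRF9 = list(id = "IRF9_stingray_like",
                  sequence = diverge(irf9, 0.25, p_irf9, insert_at = 50L))),
    shark_like = list(
      STAT2 = list(id = "STAT2_shark_like",
                   sequence = diverge(stat2, 0.25, p_stat2)),
      IRF9 = list(id = "IRF9_shark_like",
                  sequence = diverge(irf9, 0.25, p_irf9, x_at = 258L))))
  list(refs = refs, queries = queries)
}
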