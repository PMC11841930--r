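# End-to-end pipeline: align/lift -> NES scan -> conservation profiles ->
# signature tally + parsimony -> optional structure/interface checks.
# Every stage writes a TSV/JSON artifact into the report directory and a
# summary JSON records per-stage counts; a failing stage stops the run and
# is recorded, later stages are skipped. Outputs are deterministic:
# re-running with identical inputs reproduces the report tree byte for
# byte.

#' Build a pipeline configuration
#'
#' @param fasta,metadata,tree Paths to the ortholog FASTA, metadata TSV and
#'   newick taxonomy (tree may be NULL: the parsimony stage is then skipped
#'   with a warning).
#' @param reference_ids Named character vector: subfamily -> reference
#'   sequence id.
#' @param regions List of region annotations (see [region_annotation()]);
#'   each applies to the subfamily whose reference it names.
#' @param outdir Report directory.
#' @param clades Clade labels to tally (default: every labeled internal
#'   node of the taxonomy).
#' @param motif_region Name of the signature region (default
#'   \code{"signature"}).
#' @param motif_classes Signature classes (default YDG/FDG/LDG/VDG).
#' @param structures Optional named list: role -> PDB path, plus
#'   \code{interface_map}/reference/query records for the interface stage.
#' @param plddt_threshold,rmsd_threshold Structure-stage thresholds
#'   (defaults 50 and 1.0 Angstrom).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(fasta, metadata, tree = NULL, reference_ids,
                            regions, outdir, clades = NULL,
                            motif_region = "signature",
                            motif_classes = DEFAULT_MOTIF_CLASSES,
                            structures = NULL,
                            plddt_threshold = 50, rmsd_threshold = 1.0) {
  for (p in c(fasta, metadata, tree)) {
    if (!is.null(p) && !file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  structure(list(fasta = fasta, metadata = metadata, tree = tree,
                 reference_ids = reference_ids, regions = regions,
                 outdir = outdir, clades = clades,
                 motif_region = motif_region, motif_classes = motif_classes,
                 structures = structures,
                 plddt_threshold = plddt_threshold,
                 rmsd_threshold = rmsd_threshold),
            class = "pipeline_config")
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order: read inputs; pairwise-align every ortholog to its
#' subfamily reference and lift the annotated regions; scan every sequence
#' for NES consensus matches; build per-taxon-group conservation profiles
#' for each region; extract and tally signature motifs by clade and infer
#' the minimal substitution history on the taxonomy; optionally check
#' structures and interface residues.
#'
#' @param config A \code{pipeline_config}.
#' @return The summary list, invisibly. Artifacts are written under
#'   \code{config$outdir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(stages = list(), failed_stage = NULL)
  finish <- function() {
    write_json_stable(summary, file.path(config$outdir, "summary.json"))
    invisible(summary)
  }
  run_stage <- function(name, fun) {
    if (!is.null(summary$failed_stage)) return(NULL)
    res <- tryCatch(fun(), error = function(e) {
      summary$failed_stage <<- name
      summary$stages[[name]] <<- list(status = "error",
                                      message = conditionMessage(e))
      NULL
    })
    res
  }

  inputs <- run_stage("read", function() {
    records <- read_fasta(config$fasta)
    md <- read_metadata(config$metadata)
    records <- join_metadata(records, md)
    tree <- if (!is.null(config$tree)) read_taxonomy(config$tree) else NULL
    missing_refs <- setdiff(config$reference_ids, records$id)
    if (length(missing_refs) > 0L) {
      stop(sprintf("reference id(s) not in FASTA: %s",
                   paste(missing_refs, collapse = ", ")))
    }
    summary$stages$read <<- list(status = "ok", n_sequences = nrow(records),
                                 n_subfamilies = length(unique(records$subfamily)))
    list(records = records, tree = tree)
  })
  if (is.null(inputs)) return(finish())
  records <- inputs$records

  lifted <- run_stage("lift", function() {
    out <- list()
    for (fam in names(config$reference_ids)) {
      ref_id <- config$reference_ids[[fam]]
      fam_rec <- records[records$subfamily == fam, , drop = FALSE]
      ref <- fam_rec[fam_rec$id == ref_id, , drop = FALSE]
      fam_regions <- Filter(function(r) identical(r$ref_id, ref_id),
                            config$regions)
      if (length(fam_regions) == 0L) next
      lt <- lift_regions_all(ref, fam_rec, fam_regions)
      lt$subfamily <- fam
      out[[fam]] <- lt
    }
    lifted <- do.call(rbind, out)
    row.names(lifted) <- NULL
    idx <- match(lifted$query_id, records$id)
    lifted$species <- records$species[idx]
    lifted$taxon_group <- records$taxon_group[idx]
    write_tsv(lifted[, c("query_id", "name", "q_start", "q_end", "status",
                         "subsequence", "subfamily", "species", "taxon_group")],
              file.path(config$outdir, "lifted_regions.tsv"))
    summary$stages$lift <<- list(status = "ok", n_lifted = nrow(lifted),
                                 n_complete = sum(lifted$status == "complete"))
    lifted
  })
  if (is.null(lifted)) return(finish())

  hits <- run_stage("scan", function() {
    hits <- scan_nes_all(records, lifted)
    write_tsv(hits, file.path(config$outdir, "nes_hits.tsv"))
    nes_windows <- lifted[lifted$name == "NES" & lifted$status != "missing", ,
                          drop = FALSE]
    conforming <- 0L
    for (i in seq_len(nrow(nes_windows))) {
      m <- scan_nes(records$sequence[records$id == nes_windows$query_id[i]])
      wc <- window_check(m, as.list(nes_windows[i, ]))
      if (wc$conforms) conforming <- conforming + 1L
    }
    summary$stages$scan <<- list(status = "ok", n_matches = nrow(hits),
                                 n_nes_windows = nrow(nes_windows),
                                 n_conforming_windows = conforming)
    hits
  })
  if (is.null(hits)) return(finish())

  run_stage("profiles", function() {
    region_names <- unique(lifted$name)
    n_profiles <- 0L
    for (rn in region_names) {
      profs <- profile_by_group(lifted, rn)
      for (grp in names(profs)) {
        export_logo_data(profs[[grp]],
                         file.path(config$outdir,
                                   sprintf("logo_%s_%s.tsv", rn, grp)))
        n_profiles <- n_profiles + 1L
      }
    }
    summary$stages$profiles <<- list(status = "ok", n_profiles = n_profiles)
    TRUE
  })
  if (!is.null(summary$failed_stage)) return(finish())

  run_stage("motifs", function() {
    assignments <- assign_signatures(lifted, config$motif_region,
                                     config$motif_classes)
    if (is.null(assignments) || nrow(assignments) == 0L) {
      summary$stages$motifs <<- list(status = "ok", n_assignments = 0L,
                                     note = "no signature region annotated")
      return(TRUE)
    }
    idx <- match(assignments$seq_id, records$id)
    assignments$subfamily <- records$subfamily[idx]
    write_tsv(assignments, file.path(config$outdir, "motif_assignments.tsv"))
    if (is.null(inputs$tree)) {
      warning("no taxonomy supplied: tally and parsimony skipped")
      summary$stages$motifs <<- list(status = "ok",
                                     n_assignments = nrow(assignments),
                                     note = "no taxonomy: tally/parsimony skipped")
      return(TRUE)
    }
    tree <- inputs$tree
    clades <- config$clades
    if (is.null(clades)) {
      clades <- tree$node.label[!is.na(tree$node.label) & nzchar(tree$node.label)]
    }
    n_trans <- 0L
    for (fam in unique(assignments$subfamily)) {
      sel <- assignments[assignments$subfamily == fam & !assignments$missing, ,
                         drop = FALSE]
      tally <- tally_by_clade(sel, tree, clades, config$motif_classes)
      write_tsv(tally, file.path(config$outdir,
                                 sprintf("motif_tally_%s.tsv", fam)))
      leaf_states <- stats::setNames(sel$class_label, sel$species)
      pars <- parsimony_states(tree, leaf_states)
      write_tsv(pars$transitions,
                file.path(config$outdir, sprintf("transitions_%s.tsv", fam)))
      n_trans <- n_trans + nrow(pars$transitions)
    }
    summary$stages$motifs <<- list(status = "ok",
                                   n_assignments = nrow(assignments),
                                   n_transitions = n_trans)
    TRUE
  })
  if (!is.null(summary$failed_stage)) return(finish())

  run_stage("structure", function() {
    st <- config$structures
    if (is.null(st)) {
      summary$stages$structure <<- list(status = "skipped",
                                        note = "no structures supplied")
      return(TRUE)
    }
    out <- list(status = "ok")
    if (!is.null(st$model_a) && !is.null(st$model_b)) {
      sup <- superpose_models(read_structure(st$model_a),
                              read_structure(st$model_b),
                              plddt_threshold = config$plddt_threshold,
                              rmsd_threshold = config$rmsd_threshold)
      write_json_stable(list(rotation = sup$rotation,
                             translation = sup$translation,
                             rmsd = sup$rmsd, n_atoms = sup$n_atoms,
                             similar = sup$similar),
                        file.path(config$outdir, "superposition.json"))
      out$rmsd <- sup$rmsd
      out$similar <- sup$similar
    }
    if (!is.null(st$interface)) {
      rep <- check_interface(st$interface$ref_records,
                             st$interface$query_records,
                             st$interface$map %||% default_interface_map())
      write_tsv(rep$entries, file.path(config$outdir, "interface.tsv"))
      out$interface_conserved <- rep$conserved_count
      out$interface_total <- rep$denominator
    }
    summary$stages$structure <<- out
    TRUE
  })
  finish()
}
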