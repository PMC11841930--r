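# Confidence-filtered rigid superposition and interface-residue checks.
#
# Predicted models carry per-residue pLDDT in the B-factor column; residues
# below 50 are low confidence and are excluded before any comparison.
# Superposition is least-squares optimal (Kabsch, via SVD) over paired CA
# atoms, with the determinant sign corrected so only proper rotations are
# returned; structural similarity is declared when RMSD falls below 1 A.

#' Drop low-confidence residues from a structure model
#'
#' @param model A \code{structure_model} from [read_structure()].
#' @param threshold pLDDT cutoff (default 50); residues with
#'   \code{plddt < threshold} are removed. When nothing survives the model
#'   is flagged \code{excluded_entirely}.
#' @return The filtered \code{structure_model}. Idempotent.
#' @export
filter_plddt <- function(model, threshold = 50) {
  stopifnot(inherits(model, "structure_model"))
  keep <- model$residues$plddt >= threshold
  res <- model$residues[keep, , drop = FALSE]
  key_res <- paste(model$residues$chain, model$residues$resno)[keep]
  key_atoms <- paste(model$atoms$chain, model$atoms$resno)
  atoms <- model$atoms[key_atoms %in% key_res, , drop = FALSE]
  structure(list(atoms = atoms, residues = res, source = model$source,
                 excluded_entirely = nrow(res) == 0L),
            class = "structure_model")
}

#' Optimal rigid superposition of paired coordinates
#'
#' Kabsch algorithm: centers both sets, takes the SVD of the covariance, and
#' corrects the determinant sign so the result is a proper rotation (no
#' reflection). The returned transform maps B onto A:
#' \code{B \%*\% rotation + translation}.
#'
#' @param coordsA,coordsB Numeric n x 3 matrices of paired coordinates
#'   (n >= 3).
#' @param threshold RMSD (in Angstrom) below which the pair is called
#'   structurally similar (default 1.0).
#' @param allow_degenerate Permit n < 3 (degenerate point systems with
#'   rank-deficient covariance; the RMSD is still the least-squares optimum,
#'   e.g. |d1 - d2| / 2 for two 2-point segments of lengths d1, d2). Off by
#'   default: real superpositions with fewer than 3 pairs are an error.
#' @return An object of class \code{superposition}: \code{rotation} (3 x 3,
#'   det +1), \code{translation}, \code{rmsd}, \code{n_atoms},
#'   \code{similar}.
#' @export
kabsch <- function(coordsA, coordsB, threshold = 1.0,
                   allow_degenerate = FALSE) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (ncol(coordsA) != 3L || ncol(coordsB) != 3L) stop("coordinates must be n x 3")
  if (nrow(coordsA) != nrow(coordsB)) {
    stop(sprintf("mismatched atom counts: %d vs %d", nrow(coordsA), nrow(coordsB)))
  }
  n <- nrow(coordsA)
  if (n < 3L && !allow_degenerate) stop("need at least 3 atom pairs")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A0 <- sweep(coordsA, 2, ca); B0 <- sweep(coordsB, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  B0r <- B0 %*% R
  rmsd <- sqrt(mean(rowSums((A0 - B0r)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% R),
                 rmsd = rmsd, n_atoms = n,
                 similar = rmsd < threshold, threshold = threshold),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d CA pairs, RMSD %.3f A (%s at %.1f A)\n",
              x$n_atoms, x$rmsd,
              if (x$similar) "similar" else "not similar", x$threshold))
  invisible(x)
}

# One-letter sequence of a model's CA trace.
model_sequence <- function(model) {
  aa <- model$residues$aa
  aa[is.na(aa) | !(aa %in% AA_ALPHABET)] <- "X"
  paste(aa, collapse = "")
}

#' Superpose two structure models via their sequence alignment
#'
#' Both models are pLDDT-filtered, their CA sequences aligned globally, and
#' the Kabsch superposition computed over one-to-one aligned (gap-free)
#' residue pairs.
#'
#' @param modelA,modelB \code{structure_model}s.
#' @param plddt_threshold pLDDT cutoff applied to both (default 50).
#' @param rmsd_threshold Similarity call threshold in Angstrom (default 1.0).
#' @return A \code{superposition} with an extra \code{pairs} data.frame of
#'   the residue numbers used.
#' @export
superpose_models <- function(modelA, modelB, plddt_threshold = 50,
                             rmsd_threshold = 1.0) {
  fa <- filter_plddt(modelA, plddt_threshold)
  fb <- filter_plddt(modelB, plddt_threshold)
  if (fa$excluded_entirely || fb$excluded_entirely) {
    stop("model excluded entirely at this pLDDT threshold")
  }
  aln <- global_align(list(id = "A", sequence = model_sequence(fa)),
                      list(id = "B", sequence = model_sequence(fb)))
  cm <- aln$column_map
  paired <- cm[!is.na(cm$ref_pos) & !is.na(cm$query_pos), , drop = FALSE]
  coordsA <- as.matrix(fa$residues[paired$ref_pos, c("x", "y", "z")])
  coordsB <- as.matrix(fb$residues[paired$query_pos, c("x", "y", "z")])
  sup <- kabsch(coordsA, coordsB, threshold = rmsd_threshold)
  sup$pairs <- data.frame(resno_a = fa$residues$resno[paired$ref_pos],
                          resno_b = fb$residues$resno[paired$query_pos])
  sup
}

#' The reference STAT2-IRF9 interface map
#'
#' The five contact residues of the STAT2 coiled-coil / IRF9 IAD interface
#' seen in the solved mouse complex: STAT2 F174 against an IRF9 groove
#' formed by L274, A276, F283 and Q285.
#'
#' @param stat2_ref_id,irf9_ref_id Ids of the reference records the
#'   positions refer to.
#' @return Data.frame with columns \code{role}, \code{ref_id},
#'   \code{ref_position}, \code{expected_residue}.
#' @export
default_interface_map <- function(stat2_ref_id = "STAT2_ref",
                                  irf9_ref_id = "IRF9_ref") {
  data.frame(
    role = c("STAT2", "IRF9", "IRF9", "IRF9", "IRF9"),
    ref_id = c(stat2_ref_id, rep(irf9_ref_id, 4)),
    ref_position = c(174L, 274L, 276L, 283L, 285L),
    expected_residue = c("F", "L", "A", "F", "Q"),
    stringsAsFactors = FALSE)
}

#' Check conservation of interface residues in a query protein pair
#'
#' Each interface position is lifted from its reference onto the query of
#' the same role through a global alignment (as a width-1 region) and the
#' observed residue compared with the expected one. \code{X} matches
#' nothing. Positions lost to deletions are reported as not liftable and,
#' by default, count as not conserved.
#'
#' @param ref_records Named list, role -> reference protein record.
#' @param query_records Named list, role -> query protein record.
#' @param map Interface map data.frame (see [default_interface_map()]).
#' @param unliftable_counts Logical; keep unliftable entries in the
#'   conserved-count denominator (default TRUE).
#' @return A list of class \code{interface_report}: \code{entries}
#'   (data.frame role, ref_position, expected, query_id, query_pos,
#'   observed, liftable, conserved), \code{conserved_count},
#'   \code{denominator}.
#' @export
check_interface <- function(ref_records, query_records,
                            map = default_interface_map(),
                            unliftable_counts = TRUE) {
  roles <- unique(map$role)
  missing_roles <- setdiff(roles, union(names(ref_records), character(0)))
  if (length(missing_roles) > 0L || length(setdiff(roles, names(query_records))) > 0L) {
    stop("reference and query records must be supplied for every role in the map")
  }
  alns <- lapply(stats::setNames(roles, roles), function(role) {
    global_align(ref_records[[role]], query_records[[role]])
  })
  rows <- lapply(seq_len(nrow(map)), function(i) {
    role <- map$role[i]
    aln <- alns[[role]]
    lr <- lift_region(aln, list(name = sprintf("%s_%d", role, map$ref_position[i]),
                                ref_id = aln$ref_id,
                                start = map$ref_position[i],
                                end = map$ref_position[i]))
    liftable <- lr$status == "complete"
    observed <- if (liftable) lr$subsequence else NA_character_
    conserved <- liftable && !is.na(observed) && observed != "X" &&
      observed == map$expected_residue[i]
    data.frame(role = role, ref_position = map$ref_position[i],
               expected = map$expected_residue[i],
               query_id = aln$query_id,
               query_pos = if (liftable) lr$q_start else NA_integer_,
               observed = observed, liftable = liftable,
               conserved = conserved, stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  denom <- if (unliftable_counts) nrow(entries) else sum(entries$liftable)
  structure(list(entries = entries,
                 conserved_count = sum(entries$conserved),
                 denominator = denom),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: %d/%d residues conserved\n",
              x$conserved_count, x$denominator))
  for (i in seq_len(nrow(x$entries))) {
    e <- x$entries[i, ]
    cat(sprintf("  %s %s%d -> %s : %s\n", e$role, e$expected, e$ref_position,
                if (is.na(e$observed)) "lost" else e$observed,
                if (e$conserved) "conserved" else "NOT conserved"))
  }
  invisible(x)
}

#' Replace unknown residues using companion sequences
#'
#' An \code{X} arising from an ambiguous base in the underlying gene model
#' can be replaced by the majority residue observed at the homologous
#' position in companion orthologs (mirroring the practice of repairing a
#' single ambiguous codon from close relatives before modeling). Off by
#' default in the pipeline; every replacement is recorded.
#'
#' @param record Protein record containing \code{X} residues.
#' @param companions Data.frame of companion protein records.
#' @return The record (list form) with \code{sequence} repaired and a
#'   \code{replacements} data.frame attribute (\code{position}, \code{from},
#'   \code{to}, \code{support}).
#' @export
sanitize_x <- function(record, companions) {
  rec <- as_protein_record(record)
  chars <- seq_chars(rec$sequence)
  xpos <- which(chars == "X")
  reps <- data.frame(position = integer(), from = character(),
                     to = character(), support = integer(),
                     stringsAsFactors = FALSE)
  for (p in xpos) {
    votes <- character(0)
    for (i in seq_len(nrow(companions))) {
      aln <- global_align(rec, companions[i, , drop = FALSE])
      lr <- lift_region(aln, list(name = "x", ref_id = rec$id, start = p, end = p))
      if (lr$status == "complete" && lr$subsequence != "X") {
        votes <- c(votes, lr$subsequence)
      }
    }
    if (length(votes) > 0L) {
      tab <- sort(table(votes), decreasing = TRUE)
      winner <- names(tab)[1]
      chars[p] <- winner
      reps <- rbind(reps, data.frame(position = p, from = "X", to = winner,
                                     support = as.integer(tab[1]),
                                     stringsAsFactors = FALSE))
    }
  }
  out <- list(id = rec$id, sequence = paste(chars, collapse = ""))
  attr(out, "replacements") <- reps
  out
}
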