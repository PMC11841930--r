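# Reference-anchored alignment and coordinate lifting.
#
# Each ortholog is aligned pairwise to the reference sequence with an optimal
# global (Needleman-Wunsch) alignment under BLOSUM62 and affine gaps; annotated
# reference windows are then lifted through the alignment's column map onto
# ortholog coordinates. All coordinates are 1-based inclusive on the ungapped
# sequences.

.motifshift_env <- new.env(parent = emptyenv())

# BLOSUM62 with the unknown residue X neutralized: X scores 0 against
# everything so an unknown never attracts nor repels the traceback.
scoring_matrix <- function() {
  if (is.null(.motifshift_env$blosum62x)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()), envir = environment())
    keep <- c(AA20, "X")
    mat <- mat[keep, keep]
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .motifshift_env$blosum62x <- mat
  }
  .motifshift_env$blosum62x
}

#' Optimal global pairwise alignment to a reference
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (a gap of length k costs \code{gap_open + k * gap_extend}); terminal gaps
#' are penalized. \code{X} scores 0 against every residue.
#'
#' @param ref,query Protein records (data.frame row, list with \code{id} and
#'   \code{sequence}, or a bare sequence string).
#' @param gap_open,gap_extend Affine gap parameters (defaults 10 and 1).
#' @return An object of class \code{pairwise_alignment}: \code{ref_id},
#'   \code{query_id}, \code{aligned_ref}, \code{aligned_query}, \code{score},
#'   and \code{column_map}, a data.frame with one row per alignment column
#'   giving \code{ref_pos} and \code{query_pos} (NA at gaps).
#' @export
global_align <- function(ref, query, gap_open = 10, gap_extend = 1) {
  ref <- as_protein_record(ref, id = "ref")
  query <- as_protein_record(query, id = "query")
  if (nchar(ref$sequence) == 0L) stop("empty reference sequence")
  if (nchar(query$sequence) == 0L) stop("empty query sequence")
  check_sequence_alphabet(ref$sequence, id = ref$id)
  check_sequence_alphabet(query$sequence, id = query$id)

  pwa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref$sequence),
    subject = Biostrings::AAString(query$sequence),
    substitutionMatrix = scoring_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  aligned_ref <- as.character(Biostrings::alignedPattern(pwa))
  aligned_query <- as.character(Biostrings::alignedSubject(pwa))

  rc <- seq_chars(aligned_ref)
  qc <- seq_chars(aligned_query)
  stopifnot(length(rc) == length(qc))
  if (any(rc == "-" & qc == "-")) stop("alignment column gapped in both rows")
  column_map <- data.frame(
    column = seq_along(rc),
    ref_pos = ifelse(rc == "-", NA_integer_, cumsum(rc != "-")),
    query_pos = ifelse(qc == "-", NA_integer_, cumsum(qc != "-")))

  structure(list(ref_id = ref$id, query_id = query$id,
                 aligned_ref = aligned_ref, aligned_query = aligned_query,
                 score = Biostrings::score(pwa), column_map = column_map),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %s vs %s, score %.1f, %d columns\n",
              x$ref_id, x$query_id, x$score, nrow(x$column_map)))
  invisible(x)
}

#' Define a reference region annotation
#'
#' @param name Region name (e.g. \code{"NES"}, \code{"SRR"},
#'   \code{"signature"}).
#' @param ref_id Id of the reference sequence the coordinates refer to.
#' @param start,end 1-based inclusive positions on the ungapped reference.
#' @return A list of class \code{region_annotation}.
#' @export
region_annotation <- function(name, ref_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("require 1 <= start <= end")
  }
  structure(list(name = name, ref_id = ref_id, start = start, end = end),
            class = "region_annotation")
}

#' Lift a reference region onto an aligned ortholog
#'
#' Maps a reference-coordinate window through a pairwise alignment onto the
#' query. The lifted start is the query position of the first window column
#' where the query is not gapped, and symmetrically from the right for the
#' end. Status is \code{complete} when every reference position in the window
#' aligns to a query residue, \code{partial} when some align to gaps, and
#' \code{missing} when all do.
#'
#' @param aln A \code{pairwise_alignment} from [global_align()].
#' @param region A \code{region_annotation} (or equivalent list).
#' @return An object of class \code{lifted_region}: \code{query_id},
#'   \code{name}, \code{q_start}, \code{q_end} (NA when missing),
#'   \code{status}, \code{subsequence}.
#' @export
lift_region <- function(aln, region) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (!is.null(region$ref_id) && !identical(region$ref_id, aln$ref_id)) {
    stop(sprintf("region is annotated on '%s' but alignment reference is '%s'",
                 region$ref_id, aln$ref_id))
  }
  cm <- aln$column_map
  ref_len <- max(cm$ref_pos, na.rm = TRUE)
  if (region$end > ref_len) {
    stop(sprintf("region %s (%d-%d) exceeds reference length %d",
                 region$name, region$start, region$end, ref_len))
  }
  win <- cm[!is.na(cm$ref_pos) & cm$ref_pos >= region$start &
              cm$ref_pos <= region$end, , drop = FALSE]
  aligned_pos <- win$query_pos[!is.na(win$query_pos)]
  if (length(aligned_pos) == 0L) {
    return(structure(list(query_id = aln$query_id, name = region$name,
                          q_start = NA_integer_, q_end = NA_integer_,
                          status = "missing", subsequence = ""),
                     class = "lifted_region"))
  }
  q_start <- min(aligned_pos)
  q_end <- max(aligned_pos)
  status <- if (anyNA(win$query_pos)) "partial" else "complete"
  query_seq <- gsub("-", "", aln$aligned_query, fixed = TRUE)
  structure(list(query_id = aln$query_id, name = region$name,
                 q_start = q_start, q_end = q_end, status = status,
                 subsequence = substr(query_seq, q_start, q_end)),
            class = "lifted_region")
}

#' @export
print.lifted_region <- function(x, ...) {
  cat(sprintf("lifted_region %s on %s: %s", x$name, x$query_id, x$status))
  if (x$status != "missing") {
    cat(sprintf(" [%d-%d] %s", x$q_start, x$q_end, x$subsequence))
  }
  cat("\n")
  invisible(x)
}

#' Lift a set of regions across a set of ortholog records
#'
#' Convenience wrapper: aligns every query to the reference once and lifts
#' every region, returning a tidy table.
#'
#' @param ref Reference protein record.
#' @param queries Data.frame of protein records (one per row).
#' @param regions List of \code{region_annotation}s.
#' @return A data.frame with columns \code{query_id}, \code{name},
#'   \code{q_start}, \code{q_end}, \code{status}, \code{subsequence}.
#' @export
lift_regions_all <- function(ref, queries, regions) {
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    aln <- global_align(ref, queries[i, , drop = FALSE])
    for (region in regions) {
      lr <- lift_region(aln, region)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = lr$query_id, name = lr$name,
        q_start = lr$q_start, q_end = lr$q_end,
        status = lr$status, subsequence = lr$subsequence,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
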