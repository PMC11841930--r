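#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header; the
#' remainder is kept as a description. Sequences are uppercased and a single
#' terminal stop character (\code{*}) is stripped. Only the 20 standard
#' residues plus \code{X} are accepted; gaps are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns \code{id}, \code{sequence},
#'   \code{description}, one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("cannot parse FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop(sprintf("empty sequence for id '%s'", ids[i]))
    check_sequence_alphabet(seqs[i], id = sprintf("record '%s'", ids[i]))
  }
  data.frame(id = ids, sequence = unname(seqs), description = desc,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data.frame with columns \code{id}, \code{sequence} and
#'   optionally \code{description}.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  if (!is.null(records$description)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read per-sequence metadata
#'
#' Expects a tab-delimited file with header row and columns \code{seq_id},
#' \code{species}, \code{taxon_group}, \code{subfamily}, \code{accession}.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the five columns above.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  md <- read_tsv(path)
  required <- c("seq_id", "species", "taxon_group", "subfamily", "accession")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0L) {
    stop(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  }
  md[required]
}

#' Join sequence records with their metadata
#'
#' Joins on \code{id == seq_id}. Any record without metadata or metadata row
#' without a record is an error, so mislabeled ortholog sets fail fast.
#'
#' @param records Data.frame from [read_fasta()].
#' @param metadata Data.frame from [read_metadata()].
#' @return The records data.frame with \code{species}, \code{taxon_group},
#'   \code{subfamily}, \code{accession} columns added.
#' @export
join_metadata <- function(records, metadata) {
  unmatched_rec <- setdiff(records$id, metadata$seq_id)
  if (length(unmatched_rec) > 0L) {
    stop(sprintf("records without metadata: %s", paste(unmatched_rec, collapse = ", ")))
  }
  unmatched_md <- setdiff(metadata$seq_id, records$id)
  if (length(unmatched_md) > 0L) {
    stop(sprintf("metadata rows without records: %s", paste(unmatched_md, collapse = ", ")))
  }
  idx <- match(records$id, metadata$seq_id)
  cbind(records,
        metadata[idx, c("species", "taxon_group", "subfamily", "accession")],
        row.names = NULL)
}

#' Read a taxonomy tree from newick
#'
#' The tree may be multifurcating; internal nodes may carry clade labels.
#' Leaf labels must be unique.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("cannot parse newick file: %s", path))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate leaf label(s): %s", paste(dup, collapse = ", ")))
  }
  tree
}

# Validate the fixed-column numeric fields of ATOM/HETATM records so parse
# failures carry a line number; bio3d does the actual parsing.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop(sprintf("malformed ATOM record at line %d: too short", i))
    }
    fields <- c(resno = substr(ln, 23, 26), x = substr(ln, 31, 38),
                y = substr(ln, 39, 46), z = substr(ln, 47, 54))
    if (nchar(ln) >= 66L) fields["b"] <- substr(ln, 61, 66)
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("malformed ATOM record at line %d: non-numeric %s field",
                   i, names(fields)[which(is.na(vals))[1]]))
    }
  }
  invisible(length(atom_idx))
}

#' Read a predicted structure model from PDB
#'
#' Per-residue confidence (pLDDT) is taken from the B-factor column of each
#' residue's CA atom, the convention used by structure predictors.
#'
#' @param path Path to a PDB coordinate file.
#' @return An object of class \code{structure_model}: a list with
#'   \code{atoms} (all ATOM records) and \code{residues} (one row per CA atom:
#'   \code{chain}, \code{resno}, \code{resid}, \code{aa} one-letter code,
#'   \code{x}, \code{y}, \code{z}, \code{plddt}).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  n_atoms <- validate_pdb_lines(path)
  if (n_atoms == 0L) stop(sprintf("no ATOM records in %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L) stop(sprintf("no CA atoms in %s", path))
  for (ch in unique(ca$chain)) {
    resno <- ca$resno[ca$chain %in% ch]
    if (any(diff(resno) <= 0)) {
      stop(sprintf("CA residue numbers not strictly increasing in chain %s", ch))
    }
  }
  plddt <- ca$b
  if (any(plddt < 0 | plddt > 100)) {
    stop("B-factor (pLDDT) values outside [0, 100]")
  }
  residues <- data.frame(chain = ca$chain, resno = ca$resno, resid = ca$resid,
                         aa = suppressWarnings(bio3d::aa321(ca$resid)),
                         x = ca$x, y = ca$y, z = ca$z, plddt = plddt,
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues, source = path,
                 excluded_entirely = FALSE),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d residues (CA), %d atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  cat(sprintf("  pLDDT range: %.1f-%.1f%s\n",
              min(x$residues$plddt), max(x$residues$plddt),
              if (isTRUE(x$excluded_entirely)) " [excluded entirely]" else ""))
  invisible(x)
}
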