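# Reading FASTA, extracting cysteine-centred motifs, and motif-table I/O.

#' Read a FASTA file of protein sequences
#'
#' Identifiers are taken from the header line up to the first
#' whitespace. Sequences are uppercased and residues outside the
#' 20-letter amino-acid alphabet (e.g. selenocysteine `U`, ambiguity
#' codes `B`/`Z`/`J`, pyrrolysine `O`, stops `*`) are replaced by the
#' gap-filling residue `X` with a warning.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A named character vector of protein sequences; names are the
#'   protein identifiers.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 description", "ACDEF", ">P2", "mkcll"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty FASTA record(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  odd <- unique(unlist(strsplit(seqs, "")))
  odd <- setdiff(odd, ALPHABET21)
  if (length(odd) > 0) {
    warning("non-standard residue(s) ", paste(odd, collapse = ", "),
            " replaced by 'X'")
    seqs <- chartr(paste(odd, collapse = ""),
                   strrep("X", length(odd)), seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Construct a motif dataset
#'
#' A motif is a fixed-length sequence window centred on a cysteine. All
#' windows in a dataset share the same odd width (21 by default:
#' a central Cys flanked by 10 residues each side); protein termini are
#' padded with `X`.
#'
#' @param protein_id Character vector of protein identifiers.
#' @param position Integer vector, 1-based position of the central Cys
#'   in the full protein.
#' @param sequence Character vector of motif windows.
#' @param label Character vector in `positive`, `negative`, `unknown`.
#' @return A `data.frame` of class `motif_dataset` with columns
#'   `protein_id`, `position`, `sequence`, `label`.
#' @export
motif_dataset <- function(protein_id, position, sequence,
                          label = "unknown") {
  df <- data.frame(protein_id = as.character(protein_id),
                   position = as.integer(position),
                   sequence = as.character(sequence),
                   label = rep_len(as.character(label), length(sequence)),
                   stringsAsFactors = FALSE)
  validate_motifs(df)
  class(df) <- c("motif_dataset", "data.frame")
  df
}

# Enforce the motif invariants; `where` prefixes error messages with a
# row locator (e.g. file row numbers when loading a table).
validate_motifs <- function(df, where = function(i) paste0("motif ", i)) {
  if (nrow(df) == 0) return(invisible(df))
  widths <- nchar(df$sequence)
  w <- widths[1]
  if (w %% 2 == 0 || any(widths != w)) {
    bad <- which(widths != w | w %% 2 == 0)[1]
    stop(where(bad), ": motif must have a single odd width (got ",
         widths[bad], ", expected ", w, ")")
  }
  centre <- substr(df$sequence, (w + 1) / 2, (w + 1) / 2)
  if (any(centre != "C")) {
    bad <- which(centre != "C")[1]
    stop(where(bad), ": central residue must be 'C', got '", centre[bad], "'")
  }
  chars <- unique(unlist(strsplit(df$sequence, "")))
  bad_chars <- setdiff(chars, ALPHABET21)
  if (length(bad_chars) > 0) {
    bad <- which(!vapply(strsplit(df$sequence, ""),
                         function(x) all(x %in% ALPHABET21), TRUE))[1]
    stop(where(bad), ": residue(s) outside the 21-letter alphabet: ",
         paste(bad_chars, collapse = ", "))
  }
  bad_lab <- which(!df$label %in% c("positive", "negative", "unknown"))
  if (length(bad_lab) > 0)
    stop(where(bad_lab[1]), ": invalid label '", df$label[bad_lab[1]], "'")
  key <- paste(df$protein_id, df$position)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(where(bad), ": duplicate protein_id/position pair ",
         df$protein_id[bad], "/", df$position[bad])
  }
  invisible(df)
}

#' @export
print.motif_dataset <- function(x, ...) {
  cat("motif_dataset:", nrow(x), "motifs, width",
      if (nrow(x) > 0) nchar(x$sequence[1]) else NA, "\n")
  print(table(x$label))
  invisible(x)
}

# Sample identifiers used as feature-matrix row names.
motif_ids <- function(dataset) paste(dataset$protein_id, dataset$position,
                                     sep = "@")

#' Extract cysteine-centred motifs from a protein sequence
#'
#' Produces one window per cysteine, of length `2 * flank + 1`.
#' Cysteines within `flank` residues of a terminus get `X` padding so
#' every cysteine in the protein is predictable.
#'
#' @param protein_id Protein identifier recorded in the output.
#' @param sequence Protein sequence (characters in the 20-letter
#'   alphabet or `X`).
#' @param flank Number of residues on each side of the cysteine
#'   (default 10, i.e. 21-residue windows).
#' @return A [motif_dataset()] with one row per cysteine and label
#'   `unknown`; zero rows if the sequence has no cysteine.
#' @examples
#' extract_cys_motifs("P1", "MKCLLAVCDE")
#' @export
extract_cys_motifs <- function(protein_id, sequence, flank = 10) {
  stopifnot(length(sequence) == 1, flank >= 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  pos <- which(chars == "C")
  if (length(pos) == 0) {
    return(motif_dataset(character(0), integer(0), character(0),
                         character(0)))
  }
  padded <- c(rep("X", flank), chars, rep("X", flank))
  windows <- vapply(pos, function(p) {
    paste(padded[p:(p + 2 * flank)], collapse = "")
  }, character(1))
  motif_dataset(protein_id, pos, windows, "unknown")
}

#' Load / write a labelled motif table
#'
#' The on-disk format is a TSV with header
#' `protein_id<TAB>position<TAB>sequence<TAB>label`. Motif invariants
#' (odd width, central `C`, 21-letter alphabet, unique
#' protein/position) are enforced on load and violations are reported
#' with their file row number.
#'
#' @param path Path of the TSV file.
#' @return `load_motif_table()` returns a [motif_dataset()];
#'   `write_motif_table()` returns `path` invisibly.
#' @export
load_motif_table <- function(path) {
  if (!file.exists(path)) stop("motif table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "position", "sequence", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("motif table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[need]
  df$position <- as.integer(df$position)
  # +1 for the header line
  validate_motifs(df, where = function(i) paste0(path, " row ", i + 1))
  class(df) <- c("motif_dataset", "data.frame")
  df
}

#' @param dataset A [motif_dataset()].
#' @rdname load_motif_table
#' @export
write_motif_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "motif_dataset"))
  write.table(as.data.frame(dataset)[c("protein_id", "position",
                                       "sequence", "label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
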