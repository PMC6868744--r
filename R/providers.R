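# Structural annotation providers: parsers for the output of external
# predictors (PSI-BLAST ASCII PSSM, DISOPRED .diso, PSIPRED .ss2,
# NetSurfP-1.1 tabular) and a deterministic mock provider for testing.
#
# An annotation store is a named list (protein_id -> record) where each
# record holds per-residue tracks:
#   disorder  numeric[L] in [0,1]
#   ss        data.frame(class in {C,E,H}, pC, pE, pH)
#   acc       matrix[L x 7]: buried/exposed flag, relative ASA,
#             absolute ASA, Z-fit, p(helix), p(strand), p(coil)
#   pssm      matrix[L x 21]: 20 log-odds (PSI-BLAST residue order) +
#             per-position information content

PSSM_RESIDUE_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
ACC_SCORE_NAMES <- c("exposed", "rsa", "asa", "zfit", "pA", "pB", "pC")

#' Build an annotation store
#'
#' @param records Named list of per-protein annotation records (see
#'   [mock_annotations()] for the record layout). Names are protein
#'   identifiers.
#' @return The records, classed as `annotation_store`.
#' @export
annotation_store <- function(records) {
  stopifnot(is.list(records),
            !is.null(names(records)), !anyDuplicated(names(records)))
  structure(records, class = "annotation_store")
}

get_annotation <- function(store, protein_id, track = NULL) {
  rec <- store[[protein_id]]
  if (is.null(rec))
    stop("no structural annotation for protein ", protein_id)
  if (is.null(track)) return(rec)
  val <- rec[[track]]
  if (is.null(val))
    stop("annotation track '", track, "' missing for protein ", protein_id)
  val
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` checkpoint format of PSI-BLAST 2.2.26:
#' header and footer lines are ignored; each residue row carries the
#' position, the residue letter, 20 log-odds integers, 20 weighted
#' percentages, the per-position information content and the relative
#' weight. The 20 log-odds and the information content are kept.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional protein sequence; when given, the residue
#'   column is checked against it.
#' @return Numeric matrix with one row per residue and 21 columns (20
#'   log-odds in PSI-BLAST residue order, then `info`).
#' @export
parse_psiblast_pssm <- function(path, sequence = NULL) {
  lines <- readLines(path)
  data_re <- "^\\s*[0-9]+\\s+[A-Z]\\s+-?[0-9]"
  rows <- grep(data_re, lines, value = TRUE)
  if (length(rows) == 0)
    stop("no PSSM rows found in ", path,
         " (expected PSI-BLAST 2.2.x -out_ascii_pssm dialect)")
  parsed <- lapply(rows, function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  nf <- lengths(parsed)
  if (any(nf < 22))
    stop("truncated PSSM row in ", path, " (", min(nf) - 2,
         " score columns; expected at least 20)")
  pos <- as.integer(vapply(parsed, `[`, "", 1))
  res <- vapply(parsed, `[`, "", 2)
  if (!identical(pos, seq_along(pos)))
    stop("non-contiguous residue positions in ", path)
  scores <- t(vapply(parsed, function(x) as.numeric(x[3:22]), numeric(20)))
  info <- vapply(parsed, function(x) {
    if (length(x) >= 43) as.numeric(x[43]) else 0
  }, numeric(1))
  if (!is.null(sequence)) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    if (length(chars) != length(pos))
      stop("PSSM has ", length(pos), " rows but sequence has ",
           length(chars), " residues (", path, ")")
    mism <- which(res != chars & chars != "X")
    if (length(mism) > 0)
      stop("PSSM residue mismatch at position ", mism[1], " in ", path,
           ": '", res[mism[1]], "' vs sequence '", chars[mism[1]], "'")
  }
  out <- cbind(scores, info)
  colnames(out) <- c(PSSM_RESIDUE_ORDER, "info")
  rownames(out) <- NULL
  out
}

#' Parse a DISOPRED3 `.diso` file
#'
#' Data lines carry position, residue, state (`*` disordered / `.`
#' ordered; ignored) and the disorder score. Comment lines starting
#' with `#` are skipped.
#'
#' @param path Path to the `.diso` file.
#' @param sequence Optional sequence for a residue-count check.
#' @return Numeric vector of per-residue disorder scores in `[0, 1]`.
#' @export
parse_disopred <- function(path, sequence = NULL) {
  lines <- readLines(path)
  keep <- grep("^\\s*[0-9]+\\s+\\S", lines)
  if (length(keep) == 0)
    stop("no residue rows found in ", path, " (expected DISOPRED3 .diso)")
  scores <- vapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 4)
      stop("line ", i, " of ", path, ": expected 4 columns, got ", length(f))
    s <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s)) stop("line ", i, " of ", path, ": non-numeric score '",
                       f[4], "'")
    if (s < 0 || s > 1)
      stop("line ", i, " of ", path, ": disorder score ", s,
           " outside [0, 1]")
    s
  }, numeric(1))
  check_residue_count(length(scores), sequence, path)
  scores
}

#' Parse a PSIPRED `.ss2` file
#'
#' The VFORMAT layout: a header comment, then one line per residue with
#' position, residue, predicted class (`C` coil, `E` strand, `H`
#' helix) and the three class probabilities in file order coil, helix,
#' strand.
#'
#' @param path Path to the `.ss2` file.
#' @param sequence Optional sequence for a residue-count check.
#' @return `data.frame` with columns `class`, `pC`, `pE`, `pH`.
#' @export
parse_psipred_ss2 <- function(path, sequence = NULL) {
  lines <- readLines(path)
  keep <- grep("^\\s*[0-9]+\\s+[A-Z]\\s+[A-Z]", lines)
  if (length(keep) == 0)
    stop("no residue rows found in ", path, " (expected PSIPRED 3.x .ss2)")
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6)
      stop("line ", i, " of ", path, ": expected 6 columns, got ", length(f))
    if (!f[3] %in% c("C", "E", "H"))
      stop("line ", i, " of ", path, ": unknown secondary-structure class '",
           f[3], "'")
    p <- as.numeric(f[4:6]) # file order: coil, helix, strand
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
      stop("line ", i, " of ", path, ": probabilities outside [0, 1]")
    list(class = f[3], pC = p[1], pE = p[3], pH = p[2])
  })
  out <- data.frame(class = vapply(rows, `[[`, "", "class"),
                    pC = vapply(rows, `[[`, 0, "pC"),
                    pE = vapply(rows, `[[`, 0, "pE"),
                    pH = vapply(rows, `[[`, 0, "pH"),
                    stringsAsFactors = FALSE)
  check_residue_count(nrow(out), sequence, path)
  out
}

#' Parse a NetSurfP-1.1 output file
#'
#' Tabular NetSurfP-1.1 rows: class assignment (`B` buried / `E`
#' exposed), amino acid, chain id, residue number, relative surface
#' accessibility, absolute surface accessibility, Z-fit score and the
#' three secondary-structure probabilities (helix, strand, coil).
#' Blank and comment lines are tolerated.
#'
#' @param path Path to the NetSurfP output.
#' @param sequence Optional sequence for a residue-count check.
#' @return Numeric matrix with one row per residue and 7 columns:
#'   exposed flag (`B` -> 0, `E` -> 1), relative ASA, absolute ASA,
#'   Z-fit, p(helix), p(strand), p(coil). Values are raw; min-max
#'   normalization happens in the encoder.
#' @export
parse_netsurfp <- function(path, sequence = NULL) {
  lines <- readLines(path)
  keep <- grep("^\\s*[BE]\\s+[A-Z]", lines)
  if (length(keep) == 0)
    stop("no residue rows found in ", path, " (expected NetSurfP-1.1 output)")
  out <- t(vapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 10)
      stop("line ", i, " of ", path, ": expected 10 columns, got ",
           length(f))
    c(if (f[1] == "E") 1 else 0, as.numeric(f[5:10]))
  }, numeric(7)))
  colnames(out) <- ACC_SCORE_NAMES
  rownames(out) <- NULL
  check_residue_count(nrow(out), sequence, path)
  out
}

check_residue_count <- function(n, sequence, path) {
  if (!is.null(sequence) && n != nchar(sequence))
    stop(path, ": ", n, " residue rows but the sequence has ",
         nchar(sequence), " residues")
  invisible(n)
}

#' Read an annotation directory
#'
#' Expects the layout `<dir>/<protein_id>.{pssm,diso,ss2,nsp}`. Files
#' that are absent leave the corresponding track `NULL`; encoders that
#' need the track will then raise an error naming the protein.
#'
#' @param dir Directory of per-protein predictor outputs.
#' @param sequences Named character vector of protein sequences (names
#'   are protein identifiers); used for residue-count checks.
#' @return An [annotation_store()].
#' @export
read_annotation_dir <- function(dir, sequences) {
  stopifnot(dir.exists(dir), !is.null(names(sequences)))
  records <- lapply(names(sequences), function(id) {
    seq <- sequences[[id]]
    rd <- function(ext, fun) {
      f <- file.path(dir, paste0(id, ".", ext))
      if (file.exists(f)) fun(f, seq) else NULL
    }
    list(protein_id = id, length = nchar(seq),
         disorder = rd("diso", parse_disopred),
         ss = rd("ss2", parse_psipred_ss2),
         acc = rd("nsp", parse_netsurfp),
         pssm = rd("pssm", parse_psiblast_pssm))
  })
  names(records) <- names(sequences)
  annotation_store(records)
}

# Derive one integer hash per string (in [0, 2^31-1)), then mix a
# channel index in numerically. All products stay below 2^53 so the
# arithmetic is exact in doubles on every platform.
hash_int <- function(strings) {
  M <- 2147483647
  vapply(strings, function(s) {
    h <- 113
    for (code in utf8ToInt(s)) h <- (h * 131 + code) %% M
    h
  }, numeric(1), USE.NAMES = FALSE)
}

hash_channel <- function(h0, k) {
  M <- 2147483647
  h <- ((h0 + k * 7919) %% M * 16807) %% M
  ((h * 48271) %% M) / M
}

#' Deterministic mock structural annotations
#'
#' Generates pseudo disorder, secondary-structure, surface-accessibility
#' and PSSM tracks from a seeded hash of `(protein_id, position)`. The
#' output is identical across runs and platforms (integer hashing, not
#' floating-point RNG), which makes the full pipeline runnable and
#' testable without any external structure predictor. The scores carry
#' no biological signal.
#'
#' @param sequences Named character vector of protein sequences.
#' @param seed Integer seed mixed into every hash.
#' @return An [annotation_store()].
#' @examples
#' st <- mock_annotations(c(P1 = "MKCLLAV"), seed = 7)
#' st[["P1"]]$disorder
#' @export
mock_annotations <- function(sequences, seed = 1) {
  stopifnot(!is.null(names(sequences)))
  records <- lapply(names(sequences), function(id) {
    L <- nchar(sequences[[id]])
    h0 <- hash_int(paste(id, seq_len(L), seed, sep = "|"))
    u <- function(k) hash_channel(h0, k)
    p3 <- cbind(u(2), u(3), u(4))
    p3 <- p3 / rowSums(p3)
    cls <- c("C", "E", "H")[max.col(p3, ties.method = "first")]
    acc <- cbind(round(u(5)), u(6), u(7) * 150, (u(8) - 0.5) * 6,
                 p3[, 3], p3[, 2], p3[, 1])
    colnames(acc) <- ACC_SCORE_NAMES
    pssm <- matrix(0, L, 21,
                   dimnames = list(NULL, c(PSSM_RESIDUE_ORDER, "info")))
    for (j in 1:20) pssm[, j] <- round(u(8 + j) * 13) - 6
    pssm[, 21] <- u(30) * 2
    list(protein_id = id, length = L,
         disorder = u(1), ss = data.frame(class = cls, pC = p3[, 1],
                                          pE = p3[, 2], pH = p3[, 3],
                                          stringsAsFactors = FALSE),
         acc = acc, pssm = pssm)
  })
  names(records) <- names(sequences)
  annotation_store(records)
}
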