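# The nine motif feature encoders and their assembly into one matrix.
#
# All encoders are pure functions of (motif, annotation, config):
# repeated calls give identical output. Sequence encoders accept a
# character vector of motif windows or a motif_dataset; structural
# encoders additionally need an annotation store.

CLUSTER_NAMES <- c("AAC", "CKSAAP", "BLOSUM62", "PSSM", "AAindex",
                   "BINARY", "DISOPRED", "PSIPRED", "ACC")
SEQUENCE_CLUSTERS <- c("AAC", "CKSAAP", "BLOSUM62", "AAindex", "BINARY")

#' Encoder configuration
#'
#' @param k_max Largest residue spacing for the k-spaced amino-acid
#'   pair encoding (default 5, i.e. spacings 0..5 and 2400 features).
#' @param pssm_width Scores kept per PSSM row: 21 keeps the 20 log-odds
#'   plus the per-position information content (441 features for a
#'   21-mer); 20 keeps the log-odds only (420 features).
#' @param pssm_drop_terminal If `TRUE`, the last motif position is
#'   dropped from the PSSM block; together with `pssm_width = 20` this
#'   yields a 400-feature PSSM block and a 5297-column total over all
#'   nine blocks.
#' @param aaindex_ids AAindex accessions for the physicochemical
#'   encoder (default [default_aaindex_ids()], 64 indices giving
#'   21 x 64 = 1344 features).
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(k_max = 5, pssm_width = 21,
                           pssm_drop_terminal = FALSE,
                           aaindex_ids = default_aaindex_ids()) {
  stopifnot(k_max >= 0, pssm_width %in% c(20, 21))
  structure(list(k_max = k_max, pssm_width = pssm_width,
                 pssm_drop_terminal = pssm_drop_terminal,
                 aaindex_ids = aaindex_ids),
            class = "encoder_config")
}

as_motif_seqs <- function(motifs) {
  if (inherits(motifs, "motif_dataset")) motifs$sequence
  else as.character(motifs)
}

# n x W matrix of indices into ALPHABET21 (X = 21).
motif_index_matrix <- function(seqs) {
  w <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == w))
  m <- matrix(match(unlist(strsplit(seqs, "")), ALPHABET21),
              ncol = w, byrow = TRUE)
  if (anyNA(m)) stop("motif contains residues outside the 21-letter alphabet")
  m
}

#' Amino-acid composition (AAC) encoding
#'
#' Occurrence count of each of the 20 amino acids in the window,
#' divided by the window length. Padding residues `X` contribute to no
#' dimension, so the vector sums to (W - #X) / W.
#'
#' @param motifs Motif windows (character vector or [motif_dataset()]).
#' @return Numeric matrix, one row per motif, 20 columns `AAC.A` ...
#'   `AAC.Y`.
#' @export
encode_aac <- function(motifs) {
  seqs <- as_motif_seqs(motifs)
  m <- motif_index_matrix(seqs)
  w <- ncol(m)
  out <- vapply(1:20, function(j) rowSums(m == j) / w,
                numeric(length(seqs)))
  out <- matrix(out, nrow = length(seqs),
                dimnames = list(NULL, paste0("AAC.", AA20)))
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing k = 0..`k_max` and each ordered pair (a, b) of the
#' 20 amino acids, counts occurrences of a ... b with exactly k
#' residues in between and divides by the number of k-spaced pair slots
#' in the window, W - k - 1. Pairs touching a padding `X` are excluded
#' from the numerator only.
#'
#' @inheritParams encode_aac
#' @param k_max Largest spacing (default 5; 6 x 400 = 2400 features).
#' @return Numeric matrix with `(k_max + 1) * 400` columns
#'   `CKSAAP.k0.AA`, `CKSAAP.k0.AC`, ...
#' @export
encode_cksaap <- function(motifs, k_max = 5) {
  seqs <- as_motif_seqs(motifs)
  m <- motif_index_matrix(seqs)
  n <- nrow(m); w <- ncol(m)
  if (k_max < 0 || w <= k_max + 1)
    stop("k_max = ", k_max, " too large for window width ", w)
  pair_names <- as.vector(t(outer(AA20, AA20, paste0)))
  blocks <- vector("list", k_max + 1)
  for (k in 0:k_max) {
    counts <- matrix(0, n, 400)
    for (i in seq_len(w - k - 1)) {
      a <- m[, i]; b <- m[, i + k + 1]
      ok <- a <= 20 & b <= 20
      if (any(ok)) {
        code <- (a[ok] - 1L) * 20L + b[ok]
        idx <- cbind(which(ok), code)
        # accumulate; duplicated (row, code) pairs cannot occur within
        # one slot i, so plain assignment-with-add is safe
        counts[idx] <- counts[idx] + 1
      }
    }
    colnames(counts) <- paste0("CKSAAP.k", k, ".", pair_names)
    blocks[[k + 1]] <- counts / (w - k - 1)
  }
  do.call(cbind, blocks)
}

#' One-hot (binary) motif encoding
#'
#' Each of the 21 window positions is a 21-dimensional indicator vector
#' over the alphabet A, C, D, ..., Y, X (alphabetical order of the 20
#' amino acids, then the gap-filling residue).
#'
#' @inheritParams encode_aac
#' @return 0/1 matrix with `21 * W` columns `BINARY.p01.A` ...
#' @export
encode_binary <- function(motifs) {
  seqs <- as_motif_seqs(motifs)
  m <- motif_index_matrix(seqs)
  n <- nrow(m); w <- ncol(m)
  out <- matrix(0, n, 21 * w)
  for (i in seq_len(w))
    out[cbind(seq_len(n), (i - 1L) * 21L + m[, i])] <- 1
  colnames(out) <- as.vector(vapply(position_tags(w), function(p)
    paste0("BINARY.", p, ".", ALPHABET21), character(21)))
  out
}

#' BLOSUM62 substitution-profile encoding
#'
#' Each window position contributes the 21-entry BLOSUM62 row of its
#' residue: substitution scores against the 20 amino acids plus the
#' terminal-signal (`*`) column. Padding residues use the matrix's `X`
#' row.
#'
#' @inheritParams encode_aac
#' @param matrix Substitution table as returned by [blosum62_table()].
#' @return Numeric matrix with `21 * W` columns `BLOSUM62.p01.A` ...
#'   `BLOSUM62.p01.ter`, ...
#' @export
encode_blosum62 <- function(motifs, matrix = blosum62_table()) {
  seqs <- as_motif_seqs(motifs)
  m <- motif_index_matrix(seqs)
  n <- nrow(m); w <- ncol(m)
  out <- base::matrix(0, n, 21 * w)
  for (i in seq_len(w))
    out[, (i - 1L) * 21L + 1:21] <- matrix[m[, i], , drop = FALSE]
  colnames(out) <- as.vector(vapply(position_tags(w), function(p)
    paste0("BLOSUM62.", p, ".", colnames(matrix)), character(21)))
  out
}

#' AAindex physicochemical encoding
#'
#' Each window position contributes the residue's value under each
#' configured AAindex index; `X` positions use the mean of the 20
#' residue values of the index.
#'
#' @inheritParams encode_aac
#' @param table Lookup matrix from [aaindex_table()] (indices x 21
#'   residues).
#' @return Numeric matrix with `W * n_indices` columns
#'   `AAindex.p01.<accession>` ... (21 x 64 = 1344 by default).
#' @export
encode_aaindex <- function(motifs, table = aaindex_table()) {
  seqs <- as_motif_seqs(motifs)
  m <- motif_index_matrix(seqs)
  n <- nrow(m); w <- ncol(m); ni <- nrow(table)
  out <- matrix(0, n, w * ni)
  for (i in seq_len(w))
    out[, (i - 1L) * ni + seq_len(ni)] <- t(table[, m[, i], drop = FALSE])
  colnames(out) <- as.vector(vapply(position_tags(w), function(p)
    paste0("AAindex.", p, ".", rownames(table)), character(ni)))
  out
}

# Absolute protein positions covered by each motif window, plus which
# window slots fall outside the protein (terminal padding).
motif_window_positions <- function(dataset, store) {
  w <- nchar(dataset$sequence[1])
  flank <- (w - 1) / 2
  offsets <- -flank:flank
  lens <- vapply(dataset$protein_id, function(id)
    get_annotation(store, id)$length, numeric(1))
  abspos <- outer(dataset$position, offsets, `+`)
  valid <- abspos >= 1 & abspos <= matrix(lens, nrow(dataset), w)
  list(abspos = abspos, valid = valid, width = w, flank = flank)
}

#' Predicted-disorder encoding
#'
#' The per-residue disorder scores of the 10 upstream and 10 downstream
#' flanking positions (the central cysteine is excluded). Positions
#' padded past a protein terminus score 0.
#'
#' @param dataset A [motif_dataset()].
#' @param store An [annotation_store()] with a `disorder` track per
#'   protein.
#' @return Numeric matrix with `W - 1` columns `DISOPRED.m10` ...
#'   `DISOPRED.m01`, `DISOPRED.p01` ... `DISOPRED.p10`.
#' @export
encode_disorder <- function(dataset, store) {
  win <- motif_window_positions(dataset, store)
  n <- nrow(dataset); w <- win$width
  out <- matrix(0, n, w)
  for (r in seq_len(n)) {
    track <- get_annotation(store, dataset$protein_id[r], "disorder")
    ok <- win$valid[r, ]
    out[r, ok] <- track[win$abspos[r, ok]]
  }
  centre <- win$flank + 1
  out <- out[, -centre, drop = FALSE]
  off <- setdiff(-win$flank:win$flank, 0)
  colnames(out) <- paste0("DISOPRED.",
                          ifelse(off < 0, sprintf("m%02d", -off),
                                 sprintf("p%02d", off)))
  out
}

#' Predicted secondary-structure encoding
#'
#' Four values per window position: the predicted class coded C = 0,
#' E = 1, H = 2, and the three class probabilities. Padded positions
#' are all-zero.
#'
#' @inheritParams encode_disorder
#' @return Numeric matrix with `4 * W` columns (`PSIPRED.p01.class`,
#'   `.pC`, `.pE`, `.pH`, ...); 84 for 21-mers.
#' @export
encode_secondary_structure <- function(dataset, store) {
  win <- motif_window_positions(dataset, store)
  n <- nrow(dataset); w <- win$width
  out <- matrix(0, n, 4 * w)
  class_code <- c(C = 0, E = 1, H = 2)
  for (r in seq_len(n)) {
    ss <- get_annotation(store, dataset$protein_id[r], "ss")
    if (any(ss$pC < 0 | ss$pC > 1 | ss$pE < 0 | ss$pE > 1 |
            ss$pH < 0 | ss$pH > 1))
      stop("secondary-structure probabilities outside [0, 1] for protein ",
           dataset$protein_id[r])
    ok <- which(win$valid[r, ])
    p <- win$abspos[r, ok]
    out[r, (ok - 1L) * 4L + 1L] <- class_code[ss$class[p]]
    out[r, (ok - 1L) * 4L + 2L] <- ss$pC[p]
    out[r, (ok - 1L) * 4L + 3L] <- ss$pE[p]
    out[r, (ok - 1L) * 4L + 4L] <- ss$pH[p]
  }
  colnames(out) <- as.vector(vapply(position_tags(w), function(ptag)
    paste0("PSIPRED.", ptag, ".", c("class", "pC", "pE", "pH")),
    character(4)))
  out
}

# Raw (un-normalized) surface-accessibility block plus the padding mask.
acc_raw_block <- function(dataset, store) {
  win <- motif_window_positions(dataset, store)
  n <- nrow(dataset); w <- win$width
  raw <- matrix(0, n, 7 * w)
  for (r in seq_len(n)) {
    acc <- get_annotation(store, dataset$protein_id[r], "acc")
    ok <- which(win$valid[r, ])
    for (j in 1:7)
      raw[r, (ok - 1L) * 7L + j] <- acc[win$abspos[r, ok], j]
  }
  colnames(raw) <- as.vector(vapply(position_tags(w), function(ptag)
    paste0("ACC.", ptag, ".", ACC_SCORE_NAMES), character(7)))
  list(raw = raw, valid = win$valid, width = w)
}

#' Fit min-max normalization parameters
#'
#' Per-column minimum and maximum of a training matrix, used to rescale
#' values to `[0, 1]` as `(v - min) / (max - min)`. Constant columns
#' are flagged (they map to 0) with a warning.
#'
#' @param values Numeric matrix (observations x score types).
#' @return List of class `min_max_params` with `min`, `max` and
#'   `constant` per column.
#' @examples
#' p <- min_max_fit(cbind(a = c(0, 10)))
#' min_max_apply(cbind(a = 5), p) # 0.5
#' @export
min_max_fit <- function(values) {
  values <- as.matrix(values)
  lo <- apply(values, 2, min)
  hi <- apply(values, 2, max)
  constant <- hi == lo
  if (any(constant))
    warning("constant score column(s) map to 0: ",
            paste(colnames(values)[constant], collapse = ", "))
  structure(list(min = lo, max = hi, constant = constant),
            class = "min_max_params")
}

#' @param params Parameters from [min_max_fit()].
#' @param clip If `TRUE`, clip rescaled values into `[0, 1]` (used at
#'   prediction time, where new scores may exceed the training range).
#' @rdname min_max_fit
#' @export
min_max_apply <- function(values, params, clip = FALSE) {
  if (!inherits(params, "min_max_params"))
    stop("min_max_apply() called before min_max_fit()")
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(params$min))
  rng <- ifelse(params$constant, 1, params$max - params$min)
  out <- sweep(sweep(values, 2, params$min), 2, rng, `/`)
  out[, params$constant] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Predicted surface-accessibility encoding
#'
#' Seven predictor scores per window position (buried/exposed flag,
#' relative and absolute ASA, Z-fit, and the three secondary-structure
#' probabilities), min-max rescaled per score type with parameters
#' fitted on training data. Padded positions are all-zero.
#'
#' @inheritParams encode_disorder
#' @param norm `min_max_params` for the 7 score types, fitted with
#'   [acc_norm_fit()] on the training dataset.
#' @param clip Clip rescaled values into `[0, 1]` (prediction time).
#' @return Numeric matrix with `7 * W` columns (147 for 21-mers).
#' @export
encode_surface_accessibility <- function(dataset, store, norm,
                                         clip = FALSE) {
  if (missing(norm) || !inherits(norm, "min_max_params"))
    stop("surface-accessibility normalization not fitted; ",
         "call acc_norm_fit() on the training data first")
  blk <- acc_raw_block(dataset, store)
  w <- blk$width
  out <- blk$raw
  for (j in 1:7) {
    cols <- seq(j, 7 * w, by = 7)
    sub <- out[, cols, drop = FALSE]
    scaled <- (sub - norm$min[j]) /
      (if (norm$constant[j]) 1 else norm$max[j] - norm$min[j])
    if (norm$constant[j]) scaled[] <- 0
    if (clip) scaled <- pmin(pmax(scaled, 0), 1)
    scaled[!blk$valid] <- 0
    out[, cols] <- scaled
  }
  out
}

#' @rdname encode_surface_accessibility
#' @return `acc_norm_fit()` returns `min_max_params` for the 7 score
#'   types, fitted on all non-padded window positions of the dataset.
#' @export
acc_norm_fit <- function(dataset, store) {
  blk <- acc_raw_block(dataset, store)
  w <- blk$width
  pooled <- do.call(rbind, lapply(1:w, function(i) {
    rows <- blk$valid[, i]
    blk$raw[rows, (i - 1L) * 7L + 1:7, drop = FALSE]
  }))
  colnames(pooled) <- ACC_SCORE_NAMES
  min_max_fit(pooled)
}

#' PSSM conservation-profile encoding
#'
#' Concatenates the per-position PSSM rows (20 log-odds and, with
#' `pssm_width = 21`, the per-position information content) over the
#' window. Padded positions contribute zero rows. With
#' `pssm_drop_terminal = TRUE` the last window position is omitted.
#'
#' @inheritParams encode_disorder
#' @param config An [encoder_config()] (fields `pssm_width`,
#'   `pssm_drop_terminal`).
#' @return Numeric matrix; 441 columns by default for 21-mers, 420 with
#'   `pssm_width = 20`, 400 with the 20-wide terminal-dropping
#'   configuration.
#' @export
encode_pssm <- function(dataset, store, config = encoder_config()) {
  win <- motif_window_positions(dataset, store)
  n <- nrow(dataset); w <- win$width
  keep_cols <- seq_len(config$pssm_width)
  out <- matrix(0, n, w * config$pssm_width)
  for (r in seq_len(n)) {
    pssm <- get_annotation(store, dataset$protein_id[r], "pssm")
    if (nrow(pssm) != get_annotation(store, dataset$protein_id[r])$length)
      stop("PSSM rows do not match protein length for ",
           dataset$protein_id[r])
    ok <- which(win$valid[r, ])
    rows <- pssm[win$abspos[r, ok], keep_cols, drop = FALSE]
    for (j in seq_along(keep_cols))
      out[r, (ok - 1L) * config$pssm_width + j] <- rows[, j]
  }
  score_names <- c(PSSM_RESIDUE_ORDER, "info")[keep_cols]
  colnames(out) <- as.vector(vapply(position_tags(w), function(ptag)
    paste0("PSSM.", ptag, ".", score_names),
    character(config$pssm_width)))
  if (config$pssm_drop_terminal)
    out <- out[, seq_len((w - 1) * config$pssm_width), drop = FALSE]
  out
}

#' Assemble the full feature matrix
#'
#' Encodes a motif dataset with the requested feature blocks and binds
#' them, in the fixed order AAC, CKSAAP, BLOSUM62, PSSM, AAindex,
#' BINARY, DISOPRED, PSIPRED, ACC, into a single matrix with
#' deterministic column names. Under the 400-column PSSM configuration
#' the nine blocks total 5297 columns for 21-mers.
#'
#' @param dataset A [motif_dataset()].
#' @param store An [annotation_store()]; required when any structural
#'   block (PSSM, DISOPRED, PSIPRED, ACC) is requested.
#' @param config An [encoder_config()].
#' @param blocks Cluster names to include (default all nine).
#' @param norm Normalization parameters from a previous (training)
#'   assembly; when `NULL` they are fitted on `dataset`. Supplying them
#'   switches the ACC block to prediction mode (clipping to `[0, 1]`).
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix, rows named by protein/position), `blocks` (named
#'   list of column names per cluster), `config` and `norm`.
#' @export
assemble_feature_matrix <- function(dataset, store = NULL,
                                    config = encoder_config(),
                                    blocks = CLUSTER_NAMES,
                                    norm = NULL) {
  stopifnot(inherits(dataset, "motif_dataset"), nrow(dataset) > 0)
  blocks <- match.arg(blocks, CLUSTER_NAMES, several.ok = TRUE)
  blocks <- CLUSTER_NAMES[CLUSTER_NAMES %in% blocks] # fixed order
  needs_store <- intersect(blocks, setdiff(CLUSTER_NAMES, SEQUENCE_CLUSTERS))
  if (length(needs_store) > 0 && is.null(store))
    stop("blocks ", paste(needs_store, collapse = ", "),
         " need an annotation store")
  predicting <- !is.null(norm)
  if (is.null(norm)) norm <- list()
  parts <- list()
  for (b in blocks) {
    parts[[b]] <- switch(b,
      AAC = encode_aac(dataset),
      CKSAAP = encode_cksaap(dataset, k_max = config$k_max),
      BLOSUM62 = encode_blosum62(dataset),
      PSSM = encode_pssm(dataset, store, config),
      AAindex = encode_aaindex(dataset, aaindex_table(config$aaindex_ids)),
      BINARY = encode_binary(dataset),
      DISOPRED = encode_disorder(dataset, store),
      PSIPRED = encode_secondary_structure(dataset, store),
      ACC = {
        if (is.null(norm$acc)) norm$acc <- acc_norm_fit(dataset, store)
        encode_surface_accessibility(dataset, store, norm$acc,
                                     clip = predicting)
      })
  }
  values <- do.call(cbind, parts)
  rownames(values) <- motif_ids(dataset)
  if (anyDuplicated(colnames(values)))
    stop("internal error: duplicate feature names")
  structure(list(values = values,
                 blocks = lapply(parts, colnames),
                 config = config, norm = norm),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "motifs x", ncol(x$values),
      "features\n")
  dims <- vapply(x$blocks, length, integer(1))
  cat(paste0("  ", names(dims), ": ", dims, collapse = "\n"), "\n")
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' Plain-text exchange format: first column `sample_id`, then one named
#' column per feature. Block structure is recovered from the
#' `<CLUSTER>.` prefixes of the column names.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm$values), fm$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  cluster <- sub("\\..*$", "", colnames(values))
  structure(list(values = values,
                 blocks = split(colnames(values), factor(cluster,
                   levels = unique(cluster))),
                 config = NULL, norm = NULL),
            class = "feature_matrix")
}
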