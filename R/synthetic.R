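# Synthetic motif generator: labelled cysteine-centred windows whose
# flank composition is tilted for positives (the over/under-
# representation seen around real S-sulphenylation sites), plus
# class-conditional pseudo-structural annotations. Everything is
# reproducible from one seed, so the whole selection/stacking/
# evaluation stack is testable without downloads.

#' Synthetic dataset configuration
#'
#' Defaults emulate the reported motif conservation pattern around
#' S-sulphenylated cysteines: leucine, lysine, glutamate and aspartate
#' over-represented, cysteine, serine and phenylalanine
#' under-represented in positives, on a uniform background. The
#' enrichment is a per-residue log-odds shift (nats) applied at every
#' flank position of the positive class.
#'
#' @param n_pos,n_neg Number of positive / negative motifs (>= 10).
#' @param enrichment Named numeric: residue -> log-odds shift for
#'   positives.
#' @param structural_effect Shift of the disorder and relative-
#'   accessibility means for positives (0 = no structural signal).
#' @param background Named numeric over the 20 amino acids (need not be
#'   normalized); default uniform.
#' @param flank Flank width (default 10: 21-mers).
#' @param seed Integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_pos = 500, n_neg = 500,
                         enrichment = c(L = 2, K = 2, E = 2, D = 2,
                                        C = -2, S = -2, F = -2),
                         structural_effect = 0.5,
                         background = NULL, flank = 10, seed = 1) {
  stopifnot(n_pos >= 10, n_neg >= 10, flank >= 1)
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  stopifnot(all(names(background) %in% AA20),
            all(names(enrichment) %in% AA20))
  bg <- setNames(rep(0, 20), AA20)
  bg[names(background)] <- background
  if (any(bg < 0) || sum(bg) <= 0 || any(!is.finite(bg)))
    stop("degenerate background distribution")
  bg <- bg / sum(bg)
  shift <- setNames(rep(0, 20), AA20)
  shift[names(enrichment)] <- enrichment
  pos <- bg * exp(shift)
  if (sum(pos) <= 0 || any(!is.finite(pos)))
    stop("degenerate positive-class distribution")
  pos <- pos / sum(pos)
  structure(list(n_pos = n_pos, n_neg = n_neg, enrichment = shift,
                 structural_effect = structural_effect,
                 bg_probs = bg, pos_probs = pos, flank = flank,
                 seed = seed),
            class = "synth_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Class-conditional pseudo-annotation for one synthetic protein.
synth_annotation <- function(id, chars, effect) {
  L <- length(chars)
  disorder <- clamp01(rnorm(L, 0.25 + effect, 0.15))
  logits <- matrix(rnorm(3 * L), L, 3)
  p3 <- exp(logits) / rowSums(exp(logits))
  cls <- c("C", "E", "H")[max.col(p3, ties.method = "first")]
  rsa <- clamp01(rnorm(L, 0.2 + effect, 0.12))
  acc <- cbind(as.numeric(runif(L) < clamp01(0.3 + effect)),
               rsa, rsa * 120 + rnorm(L, 0, 5), rnorm(L),
               p3[, 3], p3[, 2], p3[, 1])
  colnames(acc) <- ACC_SCORE_NAMES
  # PSSM rows built from the motif's own residues plus noise, so the
  # PSSM block carries class signal only through sequence composition
  pssm <- matrix(round(rnorm(L * 20, 0, 1.2)), L, 20,
                 dimnames = list(NULL, PSSM_RESIDUE_ORDER))
  own <- match(chars, PSSM_RESIDUE_ORDER)
  ok <- !is.na(own)
  pssm[cbind(which(ok), own[ok])] <- round(5 + rnorm(sum(ok)))
  pssm <- cbind(pssm, info = pmax(0, rnorm(L, 1, 0.3)))
  list(protein_id = id, length = L, disorder = disorder,
       ss = data.frame(class = cls, pC = p3[, 1], pE = p3[, 2],
                       pH = p3[, 3], stringsAsFactors = FALSE),
       acc = acc, pssm = pssm)
}

#' Generate a labelled synthetic motif dataset
#'
#' Negative flanks are drawn i.i.d. from the background residue
#' distribution; positive flanks from the background tilted by the
#' configured log-odds enrichment. The central residue is always `C`.
#' Each motif is emitted as its own synthetic protein (length
#' `2 * flank + 1`, cysteine at the centre) with class-conditional
#' pseudo-structural annotations.
#'
#' @param config A [synth_config()].
#' @return List with `dataset` (a [motif_dataset()]) and `store` (an
#'   [annotation_store()] holding disorder/ss/acc/PSSM tracks).
#' @examples
#' d <- generate_dataset(synth_config(n_pos = 10, n_neg = 10, seed = 42))
#' table(d$dataset$label)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  flank <- config$flank
  w <- 2 * flank + 1
  n <- config$n_pos + config$n_neg
  labels <- rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
  ids <- sprintf("SYN%s%05d",
                 ifelse(labels == "positive", "P", "N"),
                 c(seq_len(config$n_pos), seq_len(config$n_neg)))
  with_local_seed(config$seed, {
    seqs <- character(n)
    char_mat <- matrix("", n, w)
    for (i in seq_len(n)) {
      probs <- if (labels[i] == "positive") config$pos_probs
               else config$bg_probs
      fl <- sample(AA20, 2 * flank, replace = TRUE, prob = probs)
      chars <- c(fl[seq_len(flank)], "C", fl[flank + seq_len(flank)])
      char_mat[i, ] <- chars
      seqs[i] <- paste(chars, collapse = "")
    }
    records <- lapply(seq_len(n), function(i) {
      eff <- if (labels[i] == "positive") config$structural_effect else 0
      synth_annotation(ids[i], char_mat[i, ], eff)
    })
    names(records) <- ids
    list(dataset = motif_dataset(ids, rep(flank + 1L, n), seqs, labels),
         store = annotation_store(records))
  })
}

#' Per-position residue enrichment (positives vs negatives)
#'
#' Log-ratio of per-class residue frequencies at each window position,
#' with a 0.5/n pseudo-count: `log((f_pos + 0.5/n_pos) /
#' (f_neg + 0.5/n_neg))`. A plain-number substitute for a sequence
#' logo; the central position (always `C` by construction) is reported
#' as `NA`.
#'
#' @param dataset A labelled [motif_dataset()] with both classes
#'   present.
#' @return Numeric matrix, window positions (rows, named by offset from
#'   the central cysteine) x 20 residues.
#' @export
position_enrichment_table <- function(dataset) {
  stopifnot(inherits(dataset, "motif_dataset"))
  y <- dataset$label
  if (!all(c("positive", "negative") %in% y))
    stop("both classes must be present")
  w <- nchar(dataset$sequence[1])
  flank <- (w - 1) / 2
  m <- motif_index_matrix(dataset$sequence)
  out <- matrix(NA_real_, w, 20,
                dimnames = list(sprintf("%+d", -flank:flank), AA20))
  n_pos <- sum(y == "positive"); n_neg <- sum(y == "negative")
  for (i in seq_len(w)) {
    if (i == flank + 1) next # degenerate: every motif has C here
    for (j in 1:20) {
      fp <- sum(m[y == "positive", i] == j) / n_pos
      fn <- sum(m[y == "negative", i] == j) / n_neg
      out[i, j] <- log((fp + 0.5 / n_pos) / (fn + 0.5 / n_neg))
    }
  }
  out
}

# ---- Writers for the provider file layout (used by the CLI's
# simulate subcommand; each writer emits the dialect its parser reads).

write_annotation_dir <- function(store, dir, sequences) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(sequences)) {
    rec <- get_annotation(store, id)
    chars <- strsplit(sequences[[id]], "")[[1]]
    L <- length(chars)
    writeLines(c("# DISOPRED", sprintf("%5d %s %s %7.3f", seq_len(L),
                 chars, ifelse(rec$disorder >= 0.5, "*", "."),
                 rec$disorder)),
               file.path(dir, paste0(id, ".diso")))
    writeLines(c("# PSIPRED VFORMAT (PSIPRED V3.5)", "",
                 sprintf("%4d %s %s  %6.3f %6.3f %6.3f", seq_len(L),
                         chars, rec$ss$class, rec$ss$pC, rec$ss$pH,
                         rec$ss$pE)),
               file.path(dir, paste0(id, ".ss2")))
    writeLines(sprintf("%s %s %s %4d %8.3f %8.3f %8.3f %6.3f %6.3f %6.3f",
                       ifelse(rec$acc[, 1] >= 0.5, "E", "B"), chars, id,
                       seq_len(L), rec$acc[, 2], rec$acc[, 3],
                       rec$acc[, 4], rec$acc[, 5], rec$acc[, 6],
                       rec$acc[, 7]),
               file.path(dir, paste0(id, ".nsp")))
    pssm_rows <- vapply(seq_len(L), function(i) {
      paste0(sprintf("%5d %s ", i, chars[i]),
             paste(sprintf("%3d", rec$pssm[i, 1:20]), collapse = ""),
             paste(sprintf("%4d", rep(0, 20)), collapse = ""),
             sprintf("  %5.2f %9.2f", rec$pssm[i, 21], 0))
    }, character(1))
    writeLines(c("", "Last position-specific scoring matrix computed",
                 pssm_rows, "", "                      K         Lambda"),
               file.path(dir, paste0(id, ".pssm")))
  }
  invisible(dir)
}

write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences))), path)
  invisible(path)
}
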