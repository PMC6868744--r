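# Packaged constant tables: BLOSUM62 and the default AAindex selection.

# Default AAindex selection: 8 physicochemical property clusters x 8
# AAindex1 accessions. The indices are grouped by the property they
# describe (hydrophobicity, polarity/charge, helix propensity,
# strand/turn propensity, volume/size, flexibility, solvent
# accessibility, transfer/interaction energy); values are looked up in
# the AAindex1 release shipped with the seqinr package. The list is a
# documented default and can be overridden via `encoder_config()`.
AAINDEX_CLUSTERS <- list(
  hydrophobicity  = c("ARGP820101", "CIDH920101", "CIDH920102", "CIDH920103",
                      "CIDH920104", "CIDH920105", "EISD840101", "GOLD730101"),
  polarity_charge = c("CHAM830107", "CHAM830108", "FAUJ880111", "FAUJ880112",
                      "GRAR740102", "KLEP840101", "RADA880108", "ZIMJ680103"),
  helix           = c("ARGP820102", "BURA740101", "CHOP780201", "CHOP780206",
                      "CHOP780207", "GEIM800101", "GEIM800102", "GEIM800103"),
  strand_turn     = c("BEGF750103", "CHAM830102", "CHOP780101", "CHOP780202",
                      "CHOP780203", "CHOP780208", "CHOP780209", "CHOP780212"),
  volume          = c("BIGC670101", "BULH740102", "CHOC750101", "COHE430101",
                      "DAWD720101", "FASG760101", "FAUJ880103", "GOLD730102"),
  flexibility     = c("BHAR880101", "HUTJ700102", "HUTJ700103", "KARP850101",
                      "KARP850102", "KARP850103", "VINM940101", "VINM940102"),
  accessibility   = c("ARGP820103", "BIOV880101", "BIOV880102", "BULH740101",
                      "CHOC760101", "CHOC760102", "CHOC760103", "CHOC760104"),
  energy          = c("CHAM820102", "EISD860101", "HOPA770101", "JANJ790102",
                      "LAWE840101", "NOZY710101", "OOBM850103", "RADA880101")
)

#' Default AAindex accession identifiers
#'
#' Sixty-four AAindex1 accessions, eight per physicochemical property
#' cluster, used by the AAindex encoder unless a custom list is given.
#'
#' @return Character vector of 64 accession identifiers.
#' @export
default_aaindex_ids <- function() unname(unlist(AAINDEX_CLUSTERS))

# seqinr's aaindex uses three-letter residue names; map to one-letter.
.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

.const_cache <- new.env(parent = emptyenv())

#' AAindex lookup table
#'
#' Builds the residue-by-index lookup used by the AAindex encoder. Each
#' index must cover all 20 amino acids; the `X` column is the mean of
#' the 20 residue values of that index.
#'
#' @param ids AAindex1 accession identifiers
#'   (default [default_aaindex_ids()], 64 indices).
#' @return Numeric matrix with one row per index and 21 columns
#'   (`A` ... `Y`, `X`).
#' @export
aaindex_table <- function(ids = default_aaindex_ids()) {
  key <- paste0("aaindex:", paste(ids, collapse = ","))
  if (!is.null(.const_cache[[key]])) return(.const_cache[[key]])
  aaindex <- NULL
  utils::data("aaindex", package = "seqinr", envir = environment())
  acc <- vapply(aaindex, function(a) a$H, "")
  miss <- setdiff(ids, acc)
  if (length(miss) > 0)
    stop("unknown AAindex accession(s): ", paste(miss, collapse = ", "))
  tab <- t(vapply(ids, function(id) {
    v <- aaindex[[match(id, acc)]]$I
    v <- v[names(.AA3TO1)]
    if (any(is.na(v)))
      stop("AAindex ", id, " does not cover all 20 amino acids")
    stats::setNames(as.numeric(v), unname(.AA3TO1))
  }, numeric(20)))
  tab <- tab[, AA20, drop = FALSE]
  tab <- cbind(tab, X = rowMeans(tab))
  rownames(tab) <- ids
  .const_cache[[key]] <- tab
  tab
}

#' BLOSUM62 substitution table
#'
#' The standard NCBI BLOSUM62 matrix (from Biostrings), arranged for
#' the motif encoder: one row per residue of the 21-letter motif
#' alphabet (20 amino acids + `X`), and 21 columns holding the
#' substitution scores against the 20 amino acids plus the terminal
#' signal column (`*`, named `ter`).
#'
#' @return Integer matrix, 21 rows (`A` ... `Y`, `X`) by 21 columns
#'   (`A` ... `Y`, `ter`).
#' @export
blosum62_table <- function() {
  if (!is.null(.const_cache$blosum62)) return(.const_cache$blosum62)
  BLOSUM62 <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  b <- BLOSUM62[ALPHABET21, c(AA20, "*")]
  colnames(b) <- c(AA20, "ter")
  stopifnot(isSymmetric(unname(b[AA20, AA20])))
  .const_cache$blosum62 <- b
  b
}
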