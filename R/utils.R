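# Shared constants and small helpers.

# 20 natural amino acids in alphabetical one-letter order; "X" is the
# gap-filling residue used for terminal padding and non-standard codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
ALPHABET21 <- c(AA20, "X")

# Residue codes that are legal in input but outside the 21-letter
# encoder alphabet; they are mapped to 'X' on read.
NONSTANDARD_AA <- c("B", "J", "O", "U", "Z", "*")

#' Run an expression with a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so library internals never perturb user-level reproducibility.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic string hash to [0, 1)
#'
#' Pure-integer arithmetic kept below 2^53 so results are identical on
#' every platform; used by the mock annotation provider instead of R's
#' floating-point RNG.
#' @noRd
hash01 <- function(strings) {
  M <- 2147483647 # 2^31 - 1
  vapply(strings, function(s) {
    h <- 113
    for (code in utf8ToInt(s)) h <- (h * 131 + code) %% M
    h <- (h * 16807) %% M
    h <- (h * 48271) %% M
    h / M
  }, numeric(1), USE.NAMES = FALSE)
}

# Coerce labels to a factor with levels c("positive", "negative").
# Accepts character labels, logicals, or 0/1 numerics.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    labels <- ifelse(labels == 1, "positive", "negative")
  }
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad) > 0)
    stop("labels must be 'positive'/'negative' (got: ",
         paste(bad, collapse = ", "), ")")
  factor(labels, levels = c("positive", "negative"))
}

# Zero-padded per-position tags: p01 .. p21 for a 21-residue window.
position_tags <- function(width) sprintf("p%02d", seq_len(width))
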