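# Shared fixtures and independent oracles. All fixtures are built in
# code; oracles are deliberately naive (enumeration / all-pairs) and
# never call the implementation they check.

AA20_h <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# A valid random 21-mer motif (central C), possibly with X padding.
random_motif <- function(n_x = 0) {
  chars <- sample(AA20_h, 21, replace = TRUE)
  chars[11] <- "C"
  if (n_x > 0) {
    slots <- sample(setdiff(1:21, 11), n_x)
    chars[slots] <- "X"
  }
  paste(chars, collapse = "")
}

tiny_dataset <- function() {
  motif_dataset(
    protein_id = c("P1", "P1", "P2"),
    position = c(11, 40, 5),
    sequence = c("AAAAAAAAAACAAAAAAAAAA",
                 "LKEDLKEDLKCLKEDLKEDLK",
                 "XXXXXXMKVECAVDESGHIKT"),
    label = c("positive", "negative", "unknown"))
}

# Exhaustive pair-enumeration oracle for the k-spaced amino-acid pair
# composition of a single motif string.
cksaap_oracle <- function(motif, k_max = 5) {
  chars <- strsplit(motif, "")[[1]]
  w <- length(chars)
  out <- numeric(0)
  for (k in 0:k_max) {
    counts <- matrix(0, 20, 20, dimnames = list(AA20_h, AA20_h))
    for (i in seq_len(w - k - 1)) {
      a <- chars[i]; b <- chars[i + k + 1]
      if (a %in% AA20_h && b %in% AA20_h)
        counts[a, b] <- counts[a, b] + 1
    }
    vals <- as.vector(t(counts)) / (w - k - 1)
    names(vals) <- paste0("CKSAAP.k", k, ".",
                          as.vector(t(outer(AA20_h, AA20_h, paste0))))
    out <- c(out, vals)
  }
  out
}

# All-pairs AUC oracle: fraction of (positive, negative) pairs ranked
# concordantly, ties counting one half.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1 | labels == "positive"]
  neg <- scores[labels == 0 | labels == "negative"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Small labelled feature matrix with one informative column.
toy_features <- function(n = 60, p = 5, seed = 1, signal = 2) {
  withr::with_seed(seed, {
    y <- rep(c("positive", "negative"), each = n / 2)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    x[, 1] <- x[, 1] + signal * (y == "positive")
    list(x = x, y = y)
  })
}
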