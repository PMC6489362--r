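# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Derive an independent RNG substream seed from the master seed and a
# stream label, so adding one output file never perturbs the others.
# Kept strictly below .Machine$integer.max (R seeds are 32-bit).
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% 2147483587)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, label))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 helpers
qual_to_phred <- function(qual_string) utf8ToInt(qual_string) - 33L
phred_to_qual <- function(phred) intToUtf8(phred + 33L)

mean_base_quality <- function(qual_strings) {
  vapply(qual_strings, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
         USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "", ...)
}

msg <- function(...) message(format(Sys.time(), "%H:%M:%OS1 "), ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
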