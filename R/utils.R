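# Internal helpers shared across modules.

# Bases treated as informative by all statistics; everything else in the
# alignment alphabet (gaps, N, IUPAC ambiguity) counts as missing.
.VALID_BASES <- c("A", "C", "G", "T")

# Map A/C/G/T to 1:4, everything else to NA. Input: character matrix.
encode_bases <- function(mat) {
  out <- matrix(match(mat, .VALID_BASES), nrow = nrow(mat),
                dimnames = dimnames(mat))
  out
}

# Purines 1 (A), 3 (G); pyrimidines 2 (C), 4 (T). A<->G and C<->T are
# transitions; everything else between valid bases is a transversion.
is_transition <- function(x, y) {
  (x != y) & (((x == 1L) & (y == 3L)) | ((x == 3L) & (y == 1L)) |
              ((x == 2L) & (y == 4L)) | ((x == 4L) & (y == 2L)))
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Vectorised reverse complement on a character vector of single bases.
revcomp_chars <- function(v) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[v]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_plastigap <- function(module, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", module, msg), call. = call.)
}
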