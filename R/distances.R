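# barcode_discrimination (distances): p-distance and Kimura 2-parameter
# distance matrices under pairwise deletion, and the barcode-gap criterion.

# Transition/transversion/valid counts for one encoded pair.
.pair_counts <- function(xi, xj) {
  keep <- !is.na(xi) & !is.na(xj)
  m <- sum(keep)
  if (m == 0L) return(list(m = 0L, ts = 0L, tv = 0L))
  a <- xi[keep]; b <- xj[keep]
  ts <- sum(is_transition(a, b))
  tv <- sum(a != b) - ts
  list(m = m, ts = ts, tv = tv)
}

#' p-distance between two samples
#'
#' Proportion of mismatching sites over pairwise-deleted (both valid) sites.
#'
#' @param aln a \code{\link{species_alignment}}.
#' @param i,j sample ids or indices.
#' @return the distance, or NA (with a warning) when no sites are comparable.
#' @export
p_distance <- function(aln, i, j) {
  enc <- encode_bases(aln$seq)
  ct <- .pair_counts(enc[i, ], enc[j, ])
  if (ct$m == 0L) {
    warning("p_distance undefined: no comparable sites", call. = FALSE)
    return(NA_real_)
  }
  (ct$ts + ct$tv) / ct$m
}

#' Kimura 2-parameter distance between two samples
#'
#' With P = transitions/m and Q = transversions/m over pairwise-deleted
#' sites, d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)). Saturated pairs
#' (1 - 2P - Q <= 0 or 1 - 2Q <= 0) are undefined (NA with a warning),
#' never silently clamped.
#'
#' @inheritParams p_distance
#' @return the K2P distance or NA when undefined.
#' @export
k2p_distance <- function(aln, i, j) {
  enc <- encode_bases(aln$seq)
  ct <- .pair_counts(enc[i, ], enc[j, ])
  if (ct$m == 0L) {
    warning("k2p_distance undefined: no comparable sites", call. = FALSE)
    return(NA_real_)
  }
  .k2p_from_counts(ct$ts, ct$tv, ct$m)
}

.k2p_from_counts <- function(ts, tv, m) {
  P <- ts / m; Q <- tv / m
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("k2p distance saturated (log-domain violation); returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise distance matrix
#'
#' All sample pairs under pairwise deletion, with the substitution model
#' recorded. Undefined pairs (no comparable sites, or K2P saturation) are
#' carried as NA so callers can flag rather than silently drop them.
#'
#' @param aln a \code{species_alignment} (n >= 2).
#' @param model \code{"k2p"} (default) or \code{"p"}.
#' @return an object of class \code{"distance_matrix"}: list with
#'   \code{ids}, \code{d} (symmetric matrix, zero diagonal), \code{m}
#'   (compared-site counts), \code{model}.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p")) {
  model <- match.arg(model)
  enc <- encode_bases(aln$seq)
  n <- nrow(enc)
  if (n < 2L) stop_plastigap("barcode_discrimination", "need >= 2 samples")
  d <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  m <- matrix(ncol(enc), n, n, dimnames = dimnames(d))
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    ct <- .pair_counts(enc[a, ], enc[b, ])
    m[a, b] <- m[b, a] <- ct$m
    val <- if (ct$m == 0L) NA_real_
           else if (model == "p") (ct$ts + ct$tv) / ct$m
           else suppressWarnings(.k2p_from_counts(ct$ts, ct$tv, ct$m))
    d[a, b] <- d[b, a] <- val
  }
  if (anyNA(d))
    warning("distance matrix contains undefined entries", call. = FALSE)
  structure(list(ids = aln$sample_ids, d = d, m = m, model = model,
                 species = aln$species),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s model): %d samples, %d undefined pair(s)\n",
              x$model, length(x$ids), sum(is.na(x$d[upper.tri(x$d)]))))
  invisible(x)
}

#' Barcode-gap test per species
#'
#' A species passes when its minimum interspecific distance is strictly
#' greater than its maximum intraspecific distance. Single-sample species
#' get max_intra = 0 and are flagged \code{single_sample} rather than
#' excluded. Species whose relevant distances include undefined entries are
#' marked untestable (\code{pass = NA}).
#'
#' @param dm a \code{\link{distance_matrix}}.
#' @param species_of named character vector sample id -> species; defaults
#'   to the labels stored in \code{dm}.
#' @return data.frame: \code{species}, \code{max_intra}, \code{min_inter},
#'   \code{pass}, \code{single_sample}.
#' @export
barcode_gap_test <- function(dm, species_of = NULL) {
  species_of <- species_of %||% dm$species
  sp <- species_of[dm$ids]
  rows <- lapply(sort(unique(sp)), function(s) {
    own <- which(sp == s); oth <- which(sp != s)
    intra <- if (length(own) >= 2L) dm$d[own, own][upper.tri(diag(length(own)))]
             else numeric(0)
    inter <- as.vector(dm$d[own, oth, drop = FALSE])
    untestable <- anyNA(intra) || anyNA(inter) || !length(inter)
    max_intra <- if (length(intra)) max(intra) else 0
    min_inter <- if (length(inter)) suppressWarnings(min(inter)) else NA_real_
    data.frame(species = s,
               max_intra = max_intra,
               min_inter = min_inter,
               pass = if (untestable) NA else min_inter > max_intra,
               single_sample = length(own) == 1L)
  })
  do.call(rbind, rows)
}
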