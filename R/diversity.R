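# popgen_diversity: nucleotide diversity (global and sliding-window),
# segregating sites, Hudson-style FST between species, and gene flow Nm.

#' Pairwise differences between two samples
#'
#' Counts mismatching sites between two sequences of an alignment, under
#' pairwise deletion (sites where either sequence is gap/N/ambiguous are
#' skipped) or complete deletion (only sites valid across the whole
#' alignment are compared).
#'
#' @param aln a \code{\link{species_alignment}}.
#' @param i,j sample ids (or row indices); must differ.
#' @param deletion \code{"pairwise"} or \code{"complete"}.
#' @return a list with \code{k} (differences) and \code{m} (compared sites).
#'   \code{m = 0} raises an error rather than silently reporting 0 differences.
#' @export
pairwise_diff <- function(aln, i, j, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  enc <- encode_bases(aln$seq)
  xi <- enc[i, ]; xj <- enc[j, ]
  if (identical(i, j)) stop_plastigap("popgen_diversity", "i and j must differ")
  if (deletion == "complete") {
    keep <- colSums(is.na(enc)) == 0L
  } else {
    keep <- !is.na(xi) & !is.na(xj)
  }
  m <- sum(keep)
  if (m == 0L)
    stop_plastigap("popgen_diversity",
                   "no valid sites shared by the pair; comparison undefined")
  k <- sum(xi[keep] != xj[keep])
  list(k = k, m = m)
}

# Encoded-matrix core: mean per-site pairwise difference over the rows of an
# integer-encoded alignment (NA = missing). Shared by pi, FST and windows.
.pi_encoded <- function(enc, deletion) {
  n <- nrow(enc)
  if (n < 2L) stop_plastigap("popgen_diversity", "need at least 2 samples")
  if (deletion == "complete") {
    valid <- colSums(is.na(enc)) == 0L
    m <- sum(valid)
    if (m == 0L)
      stop_plastigap("popgen_diversity",
                     "no sites valid across all samples; pi undefined")
    sub <- enc[, valid, drop = FALSE]
    npairs <- n * (n - 1) / 2
    # per-column mismatching pairs from base counts
    mism <- 0
    for (b in 1:4) {
      cb <- colSums(sub == b)
      mism <- mism + cb * (cb - 1) / 2
    }
    diff_pairs <- npairs - mism          # vector over columns
    sum(diff_pairs) / (npairs * m)
  } else {
    tot <- 0; npairs <- 0L
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      keep <- !is.na(enc[a, ]) & !is.na(enc[b, ])
      m <- sum(keep)
      if (m == 0L)
        stop_plastigap("popgen_diversity",
                       "a sample pair shares no valid sites; pi undefined")
      tot <- tot + sum(enc[a, keep] != enc[b, keep]) / m
      npairs <- npairs + 1L
    }
    tot / npairs
  }
}

#' Nucleotide diversity (pi)
#'
#' Average per-site pairwise difference among the sampled sequences. Under
#' pairwise deletion, each pair is compared on its own valid sites and the
#' per-pair proportions are averaged; under complete deletion (the DnaSP
#' convention, the default) only columns valid in every sample enter, and
#' pi = (total differences) / (pairs x valid sites).
#'
#' @param aln a \code{species_alignment} (n >= 2).
#' @param deletion \code{"complete"} (default) or \code{"pairwise"}.
#' @return pi, a dimensionless per-site diversity in [0, 1].
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  .pi_encoded(encode_bases(aln$seq), deletion)
}

#' Sliding-window nucleotide diversity
#'
#' Scans the alignment with fixed-size windows (default 600 bp, step 200 bp,
#' the standard DnaSP scan for plastome hotspots). Windows are laid on
#' alignment coordinates: gap columns count toward window span but are
#' excluded from pi by the deletion rule. Only full-length windows are
#' emitted.
#'
#' @param aln a \code{species_alignment} with \code{L >= window}.
#' @param window window length in alignment columns.
#' @param step step size in alignment columns.
#' @param deletion passed to \code{\link{nucleotide_diversity}}.
#' @return a \code{diversity_track}: data.frame with columns \code{start},
#'   \code{end} (0-based half-open), \code{n_valid_sites}, \code{pi}, plus
#'   attributes \code{window} and \code{step}.
#' @export
sliding_window_pi <- function(aln, window = 600, step = 200,
                              deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (window > aln$L)
    stop_plastigap("popgen_diversity", sprintf(
      "window (%d) exceeds alignment length (%d); use nucleotide_diversity()",
      window, aln$L))
  enc <- encode_bases(aln$seq)
  starts <- seq(0L, aln$L - window, by = step)
  res <- lapply(starts, function(s) {
    cols <- (s + 1L):(s + window)
    sub <- enc[, cols, drop = FALSE]
    nv <- if (deletion == "complete") sum(colSums(is.na(sub)) == 0L)
          else sum(colSums(!is.na(sub)) >= 2L)
    p <- tryCatch(.pi_encoded(sub, deletion), error = function(e) NA_real_)
    data.frame(start = s, end = s + window, n_valid_sites = nv, pi = p)
  })
  out <- do.call(rbind, res)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("diversity_track", "data.frame")
  out
}

#' @export
print.diversity_track <- function(x, ...) {
  cat(sprintf("diversity_track: %d windows (window=%d, step=%d), pi range [%g, %g]\n",
              nrow(x), attr(x, "window"), attr(x, "step"),
              min(x$pi, na.rm = TRUE), max(x$pi, na.rm = TRUE)))
  NextMethod()
}

#' Most variable regions of a diversity track
#'
#' Returns the k windows of highest pi, with overlapping top windows merged
#' into single intervals (pi of a merged interval is the max over its
#' windows). Ties broken by leftmost start.
#'
#' @param track a \code{diversity_track}.
#' @param k number of top windows to select before merging.
#' @return data.frame with \code{start}, \code{end}, \code{pi}, ordered by
#'   decreasing pi.
#' @export
top_variable_regions <- function(track, k = 3) {
  if (k < 1) stop_plastigap("popgen_diversity", "k must be >= 1")
  ord <- order(-track$pi, track$start)
  top <- track[head(ord, k), c("start", "end", "pi")]
  top <- top[order(top$start), ]
  merged <- list()
  for (r in seq_len(nrow(top))) {
    row <- top[r, ]
    if (length(merged) && row$start < merged[[length(merged)]]$end) {
      last <- merged[[length(merged)]]
      last$end <- max(last$end, row$end)
      last$pi <- max(last$pi, row$pi)
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- row
  }
  out <- do.call(rbind, merged)
  out[order(-out$pi, out$start), ]
}

#' Number of segregating (polymorphic) sites
#'
#' Columns with at least two distinct non-missing states; gaps, N and
#' ambiguity codes never count as states.
#'
#' @param aln a \code{species_alignment} (n >= 2).
#' @param deletion \code{"complete"} restricts to columns valid in every
#'   sample before counting; \code{"pairwise"} counts over all columns.
#' @return integer count.
#' @export
segregating_sites <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  enc <- encode_bases(aln$seq)
  if (nrow(enc) < 2L) stop_plastigap("popgen_diversity", "need >= 2 samples")
  if (deletion == "complete")
    enc <- enc[, colSums(is.na(enc)) == 0L, drop = FALSE]
  nstates <- apply(enc, 2, function(col) length(unique(col[!is.na(col)])))
  sum(nstates >= 2L)
}

#' Hudson-style FST between two species and island-model gene flow
#'
#' FST = 1 - Hw/Hb, where Hw is the mean of the two within-species
#' diversities (equal species weights by default; the estimator choice is
#' exposed because sample-size weighting is an equally defensible
#' convention) and Hb is the mean per-site difference across all
#' between-species sample pairs. Nm is filled from
#' \code{\link{nm_from_fst}} when FST > 0.
#'
#' @param aln a \code{species_alignment}.
#' @param sp1,sp2 species names present in the alignment.
#' @param deletion deletion rule used throughout (default complete).
#' @param weights \code{"equal"} (default) or \code{"size"} (weight Hw by
#'   within-species pair counts).
#' @return an object of class \code{"fst_result"}: list with
#'   \code{species_pair}, \code{hw}, \code{hb}, \code{fst}, \code{nm}.
#' @export
hudson_fst <- function(aln, sp1, sp2, deletion = c("complete", "pairwise"),
                       weights = c("equal", "size")) {
  deletion <- match.arg(deletion)
  weights <- match.arg(weights)
  idx1 <- which(aln$species == sp1)
  idx2 <- which(aln$species == sp2)
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop_plastigap("popgen_diversity",
                   "each species needs >= 2 samples for within-group diversity")
  enc <- encode_bases(aln$seq)
  if (deletion == "complete") {
    enc <- enc[, colSums(is.na(enc[c(idx1, idx2), , drop = FALSE])) == 0L,
               drop = FALSE]
    if (ncol(enc) == 0L)
      stop_plastigap("popgen_diversity", "no valid sites under complete deletion")
  }
  pair_pi <- function(a, b) {    # mean per-site difference of one pair
    keep <- !is.na(enc[a, ]) & !is.na(enc[b, ])
    m <- sum(keep)
    if (m == 0L) stop_plastigap("popgen_diversity", "pair with no valid sites")
    sum(enc[a, keep] != enc[b, keep]) / m
  }
  within <- function(idx) {
    prs <- combn(idx, 2)
    mean(vapply(seq_len(ncol(prs)),
                function(c) pair_pi(prs[1, c], prs[2, c]), numeric(1)))
  }
  h1 <- within(idx1); h2 <- within(idx2)
  if (weights == "equal") hw <- (h1 + h2) / 2
  else {
    w1 <- choose(length(idx1), 2); w2 <- choose(length(idx2), 2)
    hw <- (w1 * h1 + w2 * h2) / (w1 + w2)
  }
  cross <- expand.grid(a = idx1, b = idx2)
  hb <- mean(mapply(pair_pi, cross$a, cross$b))
  if (hb == 0)
    stop_plastigap("popgen_diversity",
                   "between-group diversity is 0; FST undefined")
  fst <- 1 - hw / hb
  nm <- if (fst > 0) nm_from_fst(fst) else NA_real_
  structure(list(species_pair = c(sp1, sp2), hw = hw, hb = hb,
                 fst = fst, nm = nm),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("FST(%s, %s) = %.5f  (Hw=%.6g, Hb=%.6g)  Nm = %s\n",
              x$species_pair[1], x$species_pair[2], x$fst, x$hw, x$hb,
              if (is.na(x$nm)) "n.d." else sprintf("%.3f", x$nm)))
  invisible(x)
}

#' Island-model gene flow from FST
#'
#' Nm = (1 - FST) / (4 FST), the classic island-model conversion used to
#' report effective migrants per generation alongside FST tables.
#'
#' @param fst differentiation in (0, 1].
#' @return Nm (migrants per generation). Report tables round to 3 decimals.
#' @export
nm_from_fst <- function(fst) {
  if (any(fst <= 0) || any(fst > 1))
    stop_plastigap("popgen_diversity", "Nm defined only for 0 < FST <= 1")
  (1 - fst) / (4 * fst)
}

#' Table of FST and Nm for all species pairs
#'
#' @param aln a \code{species_alignment}.
#' @param pairs optional list of 2-element character vectors; default all
#'   unordered species pairs.
#' @param ... passed to \code{\link{hudson_fst}}.
#' @return data.frame with columns \code{species1}, \code{species2},
#'   \code{fst} (5 decimals), \code{nm} (3 decimals), matching the printed
#'   precision of differentiation tables in the field.
#' @export
fst_table <- function(aln, pairs = NULL, ...) {
  if (is.null(pairs)) {
    sps <- sort(unique(aln$species))
    cmb <- combn(sps, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  rows <- lapply(pairs, function(p) {
    r <- hudson_fst(aln, p[1], p[2], ...)
    data.frame(species1 = p[1], species2 = p[2],
               fst = round(r$fst, 5),
               nm = if (is.na(r$nm)) NA_real_ else round(r$nm, 3))
  })
  do.call(rbind, rows)
}
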