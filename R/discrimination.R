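# barcode_discrimination (criteria): monophyly support on unrooted trees,
# the Table-style discrimination report, and species-diagnostic indels.

#' Bootstrap support for the monophyly of a species
#'
#' On the unrooted tree, a species is monophyletic iff some edge bipartition
#' separates exactly its samples from all others; the support returned is
#' that edge's (bootstrap) label. Non-monophyletic species get
#' \code{monophyletic = FALSE} and no support ("n.d." in reports).
#' Singleton species are trivially monophyletic; their terminal edge carries
#' no internal-node support, so they are flagged instead.
#'
#' @param tree a \code{phylo} with supports as node labels (see
#'   \code{\link{read_newick}}).
#' @param species_of named character vector sample id -> species.
#' @param target species name to test.
#' @return list with \code{monophyletic}, \code{support} (NA when absent or
#'   not monophyletic), \code{singleton}.
#' @export
monophyly_support <- function(tree, species_of, target) {
  tips <- tree$tip.label
  members <- names(species_of)[species_of == target]
  missing <- setdiff(members, tips)
  if (length(missing))
    stop_plastigap("barcode_discrimination", sprintf(
      "samples of %s missing from tree: %s", target,
      paste(missing, collapse = ", ")))
  if (length(members) == 0L)
    stop_plastigap("barcode_discrimination", paste("no samples for", target))
  if (length(members) == 1L)
    return(list(monophyletic = TRUE, support = NA_real_, singleton = TRUE))
  if (length(members) == length(tips))
    return(list(monophyletic = TRUE, support = NA_real_, singleton = FALSE))
  sup <- tree_supports(tree)
  parts <- ape::prop.part(tree)
  key <- paste(sort(members), collapse = "|")
  ckey <- paste(sort(setdiff(tips, members)), collapse = "|")
  hit_direct <- NA_integer_; hit_comp <- NA_integer_
  for (k in seq_along(parts)) {
    set <- tips[parts[[k]]]
    if (length(set) == length(tips)) next
    sk <- paste(sort(set), collapse = "|")
    if (sk == key && is.na(hit_direct)) hit_direct <- k
    if (sk == ckey && is.na(hit_comp)) hit_comp <- k
  }
  if (is.na(hit_direct) && is.na(hit_comp))
    return(list(monophyletic = FALSE, support = NA_real_, singleton = FALSE))
  k <- if (!is.na(hit_direct)) hit_direct else hit_comp
  list(monophyletic = TRUE, support = sup[k], singleton = FALSE)
}

#' Species-discrimination report across markers
#'
#' Applies the tree-based criterion: a species is discriminated by a marker
#' when it is monophyletic with bootstrap support at or above the threshold
#' (the \code{">="} convention of published discrimination tables; the
#' operator is configurable). The summary percentage is
#' 100 x passes / species, rounded to one decimal.
#'
#' @param markers named list: marker name -> named numeric vector of
#'   per-species supports, with NA meaning the species was not monophyletic
#'   ("n.d."). All markers must cover the same species set.
#' @param threshold support cutoff (default 70).
#' @param op comparison operator, \code{">="} (default) or \code{">"}.
#' @return an object of class \code{"discrimination_report"}: list with
#'   \code{details} (long data.frame marker/species/support/pass) and
#'   \code{summary} (marker, percent_discriminated).
#' @export
discrimination_report <- function(markers, threshold = 70, op = c(">=", ">")) {
  op <- match.arg(op)
  cmp <- match.fun(op)
  species <- sort(names(markers[[1]]))
  for (m in markers)
    if (!setequal(names(m), species))
      stop_plastigap("barcode_discrimination",
                     "markers must share the same species set")
  details <- do.call(rbind, lapply(names(markers), function(nm) {
    sup <- markers[[nm]][species]
    data.frame(marker = nm, species = species, support = unname(sup),
               pass = !is.na(sup) & cmp(unname(sup), threshold))
  }))
  summary <- do.call(rbind, lapply(names(markers), function(nm) {
    p <- details$pass[details$marker == nm]
    data.frame(marker = nm,
               percent_discriminated = round(100 * sum(p) / length(p), 1))
  }))
  structure(list(details = details, summary = summary,
                 threshold = threshold, op = op),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("discrimination_report (support %s %g):\n", x$op, x$threshold))
  wide <- x$details
  for (m in unique(wide$marker)) {
    d <- wide[wide$marker == m, ]
    sup <- ifelse(is.na(d$support), "n.d.", format(d$support))
    cat(sprintf("  %-24s %s  -> %.1f%%\n", m,
                paste(sprintf("%s=%s", d$species, sup), collapse = " "),
                x$summary$percent_discriminated[x$summary$marker == m]))
  }
  invisible(x)
}

#' Per-species supports from an alignment via NJ + bootstrap
#'
#' Convenience wrapper: builds the bootstrap-annotated NJ tree for one
#' marker alignment and extracts each species' monophyly support.
#'
#' @param aln a \code{\link{species_alignment}}.
#' @param model,replicates,seed passed to \code{\link{bootstrap_supports}}.
#' @return named numeric vector species -> support (NA = not monophyletic or
#'   support absent).
#' @export
species_supports <- function(aln, model = "p", replicates = 1000, seed) {
  tr <- bootstrap_supports(aln, model = model, replicates = replicates,
                           seed = seed)
  sps <- sort(unique(aln$species))
  vapply(sps, function(s) {
    r <- monophyly_support(tr, aln$species, s)
    if (r$monophyletic) r$support else NA_real_
  }, numeric(1))
}

#' Species-diagnostic indels
#'
#' Maximal runs of alignment columns whose gap pattern is diagnostic for
#' exactly one species: either all of that species' samples carry sequence
#' where every other sample has a gap (insertion), or the converse
#' (deletion).
#'
#' @param aln a \code{\link{species_alignment}}.
#' @param min_len minimum run length in columns to report.
#' @return data.frame with \code{species}, \code{start} (0-based),
#'   \code{length}, \code{type} (\code{"insertion"}/\code{"deletion"});
#'   zero rows when nothing is diagnostic.
#' @export
diagnostic_indels <- function(aln, min_len = 1) {
  gap <- aln$seq == "-"
  sps <- unique(aln$species)
  # per-column label: "species\rtype" or "" when not diagnostic
  lab <- rep("", aln$L)
  for (s in sps) {
    own <- aln$species == s
    ins <- colSums(gap[own, , drop = FALSE]) == 0L &
           colSums(!gap[!own, , drop = FALSE]) == 0L
    del <- colSums(!gap[own, , drop = FALSE]) == 0L &
           colSums(gap[!own, , drop = FALSE]) == 0L
    lab[ins] <- paste(s, "insertion", sep = "\r")
    lab[del] <- paste(s, "deletion", sep = "\r")
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- nzchar(r$values) & r$lengths >= min_len
  if (!any(keep))
    return(data.frame(species = character(0), start = integer(0),
                      length = integer(0), type = character(0)))
  parts <- strsplit(r$values[keep], "\r", fixed = TRUE)
  data.frame(species = vapply(parts, `[`, "", 1),
             start = starts[keep],
             length = r$lengths[keep],
             type = vapply(parts, `[`, "", 2))
}
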