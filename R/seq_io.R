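# seq_io: readers/writers for the formats the pipeline touches, and the
# validated in-memory containers downstream statistics consume.

#' Construct a species-labelled alignment
#'
#' The central container of the package: an aligned set of sequences with a
#' species label per sample. Sequences are stored as an upper-case character
#' matrix (samples x columns) over \code{A,C,G,T,-,N} and IUPAC ambiguity
#' codes; downstream statistics treat everything other than \code{A,C,G,T}
#' as missing.
#'
#' @param seqs named character vector of aligned sequences (equal length), or
#'   a character matrix with one row per sample and rownames as sample ids.
#' @param species named character vector mapping sample id to species name.
#' @return an object of class \code{"species_alignment"} with elements
#'   \code{seq} (character matrix), \code{species} (named character vector),
#'   \code{sample_ids}, and \code{L}.
#' @export
species_alignment <- function(seqs, species) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop_plastigap("seq_io", "sequences must carry unique sample ids")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[lens != max(lens)]
      stop_plastigap("seq_io", sprintf(
        "alignment is ragged: sample(s) %s have length != %d",
        paste(bad, collapse = ", "), max(lens)))
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) < 1L)
    stop_plastigap("seq_io", "alignment must have at least one column")
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids))
    stop_plastigap("seq_io", "sample ids must be unique and non-missing")
  missing_meta <- setdiff(ids, names(species))
  if (length(missing_meta))
    stop_plastigap("seq_io", sprintf(
      "no species label for sample(s): %s", paste(missing_meta, collapse = ", ")))
  sp <- species[ids]
  if (any(is.na(sp)) || any(!nzchar(sp)))
    stop_plastigap("seq_io", "species labels must be non-empty")
  structure(list(seq = mat, species = sp, sample_ids = ids, L = ncol(mat)),
            class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("species_alignment: %d samples x %d columns, %d species\n",
              length(x$sample_ids), x$L, length(unique(x$species))))
  tab <- table(x$species)
  for (s in names(tab)) cat(sprintf("  %s: %d sample(s)\n", s, tab[[s]]))
  invisible(x)
}

#' Read a sample metadata table
#'
#' Tab-separated with header \code{sample_id<TAB>species<TAB>population}
#' and optional \code{lat}, \code{lon} columns.
#'
#' @param path path to the TSV file.
#' @return a data.frame with at least columns \code{sample_id}, \code{species}.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_plastigap("seq_io", paste("no such file:", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species")
  if (!all(need %in% names(df)))
    stop_plastigap("seq_io", "metadata must have columns sample_id and species")
  if (anyDuplicated(df$sample_id))
    stop_plastigap("seq_io", "duplicate sample_id in metadata")
  if (any(is.na(df$species)) || any(!nzchar(df$species)))
    stop_plastigap("seq_io", "species column must be non-empty")
  df
}

#' Read an aligned FASTA into a species alignment
#'
#' @param path aligned FASTA file.
#' @param meta a metadata data.frame (see \code{\link{read_metadata}}) or a
#'   named character vector mapping sample id to species.
#' @return a \code{\link{species_alignment}}.
#' @export
read_alignment <- function(path, meta) {
  if (!file.exists(path)) stop_plastigap("seq_io", paste("no such file:", path))
  recs <- ape::read.FASTA(path)
  seqs <- vapply(as.character(recs), paste, character(1), collapse = "")
  names(seqs) <- names(recs)
  if (is.data.frame(meta)) {
    species <- setNames(meta$species, meta$sample_id)
  } else species <- meta
  unknown <- setdiff(names(seqs), names(species))
  if (length(unknown))
    stop_plastigap("seq_io", sprintf(
      "FASTA sample(s) absent from metadata: %s", paste(unknown, collapse = ", ")))
  species_alignment(seqs, species)
}

#' Write a species alignment as aligned FASTA (70-column wrap)
#'
#' @param aln a \code{species_alignment}.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$sample_ids) {
    s <- paste(aln$seq[id, ], collapse = "")
    writeLines(paste0(">", id), con)
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Extract a column range from an alignment
#'
#' Coordinates are 0-based, half-open (internal convention); human-readable
#' reports elsewhere use 1-based inclusive.
#'
#' @param aln a \code{species_alignment}.
#' @param start,end 0-based half-open column range, \code{0 <= start < end <= L}.
#' @return a \code{species_alignment} of the columns \code{[start, end)}.
#' @export
extract_region <- function(aln, start, end) {
  if (start < 0 || end > aln$L || start >= end)
    stop_plastigap("seq_io", sprintf(
      "region [%d,%d) out of range for alignment of length %d", start, end, aln$L))
  out <- aln
  out$seq <- aln$seq[, (start + 1L):end, drop = FALSE]
  out$L <- end - start
  out
}

#' Concatenate alignments column-wise
#'
#' All regions must cover the identical sample set (order within each region
#' is irrelevant; the first region's order is used).
#'
#' @param regions list of \code{species_alignment} objects.
#' @return the concatenated \code{species_alignment}.
#' @export
concat_regions <- function(regions) {
  if (!length(regions)) stop_plastigap("seq_io", "no regions to concatenate")
  ids <- regions[[1]]$sample_ids
  for (r in regions[-1]) {
    d1 <- setdiff(ids, r$sample_ids); d2 <- setdiff(r$sample_ids, ids)
    if (length(d1) || length(d2))
      stop_plastigap("seq_io", sprintf(
        "sample sets differ between regions; symmetric difference: %s",
        paste(c(d1, d2), collapse = ", ")))
  }
  mat <- do.call(cbind, lapply(regions, function(r) r$seq[ids, , drop = FALSE]))
  rownames(mat) <- ids
  species_alignment(mat, regions[[1]]$species)
}

#' Read a Newick tree with internal-node support labels
#'
#' Supports are parsed from internal node labels (the convention used by
#' RAxML, MEGA and most bootstrap pipelines) and must lie in [0, 100] when
#' present; absent labels stay absent (NA), never coerced to 0.
#'
#' @param path Newick file.
#' @return an \code{ape} \code{phylo} object; \code{node.label} carries the
#'   supports as character (\code{""} where absent).
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_plastigap("seq_io",
                   paste("Newick parse error:", conditionMessage(e))))
  if (is.null(tr)) stop_plastigap("seq_io", "Newick parse error: empty/invalid file")
  if (anyDuplicated(tr$tip.label))
    stop_plastigap("seq_io", "duplicate leaf labels in tree")
  sup <- tree_supports(tr)
  bad <- sup[!is.na(sup)]
  if (length(bad) && (any(bad < 0) || any(bad > 100)))
    stop_plastigap("seq_io", "support values must lie in [0, 100]")
  tr
}

#' Write a tree to Newick
#'
#' @param tree a \code{phylo} object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Numeric supports of a tree's internal nodes
#'
#' @param tree a \code{phylo}; node labels are interpreted as bootstrap
#'   supports where they parse as numbers, NA otherwise.
#' @return numeric vector of length \code{tree$Nnode} (NA = no support).
#' @export
tree_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(ifelse(nzchar(lab), lab, NA)))
}
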