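# barcode_discrimination (trees): Saitou-Nei neighbour joining and
# nonparametric bootstrap supports on the original tree's bipartitions.

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix. Deterministic: when
#' several pairs minimise the Q criterion, the pair whose (id-sorted)
#' representative labels are lexicographically smallest is joined. Negative
#' branch lengths are truncated to zero with a warning.
#'
#' @param dm a \code{\link{distance_matrix}} or a plain symmetric numeric
#'   matrix with dimnames; n >= 3 and all entries defined.
#' @return an unrooted \code{phylo} tree.
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "distance_matrix")) dm$d else dm
  n <- nrow(D)
  if (n < 3L) stop_plastigap("barcode_discrimination", "NJ needs >= 3 taxa")
  if (anyNA(D)) stop_plastigap("barcode_discrimination",
                               "distance matrix has undefined entries")
  labels <- rownames(D)
  # each active cluster: newick fragment + representative (smallest tip id)
  frag <- labels
  rep_id <- labels
  negwarn <- FALSE
  bl <- function(x) { if (x < 0) negwarn <<- TRUE; format(max(x, 0), digits = 12) }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_id[ij[1]], rep_id[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(bi), frag[j], bl(bj))
    newrep <- min(rep_id[i], rep_id[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_id <- c(rep_id[keep], newrep)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    n <- n - 1L
  }
  # final three-point resolution
  ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], bl(ba), frag[2], bl(bb), frag[3], bl(bc))
  if (negwarn)
    warning("negative NJ branch length(s) truncated to 0", call. = FALSE)
  tr <- ape::read.tree(text = nwk)
  # collapse zero-length internal edges: data with no signal for a split
  # yield a multifurcation, not an arbitrary (tie-broken) resolution
  ape::di2multi(tr, tol = 1e-12)
}

# Canonical string key of an internal-edge bipartition: the side not
# containing the reference tip, sorted and pasted.
.bipart_keys <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  ref <- ref %||% min(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0); nodes <- integer(0)
  for (k in seq_along(parts)) {
    set <- tips[parts[[k]]]
    node <- k + length(tips)
    if (length(set) == length(tips)) next   # basal node: not an edge
    side <- if (ref %in% set) setdiff(tips, set) else set
    if (length(side) < 2L || length(side) > length(tips) - 2L) next  # trivial
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and attaches to each internal edge of
#' the original NJ tree the percentage of replicates containing its
#' bipartition. Replicates whose resampled distance matrix has undefined
#' entries are redrawn (counted and warned about).
#'
#' @param aln a \code{\link{species_alignment}}.
#' @param model \code{"p"} (the conventional fast bootstrap model) or
#'   \code{"k2p"}.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; required, so runs are reproducible.
#' @return the original NJ tree with \code{node.label} carrying supports in
#'   [0, 100] (the basal node's label is empty).
#' @export
bootstrap_supports <- function(aln, model = c("p", "k2p"),
                               replicates = 1000, seed) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed))
    stop_plastigap("barcode_discrimination", "seed is required for bootstrap")
  if (replicates < 1) stop_plastigap("barcode_discrimination", "replicates >= 1")
  enc <- encode_bases(aln$seq)
  n <- nrow(enc); L <- ncol(enc)
  prs <- combn(n, 2)
  np <- ncol(prs)
  # pair x column indicators; weighted column sums give per-replicate counts
  validM <- matrix(0, np, L); tsM <- matrix(0, np, L); diffM <- matrix(0, np, L)
  for (c in seq_len(np)) {
    a <- enc[prs[1, c], ]; b <- enc[prs[2, c], ]
    keep <- !is.na(a) & !is.na(b)
    validM[c, ] <- keep
    df <- keep & (a != b)
    diffM[c, ] <- df
    tsM[c, ] <- df & is_transition(a, b)
  }
  dist_from_w <- function(w) {
    m <- as.vector(validM %*% w)
    ts <- as.vector(tsM %*% w)
    dif <- as.vector(diffM %*% w)
    d <- numeric(np)
    for (c in seq_len(np)) {
      if (m[c] == 0) { d[c] <- NA_real_; next }
      d[c] <- if (model == "p") dif[c] / m[c]
              else suppressWarnings(
                .k2p_from_counts(ts[c], dif[c] - ts[c], m[c]))
    }
    D <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
    D[t(prs)] <- d; D[t(prs)[, 2:1]] <- d
    D
  }
  orig <- suppressWarnings(nj_tree(dist_from_w(rep(1, L))))
  ob <- .bipart_keys(orig)
  counts <- setNames(rep(0L, length(ob$keys)), ob$keys)
  set.seed(seed)
  redraws <- 0L
  for (r in seq_len(replicates)) {
    ok <- FALSE
    for (try in 1:100) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      D <- dist_from_w(w)
      if (!anyNA(D)) { ok <- TRUE; break }
      redraws <- redraws + 1L
    }
    if (!ok) stop_plastigap("barcode_discrimination",
                            "could not draw a replicate with defined distances")
    bt <- suppressWarnings(nj_tree(D))
    bk <- .bipart_keys(bt, ref = min(orig$tip.label))$keys
    hit <- ob$keys %in% bk
    counts[hit] <- counts[hit] + 1L
  }
  if (redraws > 0)
    warning(sprintf("%d bootstrap replicate(s) redrawn (undefined distances)",
                    redraws), call. = FALSE)
  sup <- rep("", orig$Nnode)
  sup[ob$nodes - length(orig$tip.label)] <-
    format(round(100 * counts / replicates, 1))
  orig$node.label <- sup
  orig
}
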