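# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

VALID <- c("A", "C", "G", "T")

# random species-labelled alignment as a plain character matrix
random_alignment <- function(n = 5, L = 30, n_species = 2,
                             missing_rate = 0.1) {
  pool <- c(VALID, "-", "N")
  probs <- c(rep((1 - missing_rate) / 4, 4), missing_rate / 2, missing_rate / 2)
  mat <- matrix(sample(pool, n * L, replace = TRUE, prob = probs), n, L)
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  species <- setNames(sample(paste0("sp", seq_len(n_species)), n, replace = TRUE),
                      rownames(mat))
  # guarantee every species present
  species[seq_len(n_species)] <- paste0("sp", seq_len(n_species))
  list(mat = mat, species = species)
}

as_aln <- function(x) species_alignment(x$mat, x$species)

oracle_pair_km <- function(mat, i, j) {
  ok <- mat[i, ] %in% VALID & mat[j, ] %in% VALID
  c(k = sum(mat[i, ok] != mat[j, ok]), m = sum(ok))
}

oracle_pi <- function(mat, deletion = "complete") {
  n <- nrow(mat)
  if (deletion == "complete") {
    keep <- apply(mat, 2, function(col) all(col %in% VALID))
    mat <- mat[, keep, drop = FALSE]
  }
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    km <- oracle_pair_km(mat, i, j)
    tot <- tot + km["k"] / km["m"]
    np <- np + 1
  }
  # complete deletion: every pair shares the same m, so the mean of ratios
  # equals sum(k)/(pairs*m); for pairwise deletion the mean of ratios is it
  unname(tot / np)
}

oracle_seg_sites <- function(mat) {
  keep <- apply(mat, 2, function(col) all(col %in% VALID))
  sum(apply(mat[, keep, drop = FALSE], 2,
            function(col) length(unique(col)) >= 2))
}

oracle_k2p <- function(mat, i, j) {
  ok <- mat[i, ] %in% VALID & mat[j, ] %in% VALID
  a <- mat[i, ok]; b <- mat[j, ok]
  m <- length(a)
  if (m == 0) return(NA_real_)
  pur <- c("A", "G")
  ts <- sum(a != b & ((a %in% pur) == (b %in% pur)))
  tv <- sum(a != b) - ts
  P <- ts / m; Q <- tv / m
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

oracle_gap <- function(d, species) {
  ids <- rownames(d)
  out <- list()
  for (s in sort(unique(species))) {
    own <- ids[species[ids] == s]; oth <- setdiff(ids, own)
    intra <- if (length(own) >= 2) {
      v <- c(); for (i in own) for (j in own) if (i < j) v <- c(v, d[i, j]); v
    } else 0
    inter <- c(); for (i in own) for (j in oth) inter <- c(inter, d[i, j])
    out[[s]] <- c(max_intra = max(intra), min_inter = min(inter))
  }
  out
}

# tips below each edge by naive recursion; returns list of leaf-name sets,
# one per internal edge of the (unrooted) tree
oracle_edge_partitions <- function(tree) {
  tips <- tree$tip.label
  nt <- length(tips)
  below <- function(node) {
    if (node <= nt) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  internal_children <- tree$edge[, 2][tree$edge[, 2] > nt]
  lapply(internal_children, below)
}

oracle_monophyletic <- function(tree, members) {
  tips <- tree$tip.label
  for (set in oracle_edge_partitions(tree)) {
    if (setequal(set, members) || setequal(setdiff(tips, set), members))
      return(TRUE)
  }
  FALSE
}

oracle_overlap <- function(vx, vy) {
  px <- vx / sum(vx); py <- vy / sum(vy)
  c(D = 1 - 0.5 * sum(abs(px - py)),
    I = 1 - 0.5 * sum((sqrt(px) - sqrt(py))^2))
}

# per-species alignment subset
species_subset <- function(aln, s) {
  species_alignment(aln$seq[aln$species == s, , drop = FALSE], aln$species)
}
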