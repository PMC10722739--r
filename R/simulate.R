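# synthetic_data: generators for every input the pipeline consumes, with
# ground truth recorded so estimators can be validated against known values.

#' Specification for a three-species alignment simulation
#'
#' Encodes the study design the generator emulates: three species on a fixed
#' ((B,C),A) topology — one early-diverging species A and a recently
#' diverged sister pair B/C — with a star genealogy inside each species,
#' species-specific indels, and a two-rate (transition/transversion)
#' substitution process. All depths are expected substitutions per site.
#'
#' @param species data.frame with columns \code{name}, \code{n_samples},
#'   \code{crown_depth}; row 1 is the early-diverging species A, rows 2-3
#'   the sister pair B and C.
#' @param stem named numeric vector \code{c(a=, bc=, b=, c=)}: branch depths
#'   from the basal split to A's crown, to the B/C split, and from that
#'   split to each sister crown.
#' @param seq_length alignment length in bp before indel columns.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param indels data.frame with columns \code{species}, \code{length}:
#'   each row plants one insertion private to (and shared by) all samples of
#'   that species, as gap columns in everyone else.
#' @param seed integer seed; the generator is a pure function of (spec, seed).
#' @return an object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(species, stem, seq_length = 20000, kappa = 2,
                            indels = NULL, seed = 1) {
  stopifnot(is.data.frame(species), nrow(species) == 3,
            all(c("name", "n_samples", "crown_depth") %in% names(species)))
  if (any(species$n_samples < 1) || any(species$crown_depth < 0))
    stop_plastigap("synthetic_data", "n_samples >= 1 and crown_depth >= 0 required")
  if (!all(c("a", "bc", "b", "c") %in% names(stem)) || any(stem < 0))
    stop_plastigap("synthetic_data", "stem must be c(a=,bc=,b=,c=) with depths >= 0")
  if (kappa <= 0) stop_plastigap("synthetic_data", "kappa must be > 0")
  if (is.null(indels))
    indels <- data.frame(species = character(0), length = integer(0))
  structure(list(species = species, stem = stem, seq_length = seq_length,
                 kappa = kappa, indels = indels, seed = seed),
            class = "simulation_spec")
}

#' Preset emulating a three-species plastome study design
#'
#' 33 samples (17/7/9) of an early-diverging, high-diversity species and a
#' recently diverged, low-diversity sister pair, with private 18 bp and
#' 66 bp insertions — the configuration under which the package's
#' estimators are validated.
#'
#' @param seed integer seed.
#' @param seq_length alignment length (default 20 kb).
#' @return a \code{\link{simulation_spec}}.
#' @export
triplostegia_preset <- function(seed = 1, seq_length = 20000) {
  simulation_spec(
    species = data.frame(
      name = c("T_glandulifera", "T_grandiflora", "Triplostegia_sp_A"),
      n_samples = c(17L, 7L, 9L),
      crown_depth = c(0.002, 0.0001, 0.0003)),
    stem = c(a = 0.004, bc = 0.0029, b = 0.0017, c = 0.0017),
    seq_length = seq_length, kappa = 2,
    indels = data.frame(species = c("T_grandiflora", "T_glandulifera"),
                        length = c(66L, 18L)),
    seed = seed)
}

# one branch of the two-rate process: exact Poisson substitution count at
# rate `depth` per site, events applied sequentially (multiple hits allowed)
.evolve <- function(seq_enc, depth, kappa) {
  L <- length(seq_enc)
  nsub <- rpois(1, depth * L)
  if (nsub > 0) {
    pos <- sample.int(L, nsub, replace = TRUE)
    is_ts <- runif(nsub) < kappa / (kappa + 2)
    for (e in seq_len(nsub)) {
      b <- seq_enc[pos[e]]
      # partners: transitions A<->G (1,3), C<->T (2,4)
      seq_enc[pos[e]] <- if (is_ts[e]) c(3L, 4L, 1L, 2L)[b]
        else sample(setdiff(1:4, c(b, c(3L, 4L, 1L, 2L)[b])), 1)
    }
  }
  list(seq = seq_enc, nsub = nsub)
}

#' Expected proportion of differing sites under the two-rate process
#'
#' Closed form for the Kimura two-parameter process: with total divergence
#' \code{d} (expected substitutions/site along the path separating two
#' sequences) and rate ratio kappa, returns E[p-distance].
#'
#' @param d total path divergence in expected substitutions per site.
#' @param kappa transition/transversion rate ratio.
#' @return expected mismatch proportion.
#' @export
expected_p_divergence <- function(d, kappa = 2) {
  beta <- 1 / (kappa + 2); alpha <- kappa / (kappa + 2)
  Pts <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  Qtv <- 0.5 - 0.5 * exp(-4 * beta * d)
  Pts + Qtv
}

#' Simulate a species-structured alignment with ground truth
#'
#' Draws a uniform root sequence, evolves it down the fixed ((B,C),A)
#' species tree under the two-rate substitution process with exact Poisson
#' per-branch substitution counts, evolves each sample independently from
#' its species crown (star genealogy), then splices in the species-private
#' indel columns.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{aln} (a \code{\link{species_alignment}}) and
#'   \code{truth}: realized per-branch substitution counts, expected
#'   within-species diversity (\code{expected_pi}), expected between-species
#'   divergence (\code{expected_div}), and planted indel coordinates
#'   (0-based, on the final alignment).
#' @export
simulate_alignment <- function(spec) {
  set.seed(spec$seed)
  L <- spec$seq_length
  kappa <- spec$kappa
  sp <- spec$species
  root <- sample.int(4L, L, replace = TRUE)
  bA <- .evolve(root, spec$stem[["a"]], kappa)
  bBC <- .evolve(root, spec$stem[["bc"]], kappa)
  bB <- .evolve(bBC$seq, spec$stem[["b"]], kappa)
  bC <- .evolve(bBC$seq, spec$stem[["c"]], kappa)
  crowns <- list(bA$seq, bB$seq, bC$seq)
  seqs <- list(); species_of <- character(0)
  tipsubs <- list()
  for (r in 1:3) {
    nm <- sp$name[r]
    for (s in seq_len(sp$n_samples[r])) {
      tip <- .evolve(crowns[[r]], sp$crown_depth[r], kappa)
      id <- sprintf("%s_%02d", nm, s)
      seqs[[id]] <- tip$seq
      species_of[id] <- nm
      tipsubs[[id]] <- tip$nsub
    }
  }
  mat <- do.call(rbind, lapply(seqs, function(e) c("A", "C", "G", "T")[e]))
  rownames(mat) <- names(seqs)
  # plant indels: pick non-overlapping anchor columns in base coordinates,
  # then splice blocks from right to left so earlier anchors stay valid
  indel_truth <- NULL
  if (nrow(spec$indels)) {
    anchors <- sort(sample.int(L - 1L, nrow(spec$indels)), decreasing = TRUE)
    planted <- list()
    for (k in seq_len(nrow(spec$indels))) {
      isp <- spec$indels$species[k]; ilen <- spec$indels$length[k]
      block <- matrix("-", nrow(mat), ilen)
      carrier <- species_of[rownames(mat)] == isp
      ins <- sample(c("A", "C", "G", "T"), ilen, replace = TRUE)
      block[carrier, ] <- matrix(rep(ins, each = sum(carrier)), nrow = sum(carrier))
      at <- anchors[k]
      mat <- cbind(mat[, 1:at, drop = FALSE], block,
                   mat[, (at + 1L):ncol(mat), drop = FALSE])
      planted[[k]] <- data.frame(species = isp, anchor = at, length = ilen)
    }
    # final coordinates: each anchor shifts right by the lengths inserted
    # at smaller anchors (we inserted right-to-left, so add cumulative)
    pl <- do.call(rbind, planted)
    pl <- pl[order(pl$anchor), ]
    shift <- cumsum(c(0, head(pl$length, -1)))
    indel_truth <- data.frame(species = pl$species,
                              start = pl$anchor + shift,
                              length = pl$length)
  }
  rownames(mat) <- names(seqs)
  aln <- species_alignment(mat, species_of)
  dv <- function(total) expected_p_divergence(total, kappa)
  expected_pi <- setNames(dv(2 * sp$crown_depth), sp$name)
  expected_div <- c(
    AB = dv(spec$stem[["a"]] + spec$stem[["bc"]] + spec$stem[["b"]] +
            sp$crown_depth[1] + sp$crown_depth[2]),
    AC = dv(spec$stem[["a"]] + spec$stem[["bc"]] + spec$stem[["c"]] +
            sp$crown_depth[1] + sp$crown_depth[3]),
    BC = dv(spec$stem[["b"]] + spec$stem[["c"]] +
            sp$crown_depth[2] + sp$crown_depth[3]))
  list(aln = aln,
       truth = list(
         branch_subs = c(a = bA$nsub, bc = bBC$nsub, b = bB$nsub, c = bC$nsub),
         tip_subs = unlist(tipsubs),
         expected_pi = expected_pi,
         expected_div = expected_div,
         indels = indel_truth))
}

#' Build a toy circular plastome with a planted inverted repeat
#'
#' Random LSC and SSC sequence with one random IR copied in reverse
#' complement, assembled as LSC + IRb + SSC + IRa. Truth lists the four
#' region coordinates (0-based half-open on the returned origin).
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp.
#' @param seed integer seed.
#' @return list with \code{seq} (DNA string) and \code{truth} (list of
#'   \code{lsc}, \code{irb}, \code{ssc}, \code{ira}, \code{total_length}).
#' @export
make_toy_plastome <- function(lsc_len = 89000, ir_len = 24000,
                              ssc_len = 17900, seed = 1) {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  lsc <- rnd(lsc_len); ssc <- rnd(ssc_len)
  # keep the planted repeat maximal: a single-copy region whose last base
  # complements its first would extend the IR match across the junction
  fix_flank <- function(s) {
    v <- strsplit(s, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (length(v) >= 2 && v[length(v)] == comp[[v[1]]])
      v[length(v)] <- sample(setdiff(c("A", "C", "G", "T"), comp[[v[1]]]), 1)
    paste(v, collapse = "")
  }
  lsc <- fix_flank(lsc); ssc <- fix_flank(ssc)
  irb <- if (ir_len > 0) rnd(ir_len) else ""
  ira <- if (ir_len > 0) revcomp(irb) else ""
  seqstr <- paste0(lsc, irb, ssc, ira)
  tot <- lsc_len + 2 * ir_len + ssc_len
  list(seq = seqstr,
       truth = list(total_length = tot,
                    lsc = c(0L, lsc_len),
                    irb = c(lsc_len, lsc_len + ir_len),
                    ssc = c(lsc_len + ir_len, lsc_len + ir_len + ssc_len),
                    ira = c(lsc_len + ir_len + ssc_len, tot)))
}

#' Rotate a circular sequence
#'
#' Moves the origin forward by \code{k} bases: the result starts at base
#' \code{k} (0-based) of the input circle.
#'
#' @param seq DNA string.
#' @param k rotation offset (0-based).
#' @return rotated string of the same length.
#' @export
rotate_seq <- function(seq, k) {
  n <- nchar(seq)
  k <- k %% n
  if (k == 0) return(seq)
  paste0(substring(seq, k + 1, n), substring(seq, 1, k))
}

#' Simulate a pair of suitability grids with known overlap
#'
#' Two Gaussian-bump suitability surfaces on a shared grid, with oracle
#' Schoener's D and Warren's I computed by direct cell summation at
#' generation time.
#'
#' @param shape c(nrows, ncols).
#' @param centers list of two c(row, col) bump centres.
#' @param widths numeric length-2 bump standard deviations (cells).
#' @param seed integer seed (adds reproducible low-level noise).
#' @param noise_sd sd of multiplicative log-normal noise (0 = none).
#' @return list with \code{gx}, \code{gy} (suitability_grids), and oracle
#'   \code{D}, \code{I}.
#' @export
simulate_grid_pair <- function(shape = c(40, 50),
                               centers = list(c(15, 15), c(25, 35)),
                               widths = c(5, 5), seed = 1, noise_sd = 0) {
  set.seed(seed)
  bump <- function(ctr, w) {
    r <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
    cc <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
    v <- exp(-((r - ctr[1])^2 + (cc - ctr[2])^2) / (2 * w^2))
    if (noise_sd > 0) v <- v * exp(rnorm(length(v), 0, noise_sd))
    v
  }
  vx <- bump(centers[[1]], widths[1])
  vy <- bump(centers[[2]], widths[2])
  px <- vx / sum(vx); py <- vy / sum(vy)
  list(gx = suitability_grid(vx), gy = suitability_grid(vy),
       D = 1 - 0.5 * sum(abs(px - py)),
       I = 1 - 0.5 * sum((sqrt(px) - sqrt(py))^2))
}
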