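# plastome_structure: detect the quadripartite LSC/IRb/SSC/IRa architecture
# of a circular plastome via exact inverted-repeat detection, and report
# region lengths and GC content.

#' GC content of a sequence
#'
#' (G+C)/(A+C+G+T); N and other symbols are excluded from the denominator.
#'
#' @param seq a single DNA string.
#' @return fraction in [0, 1]; error when no countable bases.
#' @export
gc_content <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  gc <- sum(v %in% c("G", "C"))
  at <- sum(v %in% c("A", "T"))
  if (gc + at == 0L)
    stop_plastigap("plastome_structure", "no A/C/G/T bases; GC undefined")
  gc / (gc + at)
}

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the longest pair of maximal exact reverse-complement repeats of at
#' least \code{min_len} bp on the circle (seed-and-extend on exact k-mer
#' anchors, k = 25; circularity handled by doubling the sequence). The
#' longer intervening single-copy arc is labelled LSC, the shorter SSC;
#' the IR copy bordering the LSC at its downstream end is reported as IRb,
#' following plastome convention. Coordinates are reported on the input
#' origin, 0-based half-open, possibly wrapping the origin.
#'
#' @param seq DNA string over A,C,G,T,N (a circular plastome).
#' @param min_len minimal IR length to accept (default 1000; true plastome
#'   IRs are ~24 kb, so this suppresses spurious short repeats).
#' @return an object of class \code{"quadripartite"}: list with
#'   \code{total_length}, \code{found} (logical), and when found
#'   \code{lsc}, \code{irb}, \code{ssc}, \code{ira} (each \code{c(start,
#'   end)} 0-based, end may exceed total for wrapping regions),
#'   \code{ir_len}, \code{gc_total} and per-region GC fractions.
#' @export
detect_inverted_repeat <- function(seq, min_len = 1000) {
  seq <- toupper(seq)
  N <- nchar(seq)
  if (N < 4 * min_len)
    stop_plastigap("plastome_structure",
                   "sequence shorter than 4 x min_len; not a plastome-scale input")
  k <- 25L
  s2 <- paste0(seq, seq)
  chars <- strsplit(s2, "")[[1]]
  rc2 <- paste(revcomp_chars(chars), collapse = "")
  n2 <- 2L * N
  starts <- 1:(n2 - k + 1L)
  K1 <- substring(s2, starts, starts + k - 1L)
  K2 <- substring(rc2, starts, starts + k - 1L)
  mm <- match(K1, K2)
  hit <- which(!is.na(mm))
  if (!length(hit)) return(.no_structure(N, seq))
  # anchor: k-mer at s2 position i equals the k-mer at rc2 position j, i.e.
  # the reverse complement of the k-mer at s2 position p = n2 - j - k + 2.
  # Extending the repeat rightward in copy 1 moves its partner leftward in
  # copy 2: i+1 pairs with p-1, hence j+1 — so j - i is invariant along a
  # reverse-complement repeat and runs of consecutive i trace maximal ones.
  i <- hit; j <- mm[hit]
  diag_id <- j - i
  best_len <- 0L; best <- NULL
  for (d in unique(diag_id)) {
    ii <- sort(i[diag_id == d])
    brk <- c(0L, which(diff(ii) != 1L), length(ii))
    for (r in seq_len(length(brk) - 1L)) {
      run <- ii[(brk[r] + 1L):brk[r + 1L]]
      len <- run[length(run)] - run[1L] + k
      if (len > best_len) { best_len <- len; best <- c(run[1L], d) }
    }
  }
  if (best_len < min_len) return(.no_structure(N, seq))
  # copy 1 in s2: [a, a+len) (1-based); copy 2 starts at the partner of the
  # run's last anchor: b = n2 - diag - a - len + 2
  a <- best[1L]; len <- best_len
  b <- n2 - best[2L] - a - len + 2L
  # map to circle (0-based starts); arcs keep start in [0,N), end may
  # exceed N when a region wraps the origin
  a0 <- (a - 1L) %% N
  b0 <- (b - 1L) %% N
  if (a0 == b0) return(.no_structure(N, seq))   # self-palindrome, degenerate
  ga <- (b0 - (a0 + len)) %% N    # arc from end of copy A to start of copy B
  gb <- (a0 - (b0 + len)) %% N    # arc from end of copy B to start of copy A
  if (ga + gb + 2L * len != N) return(.no_structure(N, seq))  # copies overlap
  arcA <- c((a0 + len) %% N, (a0 + len) %% N + ga)
  arcB <- c((b0 + len) %% N, (b0 + len) %% N + gb)
  if (ga >= gb) {
    # LSC is the arc ending at copy B, so copy B borders the LSC: IRb
    lsc <- arcA; ssc <- arcB
    irb <- c(b0, b0 + len); ira <- c(a0, a0 + len)
  } else {
    lsc <- arcB; ssc <- arcA
    irb <- c(a0, a0 + len); ira <- c(b0, b0 + len)
  }
  circ_sub <- function(rg) {
    idx <- ((rg[1]:(rg[2] - 1L)) %% N) + 1L
    paste(strsplit(seq, "")[[1]][idx], collapse = "")
  }
  structure(list(
    total_length = N, found = TRUE,
    lsc = lsc, irb = irb, ssc = ssc, ira = ira, ir_len = len,
    gc_total = gc_content(seq),
    gc_lsc = gc_content(circ_sub(lsc)),
    gc_ssc = gc_content(circ_sub(ssc)),
    gc_ir = gc_content(circ_sub(irb))),
    class = "quadripartite")
}

.no_structure <- function(N, seq) {
  structure(list(total_length = N, found = FALSE, gc_total = gc_content(seq)),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("quadripartite: no structure found (length %d, GC %.1f%%)\n",
                x$total_length, 100 * x$gc_total))
    return(invisible(x))
  }
  span <- function(r) sprintf("%d..%d (%d bp)", r[1] + 1L,
                              ((r[2] - 1L) %% x$total_length) + 1L, r[2] - r[1])
  cat(sprintf("quadripartite: total %d bp, GC %.1f%%\n",
              x$total_length, 100 * x$gc_total))
  cat(sprintf("  LSC %s | IRb %s | SSC %s | IRa %s\n",
              span(x$lsc), span(x$irb), span(x$ssc), span(x$ira)))
  invisible(x)
}

#' Summary table of quadripartite structures
#'
#' One row per accession (total, LSC, SSC, IR lengths, GC%) plus min-max
#' range rows per species, the shape of plastome characteristics tables.
#'
#' @param structures named list of \code{quadripartite} objects (names =
#'   accession ids).
#' @param species_of optional named character vector accession -> species;
#'   when given, per-species range rows are appended.
#' @return data.frame.
#' @export
structure_table <- function(structures, species_of = NULL) {
  rows <- lapply(names(structures), function(id) {
    s <- structures[[id]]
    if (!s$found)
      return(data.frame(id = id, total = s$total_length, lsc = NA, ssc = NA,
                        ir = NA, gc_pct = round(100 * s$gc_total, 1)))
    data.frame(id = id, total = s$total_length,
               lsc = s$lsc[2] - s$lsc[1], ssc = s$ssc[2] - s$ssc[1],
               ir = s$ir_len, gc_pct = round(100 * s$gc_total, 1))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(species_of)) {
    rng <- function(v) if (min(v) == max(v)) format(min(v), big.mark = ",")
                       else paste0(format(min(v), big.mark = ","), "-",
                                   format(max(v), big.mark = ","))
    for (sp in unique(species_of[tab$id])) {
      sub <- tab[species_of[tab$id] == sp & !is.na(tab$ir), ]
      if (!nrow(sub)) { warning(paste("no structures for species", sp),
                                call. = FALSE); next }
      attr(tab, "ranges") <- rbind(attr(tab, "ranges"),
        data.frame(species = sp, total = rng(sub$total), lsc = rng(sub$lsc),
                   ssc = rng(sub$ssc), ir = rng(sub$ir),
                   gc_pct = rng(sub$gc_pct)))
    }
  }
  tab
}
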