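# Dimer-forming capacity of RNA fragments and the single-strand-specific
# RNase susceptibility profile it implies.
#
# Short (30-31 nt) glycine 5' tRNA halves survive in RNase-rich
# extracellular samples because they hybridize into homo-/heterodimers that
# single-strand-specific RNases cannot attack. The scoring here is a
# sequence-complementarity proxy for that behaviour: the best antiparallel
# hybridization register between two strands (Watson-Crick plus GU wobble,
# no gaps, no intramolecular structure). Capability requires a nucleation
# helix (longest contiguous duplex), near-complete coverage of the shorter
# strand (paired fraction: a duplex that leaves long single-stranded
# overhangs leaves cleavable pyrimidines exposed), and enough total base
# pairs for the duplex to be stable at all (duplex stability scales with
# pair count, so very short fragments cannot protect).

#' Score the dimer-forming capacity of two RNA strands
#'
#' Scans every antiparallel ungapped register of `a` against `b` and reports
#' the register maximizing total paired positions (ties broken by the longer
#' contiguous duplex). `best_duplex_len` is the longest contiguous duplex
#' over all registers; `paired_fraction` is paired nt at the best register
#' divided by the length of the shorter strand.
#'
#' @param a,b RNA sequences (length >= 10).
#' @param allow_gu allow GU wobble pairs (default TRUE).
#' @param min_duplex_len nucleation threshold on `best_duplex_len`.
#' @param min_paired_fraction coverage threshold on `paired_fraction`.
#' @param min_pairs stability threshold on total paired positions at the
#'   best register.
#' @return object of class `dimer_score`: list with `seq_a`, `seq_b`,
#'   `best_duplex_len`, `paired_count`, `paired_fraction`, `dimer_capable`,
#'   `best_offset`, `paired_a`, `paired_b` (0-based paired position sets at
#'   the best register).
#' @export
duplex_score <- function(a, b, allow_gu = TRUE,
                         min_duplex_len = 8, min_paired_fraction = 0.62,
                         min_pairs = 18L) {
  a <- as_rna(a); b <- as_rna(b)
  if (nchar(a) < 10 || nchar(b) < 10) stopf("duplex_score needs lengths >= 10")
  A <- strsplit(a, "")[[1]]
  Brev <- rev(strsplit(b, "")[[1]])
  na <- length(A); nb <- length(Brev)

  best_run_all <- 0L
  best <- list(pairs = -1L, run = -1L, off = NA_integer_, mask = NULL)
  for (off in (-(nb - 1L)):(na - 1L)) {
    j <- seq_len(nb)
    i <- j + off
    ok <- i >= 1L & i <= na
    m <- logical(nb)
    m[ok] <- rna_pairs(A[i[ok]], Brev[ok], allow_gu = allow_gu)
    pairs <- sum(m)
    r <- rle(m)
    run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    best_run_all <- max(best_run_all, run)
    if (pairs > best$pairs || (pairs == best$pairs && run > best$run))
      best <- list(pairs = pairs, run = run, off = off, mask = m)
  }
  j <- which(best$mask)
  paired_b0 <- nb - j                # 0-based positions on b (5'->3')
  paired_a0 <- (j + best$off) - 1L   # 0-based positions on a
  frac <- best$pairs / min(na, nb)
  structure(list(
    seq_a = a, seq_b = b,
    best_duplex_len = best_run_all,
    paired_count = best$pairs,
    paired_fraction = frac,
    dimer_capable = best_run_all >= min_duplex_len &&
      frac >= min_paired_fraction && best$pairs >= min_pairs,
    best_offset = best$off,
    paired_a = sort(paired_a0), paired_b = sort(paired_b0)),
    class = "dimer_score")
}

#' @export
print.dimer_score <- function(x, ...) {
  cat(sprintf("dimer score: duplex %d nt, %d pairs, paired fraction %.3f -> %s\n",
              x$best_duplex_len, x$paired_count, x$paired_fraction,
              if (x$dimer_capable) "dimer-capable" else "not capable"))
  invisible(x)
}

#' Per-position RNase cleavage hazard of a fragment
#'
#' Hazard 1 at every unpaired C, 0 elsewhere; positions paired in the
#' supplied dimer state (the best-register duplex of [duplex_score()],
#' taken on `seq_a`) get hazard 0. Reflects RNase A-family chemistry
#' restricted to cytosines (the motifs observed at the anticodon loop are
#' CpCpA and CpCpU, with scission after each C).
#'
#' @param seq RNA sequence.
#' @param dimer_state optional [duplex_score()] result whose `seq_a` is
#'   `seq`.
#' @return numeric vector of class `susceptibility_profile`, one hazard
#'   weight per position.
#' @export
susceptibility <- function(seq, dimer_state = NULL) {
  seq <- as_rna(seq)
  s <- strsplit(seq, "")[[1]]
  h <- as.numeric(s == "C")
  if (!is.null(dimer_state)) {
    stopifnot(inherits(dimer_state, "dimer_score"))
    if (dimer_state$seq_a != seq)
      stopf("dimer_state was scored on a different sequence")
    h[dimer_state$paired_a + 1L] <- 0
  }
  structure(h, class = "susceptibility_profile")
}

#' Pairwise dimer scores as a TSV-ready table
#'
#' @param seqs named character vector of fragment sequences.
#' @param ... passed to [duplex_score()].
#' @return data.frame with one row per unordered pair (including self pairs).
#' @export
dimer_score_table <- function(seqs, ...) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  rows <- list()
  for (i in seq_along(seqs)) for (j in i:length(seqs)) {
    d <- duplex_score(seqs[[i]], seqs[[j]], ...)
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j],
      best_duplex_len = d$best_duplex_len,
      paired_fraction = d$paired_fraction,
      dimer_capable = d$dimer_capable)
  }
  do.call(rbind, rows)
}
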