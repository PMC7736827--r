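# Shared fixtures and independent oracles used across test files.

# the synthetic reference set is deterministic; build once
REFS <- synthetic_reference_set()
GLY <- exrna:::trna_by_id(REFS, "Gly-GCC-2")

gaussian_trace <- function(centers, areas, sigma = 0.25,
                           grid = seq(4, 20, by = 0.02), drift = 0) {
  y <- drift * (grid - min(grid))
  for (i in seq_along(centers)) y <- y + areas[i] * dnorm(grid, centers[i], sigma)
  chromatogram(grid, a260 = y, a280 = y / 2)
}

# independent duplex oracle: naive per-offset walk, longest contiguous
# run of WC/GU pairs over every antiparallel register
oracle_best_run <- function(a, b, allow_gu = TRUE) {
  pa <- strsplit(a, "")[[1]]
  pb <- rev(strsplit(b, "")[[1]])
  ok <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AU", "UA", "GC", "CG") || (allow_gu && p %in% c("GU", "UG"))
  }
  best <- 0L
  for (off in -(length(pb) - 1):(length(pa) - 1)) {
    run <- 0L
    for (j in seq_along(pb)) {
      i <- j + off
      if (i >= 1 && i <= length(pa) && ok(pa[i], pb[j])) {
        run <- run + 1L
        best <- max(best, run)
      } else run <- 0L
    }
  }
  best
}

# independent cleavage-site oracle: test every trinucleotide window against
# the motif list; a window counts when it overlaps a loop (with one
# position of stem fraying); one cut 3' of each C in the motif, provided
# the scission point touches the (frayed) region and is not terminal
oracle_sites <- function(sequence, cloverleaf, motifs) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  loops <- Filter(Negate(is.null),
                  list(cloverleaf$d_loop, cloverleaf$anticodon_loop,
                       cloverleaf$t_loop))
  touches <- function(pos0)
    any(vapply(loops, function(iv) pos0 >= iv[1] - 1 && pos0 < iv[2] + 1,
               logical(1)))
  overlaps <- function(h0, w)
    any(vapply(loops, function(iv) h0 < iv[2] && h0 + w > iv[1], logical(1)))
  cuts <- integer(0)
  for (m in motifs) {
    w <- nchar(m)
    mc <- strsplit(m, "")[[1]]
    for (h0 in 0:(n - w)) {
      if (!identical(s[(h0 + 1):(h0 + w)], mc)) next
      if (!overlaps(h0, w)) next
      for (k in which(mc == "C")) {
        cut0 <- h0 + k - 1L
        if (cut0 < n - 1L && touches(cut0)) cuts <- c(cuts, cut0)
      }
    }
  }
  sort(unique(cuts))
}

# independent taxonomy oracle, written as a decision table over the published
# windows rather than nested conditionals
oracle_class <- function(start, end, body_len) {
  len <- end - start
  app <- body_len + 3L
  five_anchored <- start <= 1L
  reaches_end <- end == app
  if (start == 0L && reaches_end) return("FULL_LENGTH_CCA")
  if (five_anchored && len %in% 30:31) return("FIVE_HALF_S")
  if (five_anchored && len %in% 33:35) return("FIVE_HALF_L")
  if (five_anchored) return("FIVE_FRAGMENT_OTHER")
  if (reaches_end && len >= 30) return("THREE_HALF")
  if (reaches_end) return("THREE_FRAGMENT")
  "INTERNAL"
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")
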