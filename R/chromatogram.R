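# Size-exclusion chromatogram handling: parsing, baseline correction,
# peak calling, two-component 260/280 unmixing and peak quantitation.
#
# The central observable is a two-channel absorbance trace (A260, A280)
# against elution volume. RNA absorbs more strongly at 260 nm than 280 nm
# (A260/A280 ~ 2 for pure RNA); protein the reverse (~0.57 for BSA). A
# point-wise 2x2 linear system attributes the measured absorbances to an
# RNA and a protein component.

#' Construct a chromatogram
#'
#' @param volume numeric, strictly increasing elution volume (ml).
#' @param a260 numeric, absorbance at 260 nm (AU), same length as `volume`.
#' @param a280 numeric, absorbance at 280 nm (AU), or `NULL` if the trace was
#'   recorded at 260 nm only (stored as all-zero with `a280_missing = TRUE`).
#' @param meta free-text provenance.
#' @return object of class `chromatogram`: a list with fields `volume`,
#'   `a260`, `a280`, `a280_missing`, `meta`.
#' @export
chromatogram <- function(volume, a260, a280 = NULL, meta = "") {
  volume <- as.numeric(volume); a260 <- as.numeric(a260)
  a280_missing <- is.null(a280)
  if (a280_missing) a280 <- numeric(length(volume)) else a280 <- as.numeric(a280)
  if (length(a260) != length(volume) || length(a280) != length(volume))
    stopf("volume, a260 and a280 must have equal length")
  if (length(volume) < 1L) stopf("empty chromatogram")
  if (any(!is.finite(volume)) || any(!is.finite(a260)) || any(!is.finite(a280)))
    stopf("non-finite values in chromatogram")
  if (any(diff(volume) <= 0)) stopf("non-monotone volume")
  structure(list(volume = volume, a260 = a260, a280 = a280,
                 a280_missing = a280_missing, meta = meta),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram: %d points, %.2f-%.2f ml, max A260 %.4g AU%s\n",
              length(x$volume), min(x$volume), max(x$volume), max(x$a260),
              if (x$a280_missing) " (no A280 channel)" else ""))
  invisible(x)
}

#' Read a delimited-text chromatogram export
#'
#' Expects at least two numeric columns (volume, A260) and optionally a third
#' (A280). Instrument-export header blocks can be skipped with `skip`.
#'
#' @param path file path.
#' @param sep field separator (default `,`).
#' @param skip number of header lines to skip before the (optional) column
#'   header row.
#' @param header logical, whether a column-name row follows the skipped block.
#' @param dec decimal mark.
#' @param columns integer vector of length 2 or 3 giving the positions of the
#'   volume, A260 and (optionally) A280 columns.
#' @return a [chromatogram].
#' @export
read_chromatogram <- function(path, sep = ",", skip = 0, header = TRUE,
                              dec = ".", columns = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = sep, skip = skip, header = header,
                          dec = dec, stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE, comment.char = "")
  if (ncol(df) < 2L) stopf("need at least 2 columns (volume, A260), got %d", ncol(df))
  if (is.null(columns)) columns <- seq_len(min(3L, ncol(df)))
  df <- df[, columns, drop = FALSE]
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    stopf("unparseable rows at line(s): %s",
          paste(bad + skip + as.integer(header), collapse = ", "))
  chromatogram(num[[1]], num[[2]],
               if (length(num) >= 3L) num[[3]] else NULL,
               meta = paste0("read from ", path))
}

#' Write a chromatogram as CSV
#' @param c a [chromatogram].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(c, path) {
  stopifnot(inherits(c, "chromatogram"))
  df <- data.frame(ml = c$volume, a260 = c$a260, a280 = c$a280)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# rolling extrema of y over a volume window (ml) on a possibly irregular grid
rolling_stat <- function(volume, y, window_ml, fun) {
  half <- window_ml / 2
  left <- findInterval(volume - half, volume, left.open = FALSE)
  # findInterval gives rightmost index <= v-half; window starts one right of it
  lo <- pmax(left + 1L, 1L)
  lo[volume - half <= volume[1L]] <- 1L
  hi <- findInterval(volume + half, volume)
  vapply(seq_along(y), function(i) fun(y[lo[i]:hi[i]]), numeric(1))
}

# morphological opening: erosion (rolling min) then dilation (rolling max);
# tracks flat and linear baselines exactly while never digging into a peak
# narrower than the window
rolling_baseline <- function(volume, y, window_ml) {
  rolling_stat(volume, rolling_stat(volume, y, window_ml, min), window_ml, max)
}

#' Baseline-correct a chromatogram
#'
#' Subtracts a rolling-minimum baseline (a morphological opening: rolling
#' minimum followed by a matching rolling maximum; window in ml) from each
#' channel and clamps at zero. The opening is monotone and predictable on
#' peaks narrower than the window (it never digs into a peak) and follows
#' flat or linearly drifting baselines without the half-window bias of a
#' plain rolling minimum.
#'
#' @param c a [chromatogram].
#' @param window_ml baseline window on the volume axis (ml, default 2.0).
#' @return baseline-corrected [chromatogram].
#' @export
baseline_correct <- function(c, window_ml = 2.0) {
  stopifnot(inherits(c, "chromatogram"))
  if (window_ml <= 0) stopf("window_ml must be > 0")
  span <- max(c$volume) - min(c$volume)
  if (window_ml > span) stopf("baseline window (%.2f ml) larger than trace span (%.2f ml)",
                              window_ml, span)
  b260 <- rolling_baseline(c$volume, c$a260, window_ml)
  b280 <- rolling_baseline(c$volume, c$a280, window_ml)
  out <- chromatogram(c$volume, pmax(c$a260 - b260, 0), pmax(c$a280 - b280, 0),
                      meta = paste0(c$meta, "; baseline-corrected"))
  out$a280_missing <- c$a280_missing
  out
}

# indices of strict local maxima, plateau-tolerant
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Detect peaks in one absorbance channel
#'
#' Local maxima are filtered by topographic prominence and by width; smaller
#' maxima whose prominence relative to a retained neighbour is below
#' `min_prominence` are absorbed into that neighbour (overlapping shoulders
#' merge). Peak boundaries sit at the flanking minima (half-open on the
#' volume axis); areas in both channels are trapezoidal integrals over
#' `[start_ve, end_ve)`.
#'
#' @param c a baseline-corrected [chromatogram].
#' @param channel 260 or 280: which channel to call peaks on.
#' @param min_prominence minimum peak prominence (AU).
#' @param min_width_ml minimum peak width (ml).
#' @return `data.frame` of class `peak_table` with columns `label`, `apex_ve`,
#'   `start_ve`, `end_ve`, `area_260`, `area_280`, `height`. Labels are
#'   `peak_1..k` until assigned by [assign_peak_labels()].
#' @export
detect_peaks <- function(c, channel = 260, min_prominence = 0.01,
                         min_width_ml = 0.25) {
  stopifnot(inherits(c, "chromatogram"))
  y <- if (channel == 260) c$a260 else c$a280
  v <- c$volume
  n <- length(y)
  empty <- data.frame(label = character(0), apex_ve = numeric(0),
                      start_ve = numeric(0), end_ve = numeric(0),
                      area_260 = numeric(0), area_280 = numeric(0),
                      height = numeric(0))
  class(empty) <- c("peak_table", "data.frame")
  apexes <- local_maxima(y)
  apexes <- apexes[y[apexes] > 0]
  if (!length(apexes)) return(empty)

  # prominence-based absorption: keep apexes tallest-first; an apex is kept
  # only if it rises >= min_prominence above the deepest saddle separating it
  # from every already-kept taller apex
  keep <- integer(0)
  for (a in apexes[order(-y[apexes])]) {
    ok <- TRUE
    for (k in keep) {
      rng <- if (a < k) a:k else k:a
      saddle <- min(y[rng])
      if (y[a] - saddle < min_prominence) { ok <- FALSE; break }
    }
    if (ok && y[a] >= min_prominence) keep <- c(keep, a)
  }
  if (!length(keep)) return(empty)
  keep <- sort(keep)

  # boundaries: deepest point between consecutive retained apexes; outer
  # bounds where the signal first returns to (near) zero or the trace ends
  starts <- ends <- integer(length(keep))
  for (i in seq_along(keep)) {
    a <- keep[i]
    lo <- if (i == 1L) 1L else keep[i - 1L]
    hi <- if (i == length(keep)) n else keep[i + 1L]
    # outermost point of each flanking-minimum plateau, so zero-signal
    # stretches extend the integration bounds instead of truncating tails
    lrng <- lo:a
    lmin <- min(y[lrng])
    starts[i] <- lrng[which(y[lrng] == lmin)[1L]]
    rrng <- a:hi
    rmin <- min(y[rrng])
    ends[i] <- rrng[max(which(y[rrng] == rmin))]
  }
  wide <- (v[ends] - v[starts]) >= min_width_ml
  keep <- keep[wide]; starts <- starts[wide]; ends <- ends[wide]
  if (!length(keep)) return(empty)

  area_in <- function(y2, s, e) {
    idx <- s:e
    trapz(v[idx], y2[idx])
  }
  out <- data.frame(
    label = paste0("peak_", seq_along(keep)),
    apex_ve = v[keep],
    start_ve = v[starts],
    end_ve = v[ends],
    area_260 = vapply(seq_along(keep), function(i) area_in(c$a260, starts[i], ends[i]), numeric(1)),
    area_280 = vapply(seq_along(keep), function(i) area_in(c$a280, starts[i], ends[i]), numeric(1)),
    height = y[keep])
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Assign P0/P1/P2/BSA labels by nearest expected elution volume
#'
#' Labels are matched by proximity to an expected-V_e map rather than by rank
#' order, so a missing peak does not shift the labels of the others.
#'
#' @param peaks a `peak_table` from [detect_peaks()].
#' @param expected named numeric vector of expected apex volumes (ml).
#' @param tol_ml maximum apex distance for a label to be assigned.
#' @return the peak table with labels replaced where matched.
#' @export
assign_peak_labels <- function(peaks,
                               expected = c(P0 = 7.5, BSA = 13.0,
                                            P1 = 15.0, P2 = 16.5),
                               tol_ml = 1.0) {
  if (!nrow(peaks)) return(peaks)
  lab <- peaks$label
  for (nm in names(expected)) {
    d <- abs(peaks$apex_ve - expected[[nm]])
    i <- which.min(d)
    if (d[i] <= tol_ml) lab[i] <- nm
  }
  peaks$label <- lab
  peaks
}

#' Reference 260/280 ratios and response coefficients for unmixing
#'
#' The pure-component ratios default to textbook values for RNA (2.0) and
#' BSA (0.57); both are meant to be overridden with empirically determined
#' values when available. `ext260_rna` is the standard ssRNA response
#' (1 AU at 260 nm = 40 ug/ml, i.e. 0.025 AU per ug/ml).
#'
#' @param ratio_rna A260/A280 of pure RNA (> 1).
#' @param ratio_protein A260/A280 of pure protein (< 1).
#' @param ext260_rna AU of A260 per ug/ml RNA.
#' @param ext260_protein AU of A260 per ug/ml protein.
#' @return object of class `reference_ratios`.
#' @export
reference_ratios <- function(ratio_rna = 2.0, ratio_protein = 0.57,
                             ext260_rna = 0.025, ext260_protein = 0.0038) {
  if (any(c(ratio_rna, ratio_protein, ext260_rna, ext260_protein) <= 0))
    stopf("all reference ratios/coefficients must be positive")
  if (ratio_rna == ratio_protein)
    stopf("ratio_rna == ratio_protein: unmixing system is singular")
  structure(list(ratio_rna = ratio_rna, ratio_protein = ratio_protein,
                 ext260_rna = ext260_rna, ext260_protein = ext260_protein),
            class = "reference_ratios")
}

#' Unmix a two-channel chromatogram into RNA and protein components
#'
#' Per point, solves
#' \deqn{A260 = r + p, \quad A280 = r/R_{rna} + p/R_{prot}}
#' for the RNA-attributable A260 (`r`) and the protein-attributable A260
#' (`p`), where `R` are the pure-component 260/280 ratios. RNA is reported
#' in A260-equivalent units and protein in A280-equivalent units
#' (`p / R_prot`). Negative solutions are clamped to zero and flagged.
#'
#' @param c a baseline-corrected [chromatogram].
#' @param refs a [reference_ratios].
#' @return object of class `unmixed_chromatogram`: list with `volume`,
#'   `rna_signal` (A260 AU), `protein_signal` (A280 AU), `clamped` (logical
#'   per point).
#' @export
unmix <- function(c, refs = reference_ratios()) {
  stopifnot(inherits(c, "chromatogram"), inherits(refs, "reference_ratios"))
  R <- refs$ratio_rna; P <- refs$ratio_protein
  if (R == P) stopf("ratio_rna == ratio_protein: unmixing system is singular")
  # r/R + (a260 - r)/P = a280  =>  r (1/R - 1/P) = a280 - a260/P
  r <- (c$a280 - c$a260 / P) / (1 / R - 1 / P)
  p <- c$a260 - r
  clamped <- (r < 0) | (p < 0)
  r <- pmax(r, 0); p <- pmax(p, 0)
  structure(list(volume = c$volume, rna_signal = r, protein_signal = p / P,
                 clamped = clamped, refs = refs),
            class = "unmixed_chromatogram")
}

#' @export
print.unmixed_chromatogram <- function(x, ...) {
  cat(sprintf("unmixed chromatogram: %d points, %d clamped; max RNA %.4g AU, max protein %.4g AU\n",
              length(x$volume), sum(x$clamped), max(x$rna_signal), max(x$protein_signal)))
  invisible(x)
}

#' Forward-mix RNA and protein signals into a two-channel chromatogram
#'
#' Inverse of [unmix()]; used for round-trip checks and by the synthetic
#' chromatogram generator.
#'
#' @param volume elution volumes (ml).
#' @param rna_a260 RNA-attributable A260 per point.
#' @param protein_a280 protein-attributable A280 per point.
#' @param refs a [reference_ratios].
#' @return a [chromatogram].
#' @export
forward_mix <- function(volume, rna_a260, protein_a280, refs = reference_ratios()) {
  p260 <- protein_a280 * refs$ratio_protein
  chromatogram(volume,
               a260 = rna_a260 + p260,
               a280 = rna_a260 / refs$ratio_rna + protein_a280,
               meta = "forward-mixed")
}

#' Area ratios of the P0 and P1 peaks relative to P2
#'
#' The P0/P2 and P1/P2 260-nm area ratios summarize how much intact
#' high-molecular-weight RNA survives relative to short degradation
#' products; earlier RNase inhibition gives higher ratios.
#'
#' @param peaks a labelled `peak_table` (see [assign_peak_labels()]).
#' @return list with `p0_over_p2` and `p1_over_p2` (NA when P0/P1 absent).
#' @export
peak_ratios <- function(peaks) {
  a <- function(lbl) {
    i <- which(peaks$label == lbl)
    if (length(i) != 1L) NA_real_ else peaks$area_260[i]
  }
  p2 <- a("P2")
  if (is.na(p2)) stopf("reference peak absent: no peak labelled P2")
  if (p2 <= 0) stopf("reference peak P2 has zero area")
  list(p0_over_p2 = a("P0") / p2, p1_over_p2 = a("P1") / p2)
}

#' Quantify RNA mass under a peak of an unmixed chromatogram
#'
#' Integrates the RNA-attributable A260 over `[start_ve, end_ve)` and divides
#' by the RNA response coefficient, giving mass per injected volume
#' (ug/ml-equivalent times ml, i.e. ug under standard loading).
#'
#' @param u an `unmixed_chromatogram`.
#' @param peak one row of a `peak_table` (or any list with `start_ve`,
#'   `end_ve`).
#' @param ext260_rna AU of A260 per ug/ml of RNA.
#' @return numeric RNA amount (ug x ml / ml).
#' @export
quantify_rna <- function(u, peak, ext260_rna = u$refs$ext260_rna %||% 0.025) {
  stopifnot(inherits(u, "unmixed_chromatogram"))
  sel <- u$volume >= peak$start_ve & u$volume < peak$end_ve
  if (!any(sel)) stopf("empty peak interval [%.2f, %.2f)", peak$start_ve, peak$end_ve)
  idx <- which(sel)
  trapz(u$volume[idx], u$rna_signal[idx]) / ext260_rna
}

#' Write a peak table as TSV
#' @param peaks a `peak_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
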