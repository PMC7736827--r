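# Small-RNA read classification: parent assignment, fragment taxonomy, and
# the profiling summaries (size distributions, isoacceptor shares, rRNA
# start positions, mRNA RPKM, fragment-to-parent ratios).
#
# Taxonomy of tRNA-mapped reads (coordinates on the CCA-appended axis):
#   FULL_LENGTH_CCA     start 0, covers the body and ends in the 3' CCA
#   FIVE_HALF_S         5'-anchored, 30-31 nt (the dimer-protected short half)
#   FIVE_HALF_L         5'-anchored, 33-35 nt (anticodon-loop cleavage)
#   FIVE_FRAGMENT_OTHER 5'-anchored, any other length (32 nt falls here:
#                       it belongs to neither published window)
#   THREE_HALF          reaches the CCA-appended 3' end, >= 30 nt
#   THREE_FRAGMENT      reaches the 3' end, < 30 nt
#   INTERNAL            anywhere else
# "5'-anchored" tolerates start <= 1 (one untemplated/trimmed 5' nt).

TAXONOMY_CLASSES <- c("FULL_LENGTH_CCA", "FIVE_HALF_S", "FIVE_HALF_L",
                      "FIVE_FRAGMENT_OTHER", "THREE_HALF", "THREE_FRAGMENT",
                      "INTERNAL", "UNASSIGNED")

#' Construct a read set from unique sequences and counts
#'
#' @param sequences character vector (RNA or DNA alphabet; normalized to
#'   RNA). Reads shorter than `min_len` are dropped (inputs are expected to
#'   be adapter-trimmed already).
#' @param counts integer counts per unique sequence (default all 1;
#'   duplicate sequences are collapsed by summing).
#' @param min_len minimum retained read length (default 15).
#' @return object of class `read_set`: list with `seq`, `count`,
#'   `total_reads`.
#' @export
read_set <- function(sequences, counts = NULL, min_len = 15L) {
  sequences <- as_rna(sequences)
  counts <- counts %||% rep(1L, length(sequences))
  if (length(counts) != length(sequences)) stopf("counts length mismatch")
  if (any(counts < 1)) stopf("counts must be >= 1")
  agg <- tapply(counts, sequences, sum)
  seqs <- names(agg); cnt <- as.integer(agg)
  keep <- nchar(seqs) >= min_len
  structure(list(seq = seqs[keep], count = cnt[keep],
                 total_reads = sum(cnt[keep])),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d unique sequences, %d reads, lengths %d-%d nt\n",
              length(x$seq), x$total_reads,
              if (length(x$seq)) min(nchar(x$seq)) else 0L,
              if (length(x$seq)) max(nchar(x$seq)) else 0L))
  invisible(x)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ path (gz allowed).
#' @param min_len minimum retained read length.
#' @return a [read_set].
#' @export
read_fastq <- function(path, min_len = 15L) {
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  read_set(as.character(ss), min_len = min_len)
}

#' Read a collapsed FASTA (count in header as `>id_x123`) into a read set
#' @param path FASTA path.
#' @param min_len minimum retained read length.
#' @return a [read_set].
#' @export
read_collapsed_fasta <- function(path, min_len = 15L) {
  ss <- Biostrings::readBStringSet(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)\\s*$", "\\1", names(ss))))
  if (any(is.na(cnt))) stopf("collapsed FASTA headers must end in _x<count>")
  read_set(as.character(ss), cnt, min_len = min_len)
}

#' Read aligned reads from a SAM file into a read set
#'
#' Only the read sequences are used; alignments are re-derived against the
#' package's reference set so that tRNA coordinates land on the
#' CCA-appended axis.
#'
#' @param path SAM path.
#' @param min_len minimum retained read length.
#' @return a [read_set].
#' @export
read_sam <- function(path, min_len = 15L) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "seq"))
  read_set(as.character(res[[1]]$seq), min_len = min_len)
}

#' Assign reads to parent transcripts and the fragment taxonomy
#'
#' Each unique sequence is searched as a substring (up to `max_mismatches`
#' substitutions) against every reference, including the CCA-appended tRNA
#' shadows. Hits are resolved by the biotype hierarchy
#' tRNA > rRNA > snoRNA/other ncRNA > mRNA. Within tRNA, hits sharing one
#' anticodon family collapse to that family; ties across families split the
#' read count fractionally. Unmatched sequences are `UNASSIGNED`.
#'
#' @param reads a [read_set].
#' @param refs a `reference_set`.
#' @param max_mismatches maximum substitutions (default 0, exact).
#' @return `data.frame` of class `fragment_annotations`: columns `seq`,
#'   `count` (fractional under ties), `parent_id`, `family`, `biotype`,
#'   `start`, `end` (0-based half-open, CCA-appended axis for tRNA),
#'   `taxonomy_class`, `multimap_n`.
#' @export
match_reads <- function(reads, refs, max_mismatches = 0L) {
  stopifnot(inherits(reads, "read_set"), inherits(refs, "reference_set"))
  n_refs <- length(refs$trnas) + length(refs$seqs)
  if (n_refs == 0L) stopf("empty reference set")

  ids <- c(vapply(refs$trnas, `[[`, "", "id"), names(refs$seqs))
  seqs <- c(vapply(refs$trnas, `[[`, "", "cca_appended"),
            unname(refs$seqs))
  bts <- unname(refs$biotype[ids])
  rank <- c(trna = 1, rrna = 2, snorna = 3, other = 3, mrna = 4)

  # substring search by pigeonhole seeding: with at most one substitution,
  # at least one of two disjoint read windows occurs exactly in the true
  # reference window. Reads of >= 24 nt use two fixed-width 12-mer seeds
  # (read prefix and suffix) against one hashed reference 12-mer index;
  # shorter reads use their two halves against per-length indexes.
  # Candidates are verified by Hamming distance. Covers max_mismatches 0
  # and 1 exactly; larger values fall back to a Biostrings scan.
  rlen <- nchar(reads$seq)
  hit_list <- vector("list", length(reads$seq))
  refraw <- lapply(seqs, charToRaw)
  reflen <- nchar(seqs)

  occurrences <- function(L) {
    # id/start of every reference substring of length L, keyed by substring
    subs <- character(0); packed <- integer(0)
    for (si in seq_along(seqs)) {
      N <- reflen[si]
      if (N < L) next
      st <- seq_len(N - L + 1L)
      subs <- c(subs, substring(seqs[si], st, st + L - 1L))
      packed <- c(packed, si * 10000000L + (st - 1L))
    }
    e <- new.env(parent = emptyenv(), size = length(subs))
    for (q in seq_along(subs)) {
      prev <- e[[subs[q]]]
      e[[subs[q]]] <- if (is.null(prev)) packed[q] else c(prev, packed[q])
    }
    e
  }

  if (max_mismatches <= 1L) {
    occ_cache <- list()
    get_occ <- function(L) {
      key <- as.character(L)
      if (is.null(occ_cache[[key]])) occ_cache[[key]] <<- occurrences(L)
      occ_cache[[key]]
    }
    verify <- function(ri, cand) {
      rs <- reads$seq[ri]; L <- rlen[ri]
      rraw <- charToRaw(rs)
      hits <- list()
      for (pk in cand) {
        si <- pk %/% 10000000L; st0 <- pk %% 10000000L
        if (st0 + L > reflen[si]) next
        mm <- sum(refraw[[si]][(st0 + 1L):(st0 + L)] != rraw)
        if (mm <= max_mismatches)
          hits[[length(hits) + 1L]] <- list(id = ids[si], bt = bts[si],
                                            start = st0, mm = mm)
      }
      hits
    }
    kseed <- 12L
    occk <- if (any(rlen >= 2L * kseed)) get_occ(kseed)
    for (ri in seq_along(reads$seq)) {
      rs <- reads$seq[ri]; L <- rlen[ri]
      if (L >= 2L * kseed) {
        off2 <- L - kseed
        o1 <- occk[[substr(rs, 1L, kseed)]]
        o2 <- occk[[substr(rs, off2 + 1L, L)]]
        if (!is.null(o2)) o2 <- o2[o2 %% 10000000L >= off2] - off2
      } else {
        h1 <- L %/% 2L
        o1 <- get_occ(h1)[[substr(rs, 1L, h1)]]
        o2 <- get_occ(L - h1)[[substr(rs, h1 + 1L, L)]]
        if (!is.null(o2)) o2 <- o2[o2 %% 10000000L >= h1] - h1
      }
      cand <- unique(c(o1, o2))
      if (!length(cand)) next
      hits <- verify(ri, cand)
      if (length(hits)) hit_list[[ri]] <- hits
    }
  } else {
    subjects <- Biostrings::DNAStringSet(as_dna(seqs))
    names(subjects) <- ids
    for (ri in seq_along(reads$seq)) {
      pat <- Biostrings::DNAString(as_dna(reads$seq[ri]))
      pr <- charToRaw(as.character(pat))
      vm <- Biostrings::vmatchPattern(pat, subjects,
                                      max.mismatch = max_mismatches,
                                      with.indels = FALSE)
      hits <- list()
      for (si in seq_along(subjects)) {
        ir <- vm[[si]]
        for (k in seq_along(ir)) {
          st <- Biostrings::start(ir)[k]
          sq <- substring(seqs[si], st, st + length(pat) - 1L)
          mm <- sum(charToRaw(sq) != charToRaw(reads$seq[ri]))
          hits[[length(hits) + 1L]] <- list(id = ids[si], bt = bts[si],
                                            start = st - 1L, mm = mm)
        }
      }
      if (length(hits)) hit_list[[ri]] <- hits
    }
  }

  body_len <- stats::setNames(
    vapply(refs$trnas, function(t) nchar(t$sequence), integer(1)),
    vapply(refs$trnas, `[[`, "", "id"))
  acc <- list(seq = vector("list", length(reads$seq)))
  for (col in c("count", "parent_id", "family", "biotype", "start", "end",
                "taxonomy_class", "multimap_n"))
    acc[[col]] <- vector("list", length(reads$seq))
  for (ri in seq_along(reads$seq)) {
    rs <- reads$seq[ri]; rc <- reads$count[ri]
    hits <- hit_list[[ri]]
    if (is.null(hits) || !length(hits)) {
      acc$seq[[ri]] <- rs; acc$count[[ri]] <- rc
      acc$parent_id[[ri]] <- NA_character_; acc$family[[ri]] <- NA_character_
      acc$biotype[[ri]] <- NA_character_
      acc$start[[ri]] <- NA_integer_; acc$end[[ri]] <- NA_integer_
      acc$taxonomy_class[[ri]] <- "UNASSIGNED"; acc$multimap_n[[ri]] <- 0L
      next
    }
    mmv <- vapply(hits, `[[`, 0L, "mm")
    hits <- hits[mmv == min(mmv)]
    rk <- vapply(hits, function(h) rank[[h$bt]], numeric(1))
    hits <- hits[rk == min(rk)]
    bt <- hits[[1]]$bt
    if (bt == "trna") {
      fams <- unique(anticodon_family(vapply(hits, `[[`, "", "id")))
      if (length(fams) == 1L) hits <- hits[1L]  # collapse to the family
      # else: cross-family tie, split fractionally below
    }
    k <- length(hits)
    hid <- vapply(hits, `[[`, "", "id")
    hbt <- vapply(hits, `[[`, "", "bt")
    hst <- vapply(hits, `[[`, 0L, "start")
    hen <- hst + nchar(rs)
    cls <- vapply(seq_len(k), function(q) {
      if (hbt[q] == "trna") classify_interval(hst[q], hen[q], body_len[[hid[q]]])
      else "INTERNAL"
    }, character(1))
    acc$seq[[ri]] <- rep(rs, k); acc$count[[ri]] <- rep(rc / k, k)
    acc$parent_id[[ri]] <- hid
    acc$family[[ri]] <- ifelse(hbt == "trna", anticodon_family(hid), hid)
    acc$biotype[[ri]] <- hbt
    acc$start[[ri]] <- hst; acc$end[[ri]] <- hen
    acc$taxonomy_class[[ri]] <- cls; acc$multimap_n[[ri]] <- rep(k, k)
  }
  out <- data.frame(seq = unlist(acc$seq), count = unlist(acc$count),
                    parent_id = unlist(acc$parent_id),
                    family = unlist(acc$family), biotype = unlist(acc$biotype),
                    start = unlist(acc$start), end = unlist(acc$end),
                    taxonomy_class = unlist(acc$taxonomy_class),
                    multimap_n = unlist(acc$multimap_n))
  rownames(out) <- NULL
  attr(out, "total_reads") <- reads$total_reads
  attr(out, "mapped_reads") <- sum(out$count[out$taxonomy_class != "UNASSIGNED"])
  class(out) <- c("fragment_annotations", "data.frame")
  out
}

#' Taxonomy class of a tRNA-mapped interval
#'
#' Pure function of (start, end, parent body length); coordinates are
#' 0-based half-open on the CCA-appended axis (appended length =
#' `body_len + 3`).
#'
#' @param start,end read interval.
#' @param body_len mature body length (without CCA).
#' @return one of the taxonomy class labels.
#' @export
classify_interval <- function(start, end, body_len) {
  len <- end - start
  appended <- body_len + 3L
  if (start == 0L && end == appended) return("FULL_LENGTH_CCA")
  if (start <= 1L) {
    if (len >= 30 && len <= 31) return("FIVE_HALF_S")
    if (len >= 33 && len <= 35) return("FIVE_HALF_L")
    return("FIVE_FRAGMENT_OTHER")
  }
  if (end == appended) return(if (len >= 30) "THREE_HALF" else "THREE_FRAGMENT")
  "INTERNAL"
}

#' Classify one tRNA-mapped annotation row against its parent record
#'
#' @param ann one row of a `fragment_annotations` table.
#' @param parent the matching [trna_record].
#' @return taxonomy class label.
#' @export
classify <- function(ann, parent) {
  if (!identical(ann$biotype, "trna"))
    stopf("classify() applies to tRNA-mapped reads; %s keeps positional info only",
          ann$biotype %||% "unassigned")
  classify_interval(ann$start, ann$end, nchar(parent$sequence))
}

mapped_total <- function(ann) {
  tot <- attr(ann, "mapped_reads")
  if (is.null(tot)) tot <- sum(ann$count[ann$taxonomy_class != "UNASSIGNED"])
  tot
}

#' Read-length histogram in RPM for one biotype
#'
#' @param ann a `fragment_annotations` table.
#' @param biotype biotype to profile (`"trna"`, `"rrna"`, ...).
#' @param family optional anticodon family filter (tRNA only).
#' @param classes optional taxonomy class filter.
#' @return data.frame `length`, `rpm` (reads per million mapped).
#' @export
size_distribution <- function(ann, biotype = "trna", family = NULL,
                              classes = NULL) {
  tot <- mapped_total(ann)
  if (tot <= 0) stopf("no mapped reads")
  sel <- ann$biotype %in% biotype & ann$taxonomy_class != "UNASSIGNED"
  if (!is.null(family)) sel <- sel & ann$family %in% family
  if (!is.null(classes)) sel <- sel & ann$taxonomy_class %in% classes
  a <- ann[sel, , drop = FALSE]
  if (!nrow(a)) return(data.frame(length = integer(0), rpm = numeric(0)))
  len <- nchar(a$seq)
  h <- tapply(a$count, len, sum)
  data.frame(length = as.integer(names(h)), rpm = as.numeric(h) * 1e6 / tot)
}

#' Share of tRNA-mapped reads per anticodon family
#' @param ann a `fragment_annotations` table.
#' @return data.frame `family`, `share` (fractions summing to 1).
#' @export
isoacceptor_table <- function(ann) {
  a <- ann[ann$biotype %in% "trna", , drop = FALSE]
  if (!nrow(a)) stopf("no tRNA-mapped reads")
  h <- tapply(a$count, a$family, sum)
  out <- data.frame(family = names(h), share = as.numeric(h) / sum(h))
  out[order(-out$share), , drop = FALSE]
}

#' Start-position histogram of reads on one rRNA
#'
#' Positions are reported 1-based (as read "starting positions").
#'
#' @param ann a `fragment_annotations` table.
#' @param rrna_id rRNA reference id.
#' @return list with `histogram` (data.frame `start`, `rpm`) and `mode`
#'   (1-based start carrying the most reads; NA when empty).
#' @export
rrna_start_profile <- function(ann, rrna_id) {
  tot <- mapped_total(ann)
  a <- ann[ann$parent_id %in% rrna_id, , drop = FALSE]
  if (!nrow(a)) return(list(histogram = data.frame(start = integer(0),
                                                   rpm = numeric(0)),
                            mode = NA_integer_))
  h <- tapply(a$count, a$start + 1L, sum)
  hist <- data.frame(start = as.integer(names(h)),
                     rpm = as.numeric(h) * 1e6 / tot)
  list(histogram = hist, mode = hist$start[which.max(hist$rpm)])
}

#' mRNA abundance table in RPKM
#'
#' Reads of at least `min_len` nt are kept; mRNAs supported by fewer than
#' `min_count` reads are dropped. RPKM = count / (transcript kb x mapped
#' millions), mapped = all mapped reads in the annotation set.
#'
#' @param ann a `fragment_annotations` table.
#' @param refs the `reference_set` (for transcript lengths).
#' @param min_len minimum read length (default 19).
#' @param min_count minimum supporting reads per mRNA (default 5).
#' @return data.frame `id`, `count`, `length_nt`, `rpkm`.
#' @export
mrna_rpkm <- function(ann, refs, min_len = 19L, min_count = 5L) {
  tot <- mapped_total(ann)
  if (tot <= 0) stopf("zero mapped reads")
  a <- ann[ann$biotype %in% "mrna" & nchar(ann$seq) >= min_len, , drop = FALSE]
  if (!nrow(a)) return(data.frame(id = character(0), count = numeric(0),
                                  length_nt = integer(0), rpkm = numeric(0)))
  cnt <- tapply(a$count, a$parent_id, sum)
  keep <- cnt >= min_count
  cnt <- cnt[keep]
  if (!length(cnt)) return(data.frame(id = character(0), count = numeric(0),
                                      length_nt = integer(0), rpkm = numeric(0)))
  lens <- vapply(names(cnt), function(id) nchar(refs$seqs[[id]]), integer(1))
  data.frame(id = names(cnt), count = as.numeric(cnt), length_nt = lens,
             rpkm = as.numeric(cnt) / (lens / 1e3) / (tot / 1e6),
             row.names = NULL)
}

#' Correlate an RPKM table with an external expression table
#'
#' Correlation on `log10(x + pseudocount)` over intersecting ids.
#'
#' @param rpkm data.frame with `id` and `rpkm` (from [mrna_rpkm()]).
#' @param external named numeric vector or data.frame with `id` and a value
#'   column.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param pseudocount added before the log (default 0.1).
#' @return list with `r`, `p`, `n`, `method`.
#' @export
correlate_expression <- function(rpkm, external, method = c("pearson", "spearman"),
                                 pseudocount = 0.1) {
  method <- match.arg(method)
  if (is.data.frame(external)) {
    ext <- external[[2]]; names(ext) <- external[[1]]
  } else ext <- external
  common <- intersect(rpkm$id, names(ext))
  if (length(common) < 3L) stopf("fewer than 3 shared transcript ids")
  x <- log10(rpkm$rpkm[match(common, rpkm$id)] + pseudocount)
  y <- log10(as.numeric(ext[common]) + pseudocount)
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       method = method)
}

#' Fragment-to-parent read-mass ratio per anticodon family
#'
#' Ratio of read mass in fragment classes (everything tRNA-mapped except
#' `FULL_LENGTH_CCA`) to full-length read mass. A zero denominator with
#' nonzero numerator yields `Inf` with `denominator_zero = TRUE` (the
#' fully-degraded endpoint).
#'
#' @param ann a `fragment_annotations` table.
#' @param family anticodon family (e.g. `"Gly-GCC"`), or `NULL` for all
#'   tRNA-mapped reads pooled.
#' @param classes which fragment classes count as the numerator (default
#'   all non-full-length tRNA classes).
#' @return list with `ratio`, `fragment_mass`, `full_length_mass`,
#'   `denominator_zero`.
#' @export
fragment_to_parent_ratio <- function(ann, family = NULL,
                                     classes = setdiff(TAXONOMY_CLASSES,
                                                       c("FULL_LENGTH_CCA", "UNASSIGNED"))) {
  a <- ann[ann$biotype %in% "trna", , drop = FALSE]
  if (!is.null(family)) a <- a[a$family %in% family, , drop = FALSE]
  fl <- sum(a$count[a$taxonomy_class == "FULL_LENGTH_CCA"])
  fr <- sum(a$count[a$taxonomy_class %in% classes])
  if (fl == 0) {
    ratio <- if (fr > 0) Inf else 0
    return(list(ratio = ratio, fragment_mass = fr, full_length_mass = 0,
                denominator_zero = TRUE))
  }
  list(ratio = fr / fl, fragment_mass = fr, full_length_mass = fl,
       denominator_zero = FALSE)
}

#' Write a fragment-annotation table as TSV (1-based inclusive coordinates)
#' @param ann a `fragment_annotations` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  rep <- ann
  rep$start_1based <- rep$start + 1L
  rep$end_1based <- rep$end
  rep$start <- rep$end <- NULL
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
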