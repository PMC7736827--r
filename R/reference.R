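# Reference transcripts: mature tRNAs with cloverleaf annotation, plus
# rRNA/snoRNA/mRNA sequence maps, and prediction of single-strand-specific
# ribonuclease cleavage products.
#
# Coordinates are 0-based half-open internally; reports are 1-based
# inclusive. Mature tRNA bodies are stored WITHOUT the nontemplated 3' CCA;
# a CCA-appended shadow is generated for read matching.

#' Annotate a mature tRNA sequence with a canonical cloverleaf template
#'
#' Positional template: the acceptor stem pairs the first 7 nt with the 7 nt
#' preceding the 3' discriminator base; the anticodon arm is located by
#' scanning the central region for a 7-nt loop flanked by a 5-bp
#' complementary stem (GU wobble allowed); the T-loop is placed at its
#' canonical distance from the 3' end and the D-loop between the acceptor
#' and anticodon stems. Returns `NULL` (no template fit) when no anticodon
#' arm is found.
#'
#' @param sequence mature tRNA body (RNA alphabet, no CCA), length 70-95.
#' @param anticodon optional anticodon (e.g. "GCC"); when given, candidate
#'   loops whose central triplet matches are preferred.
#' @return list with 0-based half-open intervals `acceptor_5p`,
#'   `acceptor_3p`, `d_loop`, `anticodon_loop`, `t_loop`, and
#'   `anticodon` = c(start, end) of the anticodon triplet; or `NULL` if no
#'   template fit.
#' @export
annotate_cloverleaf_template <- function(sequence, anticodon = NULL) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n < 70 || n > 95) stopf("tRNA body length %d outside 70-95", n)
  s <- strsplit(sequence, "")[[1]]

  # candidate anticodon arms: 1-based loop start ls, loop = ls..ls+6,
  # stems = (ls-5..ls-1) paired with (ls+7..ls+11)
  cand <- list()
  for (ls in 6:(n - 11)) {
    st5 <- s[(ls - 5):(ls - 1)]
    st3 <- s[(ls + 7):(ls + 11)]
    pair <- rna_pairs(st5, rev(st3), allow_gu = TRUE)
    if (all(pair)) {
      wc <- sum(rna_pairs(st5, rev(st3), allow_gu = FALSE))
      ac <- paste(s[(ls + 2):(ls + 4)], collapse = "")
      cand[[length(cand) + 1L]] <- list(ls = ls, wc = wc, ac = ac)
    }
  }
  if (!length(cand)) return(NULL)
  # prefer anticodon match (when known), then central location, then WC pairs
  center <- n / 2
  score <- vapply(cand, function(x) {
    match_bonus <- if (!is.null(anticodon) && x$ac == as_rna(anticodon)) 1000 else 0
    match_bonus + x$wc * 10 - abs((x$ls + 3) - center)
  }, numeric(1))
  best <- cand[[which.max(score)]]
  ls0 <- best$ls - 1L  # 0-based loop start

  t_loop <- if (n >= 22) c(n - 22L, n - 15L) else NULL  # canonical T-loop, 0-based half-open
  d_loop_end <- max(ls0 - 9L, 11L)  # up to the 5' anticodon stem minus D-stem
  list(
    acceptor_5p = c(0L, 7L),
    acceptor_3p = c(n - 8L, n - 1L),   # 7 nt before the discriminator base
    d_loop = c(10L, d_loop_end),
    anticodon_loop = c(ls0, ls0 + 7L),
    t_loop = t_loop,
    anticodon = c(ls0 + 2L, ls0 + 5L),
    anticodon_seq = best$ac
  )
}

#' Construct a tRNA record
#'
#' @param id name carrying amino acid, anticodon and isodecoder index,
#'   e.g. `"Gly-GCC-2"`.
#' @param sequence mature body, RNA alphabet, without the 3' CCA.
#' @param cloverleaf optional precomputed template (see
#'   [annotate_cloverleaf_template()]); computed when `NULL`.
#' @return object of class `trna_record` with fields `id`, `sequence`,
#'   `cca_appended` (the matching shadow with CCA), `cloverleaf`,
#'   `anticodon`.
#' @export
trna_record <- function(id, sequence, cloverleaf = NULL) {
  sequence <- unname(as_rna(sequence))
  parts <- strsplit(id, "-")[[1]]
  anticodon <- if (length(parts) >= 2L) as_rna(parts[2]) else NULL
  if (is.null(cloverleaf))
    cloverleaf <- annotate_cloverleaf_template(sequence, anticodon)
  if (!is.null(cloverleaf) && !is.null(anticodon)) {
    ac <- substr(sequence, cloverleaf$anticodon[1] + 1L, cloverleaf$anticodon[2])
    if (ac != anticodon)
      stopf("tRNA %s: annotated anticodon reads %s, id says %s", id, ac, anticodon)
  }
  structure(list(id = id, sequence = sequence,
                 cca_appended = paste0(sequence, "CCA"),
                 cloverleaf = cloverleaf, anticodon = anticodon),
            class = "trna_record")
}

#' @export
print.trna_record <- function(x, ...) {
  cat(sprintf("tRNA %s: %d nt body%s, anticodon %s at %s\n", x$id,
              nchar(x$sequence), " (+CCA)",
              x$anticodon %||% "?",
              if (is.null(x$cloverleaf)) "no template fit"
              else sprintf("%d-%d (1-based)", x$cloverleaf$anticodon[1] + 1L,
                           x$cloverleaf$anticodon[2])))
  invisible(x)
}

#' The anticodon family ("isoacceptor") of a tRNA id
#' @param id tRNA id(s) like `"Gly-GCC-2"`.
#' @return e.g. `"Gly-GCC"`.
#' @export
anticodon_family <- function(id) {
  vapply(strsplit(id, "-"), function(p)
    paste(p[seq_len(min(2L, length(p)))], collapse = "-"), character(1))
}

#' Load reference transcripts from FASTA files
#'
#' Sequences are normalized to the RNA alphabet. tRNA entries are annotated
#' with the cloverleaf template (or per-id intervals supplied in
#' `cloverleaf_annotations`) and checked for anticodon consistency with
#' their ids.
#'
#' @param fasta_paths named character vector of FASTA paths; names are
#'   biotypes (`trna`, `rrna`, `snorna`, `mrna`, `other`). A path may be
#'   repeated under different biotypes.
#' @param cloverleaf_annotations optional named list (by tRNA id) of
#'   precomputed cloverleaf interval lists.
#' @return a `reference_set`: list with `trnas` (list of [trna_record]),
#'   `seqs` (id -> sequence for the non-tRNA biotypes), `biotype`
#'   (id -> biotype for every id), `lengths` (id -> declared length).
#' @export
load_references <- function(fasta_paths, cloverleaf_annotations = NULL) {
  if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths))))
    stopf("fasta_paths must be named by biotype")
  trnas <- list(); seqs <- character(0); biotype <- character(0)
  for (bt in names(fasta_paths)) {
    ss <- Biostrings::readBStringSet(fasta_paths[[bt]])
    ids <- sub("\\s.*$", "", names(ss))
    sq <- unname(as_rna(as.character(ss)))
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (id %in% c(names(seqs), vapply(trnas, `[[`, "", "id")))
        stopf("duplicate reference id: %s", id)
      if (bt == "trna") {
        trnas[[length(trnas) + 1L]] <-
          trna_record(id, sq[i], cloverleaf = cloverleaf_annotations[[id]])
      } else {
        seqs[id] <- sq[i]
      }
      biotype[id] <- bt
    }
  }
  reference_set(trnas, seqs, biotype)
}

#' Construct and validate a reference set
#'
#' @param trnas list of [trna_record].
#' @param seqs named character vector: id -> sequence for non-tRNA biotypes.
#' @param biotype named character vector: id -> biotype for every id.
#' @param declared_lengths optional named integer vector; when given, each
#'   sequence must have exactly this length (used for the rRNA set, e.g.
#'   28S 5070 nt, 18S 1869 nt, 5.8S 156 nt in the human set).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(trnas, seqs = character(0), biotype = character(0),
                          declared_lengths = NULL) {
  ids <- c(vapply(trnas, `[[`, "", "id"), names(seqs))
  if (anyDuplicated(ids)) stopf("duplicate reference ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(ids %in% names(biotype))) stopf("every id needs a biotype")
  if (!is.null(declared_lengths)) {
    for (id in names(declared_lengths)) {
      got <- if (id %in% names(seqs)) nchar(seqs[[id]]) else NA_integer_
      if (!identical(as.integer(got), as.integer(declared_lengths[[id]])))
        stopf("declared length of %s is %d but sequence has %s nt",
              id, declared_lengths[[id]], got)
    }
  }
  structure(list(trnas = trnas, seqs = seqs, biotype = biotype,
                 declared_lengths = declared_lengths),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference set: %d tRNAs, %d other transcripts (%s)\n",
              length(x$trnas), length(x$seqs),
              paste(names(table(x$biotype)), table(x$biotype),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

# sequence of any reference id (tRNA: CCA-appended shadow used for matching)
ref_sequence <- function(refs, id, cca = TRUE) {
  for (t in refs$trnas) if (t$id == id) return(if (cca) t$cca_appended else t$sequence)
  if (id %in% names(refs$seqs)) return(refs$seqs[[id]])
  stopf("unknown reference id: %s", id)
}

trna_by_id <- function(refs, id) {
  for (t in refs$trnas) if (t$id == id) return(t)
  stopf("no tRNA record with id %s", id)
}

#' The packaged human tRNA references
#'
#' Mature sequences (no CCA) of the four tRNAs probed throughout:
#' Gly-GCC (isodecoder 2), Glu-CTC, Lys-TTT and iMet-CAT.
#'
#' @return a `reference_set` containing only tRNAs.
#' @export
packaged_trnas <- function() {
  fa <- system.file("extdata", "trna_human4.fa", package = "exrna")
  load_references(c(trna = fa))
}

#' Predict single-strand-specific ribonuclease cleavage sites in a tRNA
#'
#' RNase A-family chemistry: the phosphodiester bond 3' of a pyrimidine is
#' cut. Within each occurrence of each motif that overlaps the requested
#' single-stranded regions, one site is emitted per cytosine, cut 3' of that
#' C (scission after each of the two Cs of CpCpA / CpCpU). With
#' `motifs = NULL` every loop C is a site (used by the degradation
#' simulator). A cut whose scission point touches a loop boundary is kept:
#' terminal stem pairs fray.
#'
#' @param t a [trna_record] with a cloverleaf annotation.
#' @param motifs character vector of trinucleotide motifs (default the
#'   anticodon-loop motifs `CCA` and `CCU`), or `NULL` for every C in the
#'   regions.
#' @param regions `"loops"` (D-, anticodon-, T-loop) or `"all_ss"` (loops
#'   plus the unpaired 3' discriminator-adjacent stretch).
#' @return `data.frame` of class `cleavage_sites`: `parent_id`, `cut_after`
#'   (0-based, scission between `cut_after` and `cut_after + 1`), `motif`,
#'   `loop`, `five_prime_len` (= `cut_after + 1`).
#' @export
predict_cleavage_sites <- function(t, motifs = c("CCA", "CCU"),
                                   regions = c("loops", "all_ss")) {
  stopifnot(inherits(t, "trna_record"))
  regions <- match.arg(regions)
  if (is.null(t$cloverleaf)) stopf("tRNA %s has no cloverleaf annotation", t$id)
  s <- strsplit(t$sequence, "")[[1]]
  n <- length(s)
  cl <- t$cloverleaf
  loops <- list(d_loop = cl$d_loop, anticodon_loop = cl$anticodon_loop,
                t_loop = cl$t_loop)
  loops <- loops[!vapply(loops, is.null, logical(1))]
  if (regions == "all_ss")
    loops$acceptor_tail <- c(n - 1L, n)  # unpaired discriminator base

  in_region <- function(pos0) {
    # which loop contains (or abuts, within one fraying position) pos0
    for (nm in names(loops)) {
      iv <- loops[[nm]]
      if (pos0 >= iv[1] - 1L && pos0 < iv[2] + 1L) return(nm)
    }
    NA_character_
  }

  rows <- list()
  emit <- function(cut0, motif, loop) {
    if (cut0 >= n - 1L) return()  # products must tile the body: no terminal cut
    rows[[length(rows) + 1L]] <<- data.frame(
      parent_id = t$id, cut_after = cut0, motif = motif, loop = loop,
      five_prime_len = cut0 + 1L)
  }

  if (is.null(motifs)) {
    for (nm in names(loops)) {
      iv <- loops[[nm]]
      for (pos0 in max(iv[1] - 1L, 0L):min(iv[2], n - 1L))
        if (s[pos0 + 1L] == "C") emit(pos0, sprintf("C@%d", pos0 + 1L), nm)
    }
  } else {
    motifs <- as_rna(motifs)
    for (m in motifs) {
      mlen <- nchar(m)
      hits <- gregexpr(m, t$sequence, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      for (h in hits) {
        h0 <- h - 1L  # 0-based motif start
        # motif must overlap a single-stranded region
        loop <- NA_character_
        for (nm in names(loops)) {
          iv <- loops[[nm]]
          if (h0 < iv[2] && h0 + mlen > iv[1]) { loop <- nm; break }
        }
        if (is.na(loop)) next
        mchars <- strsplit(m, "")[[1]]
        for (k in which(mchars == "C")) {
          cut0 <- h0 + k - 1L
          if (!is.na(in_region(cut0))) emit(cut0, m, loop)
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(parent_id = character(0), cut_after = integer(0),
                      motif = character(0), loop = character(0),
                      five_prime_len = integer(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out$cut_after), , drop = FALSE]
    out <- out[order(out$cut_after), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

#' Extract a cleavage product
#'
#' @param t a [trna_record].
#' @param site one row of a `cleavage_sites` table (or a list with
#'   `cut_after`).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param cca whether the 3' product carries the nontemplated CCA
#'   (mature-tRNA matching coordinates).
#' @return product sequence (RNA alphabet).
#' @export
fragment_from_cut <- function(t, site, side = c("five_prime", "three_prime"),
                              cca = TRUE) {
  side <- match.arg(side)
  cut0 <- site$cut_after
  n <- nchar(t$sequence)
  if (cut0 < 0 || cut0 >= n) stopf("cut_after %d outside body of %s", cut0, t$id)
  if (side == "five_prime") substr(t$sequence, 1L, cut0 + 1L)
  else substr(if (cca) t$cca_appended else t$sequence, cut0 + 2L,
              nchar(if (cca) t$cca_appended else t$sequence))
}

#' Write a cleavage-site table as TSV (1-based positions in the report)
#' @param sites a `cleavage_sites` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cleavage_sites <- function(sites, path) {
  rep <- data.frame(parent_id = sites$parent_id,
                    cut_after_1based = sites$cut_after + 1L,
                    motif = sites$motif, loop = sites$loop,
                    five_prime_len = sites$five_prime_len)
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
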