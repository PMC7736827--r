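# Synthetic-data generator: extracellular RNA release, progressive
# single-strand-specific ribonuclease fragmentation, labelled synthetic
# reads and synthetic chromatograms.
#
# The kinetic model is a discrete-copy stochastic simulation. Cells release
# a small fraction (~0.3%) of their RNA as full-length molecules; an
# extracellular RNase activity then cuts molecules at cytosines in
# single-stranded positions: full-length tRNAs only at loop cytosines
# (stems are paired), fragments and long RNAs at every cytosine.
# Dimer-capable tRNA-derived fragments (the 30-31 nt short tRNA halves) are
# exempt from cleavage; duplex protection of rRNA fragments is out of this
# model's scope. RNase-inhibitor (RI) conditions set the activity to zero;
# endogenous secreted RNases are slow; serum RNase A is fast. Copy/nt
# bookkeeping is exact: every nucleotide is in a surviving molecule or in
# the degraded sink.

#' Simulation configuration
#'
#' @param species data.frame with columns `id`, `biotype`,
#'   `cellular_copies`, and optionally `hazard_mult` (per-species
#'   susceptibility multiplier, default 1). Defaults to
#'   [default_species_table()].
#' @param release_fraction fraction of cellular RNA released per wash
#'   (default 0.003; plausible washes release 0.1-0.5%).
#' @param activity_levels named numeric: RNase hazard scale per site per
#'   hour for the `ri`, `endogenous` and `serum` conditions. RI is modelled
#'   as complete inhibition (0).
#' @param level which activity level to run.
#' @param ri_enabled overrides `level` to `ri` when TRUE.
#' @param duration_h total simulated time (h).
#' @param dt_h step size (h).
#' @param timepoints times (h) at which the pool is recorded.
#' @param s_half_route how short (30-31 nt) 5' halves arise from long
#'   (33-35 nt) halves: `"direct_cleavage"` (cytosine cuts only),
#'   `"trimming"` (exonucleolytic 3' trimming of L to S) or `"both"`.
#' @param trim_factor trimming hazard relative to the per-site cleavage
#'   hazard.
#' @param error_rate per-base substitution rate of emitted reads.
#' @param depth reads emitted per sequencing call.
#' @param fragment_mrnas fragment released mRNAs uniformly at random
#'   (random-fragmentation assumption for mRNA profiling).
#' @param mrna_break_rate per-bond break probability for released mRNAs.
#' @param protect_max_len longest fragment tested for dimer capability.
#' @param seed integer seed (mandatory for reproducibility; default 42).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species = default_species_table(),
                       release_fraction = 0.003,
                       activity_levels = c(ri = 0, endogenous = 0.05, serum = 2.0),
                       level = c("endogenous", "ri", "serum"),
                       ri_enabled = FALSE,
                       duration_h = 1, dt_h = 1,
                       timepoints = NULL,
                       s_half_route = c("both", "direct_cleavage", "trimming"),
                       trim_factor = 1,
                       error_rate = 0,
                       depth = 1e5,
                       fragment_mrnas = TRUE,
                       mrna_break_rate = 1 / 300,
                       protect_max_len = 40L,
                       seed = 42L) {
  level <- match.arg(level)
  s_half_route <- match.arg(s_half_route)
  if (ri_enabled) level <- "ri"
  if (release_fraction < 0 || release_fraction > 0.005)
    stopf("release_fraction %.4f outside the plausible wash range (0, 0.005]",
          release_fraction)
  if (any(activity_levels < 0)) stopf("hazards must be >= 0")
  if (is.null(species$hazard_mult)) species$hazard_mult <- 1
  if (is.null(timepoints)) timepoints <- unique(c(0, duration_h))
  structure(list(species = species, release_fraction = release_fraction,
                 activity_levels = activity_levels, level = level,
                 duration_h = duration_h, dt_h = dt_h,
                 timepoints = sort(unique(timepoints)),
                 s_half_route = s_half_route, trim_factor = trim_factor,
                 error_rate = error_rate, depth = depth,
                 fragment_mrnas = fragment_mrnas,
                 mrna_break_rate = mrna_break_rate,
                 protect_max_len = as.integer(protect_max_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated species: the packaged tRNAs, the synthetic rRNA set,
#' two snoRNAs and eight mRNAs
#'
#' Copy numbers are a desk-scale caricature of a mammalian cytoplasm:
#' tRNAs most abundant, ribosomes (equimolar rRNAs) next, mRNAs sparse.
#'
#' @return data.frame with `id`, `biotype`, `cellular_copies`.
#' @export
default_species_table <- function() {
  rbind(
    data.frame(id = c("Gly-GCC-2", "Glu-CTC-1", "Lys-TTT-3", "iMet-CAT-1"),
               biotype = "trna",
               cellular_copies = c(200000, 150000, 100000, 50000)),
    data.frame(id = c("28S", "18S", "5.8S"), biotype = "rrna",
               cellular_copies = 40000),
    data.frame(id = c("SNORD-A", "SNORD-B"), biotype = "snorna",
               cellular_copies = 10000),
    data.frame(id = paste0("MRNA-", 1:8), biotype = "mrna",
               cellular_copies = round(12000 * 0.6 ^ (0:7)))
  )
}

#' Synthetic reference set for simulation and testing
#'
#' The four packaged human tRNAs plus seeded random-sequence stand-ins for
#' the rRNAs (at the declared human lengths: 28S 5070 nt, 18S 1869 nt,
#' 5.8S 156 nt), two snoRNAs and eight mRNAs. The non-tRNA sequences are
#' synthetic: reproducible surrogates, not the real transcripts.
#'
#' @param seed seed for the synthetic sequences (fixed default so every
#'   session sees the same references).
#' @param mrna_lengths lengths of the synthetic mRNAs.
#' @return a `reference_set`.
#' @export
synthetic_reference_set <- function(seed = 1234L,
                                    mrna_lengths = c(2200, 1800, 1500, 1200,
                                                     1000, 800, 650, 500)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
                                  prob = c(0.26, 0.24, 0.27, 0.23)),
                           collapse = "")
  seqs <- c(`28S` = rnd(5070), `18S` = rnd(1869), `5.8S` = rnd(156),
            `SNORD-A` = rnd(95), `SNORD-B` = rnd(120))
  for (i in seq_along(mrna_lengths))
    seqs[paste0("MRNA-", i)] <- rnd(mrna_lengths[i])
  biotype <- c(rep("rrna", 3), rep("snorna", 2), rep("mrna", length(mrna_lengths)))
  names(biotype) <- names(seqs)
  trnas <- packaged_trnas()$trnas
  for (t in trnas) biotype[t$id] <- "trna"
  reference_set(trnas, seqs, biotype,
                declared_lengths = c(`28S` = 5070L, `18S` = 1869L, `5.8S` = 156L))
}

# ---- internal pool machinery -------------------------------------------

# per-parent lookup tables used by the stepper
pool_index <- function(refs, config) {
  ids <- c(vapply(refs$trnas, `[[`, "", "id"), names(refs$seqs))
  idx <- new.env(parent = emptyenv())
  mult <- stats::setNames(config$species$hazard_mult, config$species$id)
  for (id in ids) {
    bt <- refs$biotype[[id]]
    seq <- ref_sequence(refs, id, cca = TRUE)  # appended axis for tRNA
    chars <- strsplit(seq, "")[[1]]
    cpos0 <- which(chars == "C") - 1L          # 0-based C positions
    cum <- c(0L, cumsum(chars == "C"))         # cum[k+1] = #C in first k nt
    full_sites <- NULL
    if (bt == "trna") {
      t <- trna_by_id(refs, id)
      if (!is.null(t$cloverleaf))
        full_sites <- predict_cleavage_sites(t, motifs = NULL)$cut_after
    }
    assign(id, list(seq = seq, len = nchar(seq), cpos0 = cpos0, cum = cum,
                    full_sites = full_sites, biotype = bt,
                    mult = if (id %in% names(mult)) mult[[id]] else 1),
           envir = idx)
  }
  idx
}

new_pool <- function(molecules, time = 0, sink_nt = 0) {
  structure(list(time = time, molecules = molecules, sink_nt = sink_nt),
            class = "molecule_pool")
}

#' @export
print.molecule_pool <- function(x, ...) {
  m <- x$molecules
  cat(sprintf("molecule pool at t = %g h: %d species rows, %g copies, %g nt (+%g nt degraded)\n",
              x$time, nrow(m), sum(m$copies), sum(m$copies * (m$end - m$start)),
              x$sink_nt))
  invisible(x)
}

#' Total nucleotide mass of a pool (surviving + degraded sink)
#' @param pool a `molecule_pool`.
#' @return list with `surviving_nt`, `sink_nt`, `total_nt`.
#' @export
pool_mass <- function(pool) {
  m <- pool$molecules
  s <- sum(m$copies * (m$end - m$start))
  list(surviving_nt = s, sink_nt = pool$sink_nt, total_nt = s + pool$sink_nt)
}

aggregate_pool <- function(m) {
  if (!nrow(m)) return(m)
  key <- paste(m$parent_id, m$start, m$end, sep = "\r")
  cp <- rowsum(m$copies, key)
  first <- m[!duplicated(key), , drop = FALSE]
  first$copies <- as.numeric(cp[match(paste(first$parent_id, first$start,
                                            first$end, sep = "\r"),
                                      rownames(cp))])
  first <- first[first$copies > 0, , drop = FALSE]
  rownames(first) <- NULL
  first
}

molecule_row <- function(parent_id, biotype, start, end, copies, protected) {
  data.frame(parent_id = parent_id, biotype = biotype,
             start = as.integer(start), end = as.integer(end),
             copies = as.numeric(copies), protected = protected)
}

# dimer-capability cache: homodimer capability per fragment sequence
protection_cache <- new.env(parent = emptyenv())

is_protected_seq <- function(seq, protect_max_len) {
  n <- nchar(seq)
  if (n < 18L || n > protect_max_len) return(FALSE)
  hit <- get0(seq, envir = protection_cache)
  if (!is.null(hit)) return(hit)
  val <- duplex_score(seq, seq)$dimer_capable
  assign(seq, val, envir = protection_cache)
  val
}

#' Release full-length RNA into the extracellular pool
#'
#' Each species releases `Binomial(cellular_copies, release_fraction)`
#' full-length copies (tRNAs with their mature CCA). Released mRNAs are
#' optionally fragmented uniformly at random, emulating the random
#' fragmentation assumed when profiling extracellular mRNA.
#'
#' @param config a [sim_config].
#' @param refs a `reference_set` (default [synthetic_reference_set()]).
#' @return a `molecule_pool` at t = 0.
#' @export
simulate_release <- function(config, refs = synthetic_reference_set()) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    id <- sp$id[i]; bt <- sp$biotype[i]
    seq <- ref_sequence(refs, id, cca = TRUE)
    len <- nchar(seq)
    k <- stats::rbinom(1L, sp$cellular_copies[i], config$release_fraction)
    if (k == 0L) next
    if (bt == "mrna" && config$fragment_mrnas) {
      for (cp in seq_len(k)) {
        nb <- stats::rbinom(1L, len - 1L, config$mrna_break_rate)
        cuts <- sort(sample.int(len - 1L, nb))
        bounds <- c(0L, cuts, len)
        for (j in seq_len(length(bounds) - 1L)) {
          s0 <- bounds[j]; e0 <- bounds[j + 1L]
          if (e0 - s0 >= 15L)
            rows[[length(rows) + 1L]] <- molecule_row(id, bt, s0, e0, 1, FALSE)
        }
      }
    } else {
      rows[[length(rows) + 1L]] <- molecule_row(id, bt, 0L, len, k, FALSE)
    }
  }
  m <- if (length(rows)) aggregate_pool(do.call(rbind, rows))
       else molecule_row(character(0), character(0), integer(0), integer(0),
                         numeric(0), logical(0))
  pool <- new_pool(m, time = 0)
  attr(pool, "released_nt") <- pool_mass(pool)$surviving_nt
  pool
}

#' Advance the degradation model by one time step
#'
#' Per molecule copy, a first-event competing-risk draw over its cleavage
#' sites (and, for long 5' halves, the trimming route): event probability
#' `1 - exp(-(H_cut + H_trim) dt)` with `H_cut = activity x mult x n_sites`.
#' Full-length tRNAs expose only loop cytosines (cloverleaf stems are
#' paired); every other molecule exposes all its cytosines. Dimer-protected
#' molecules are exempt. Products shorter than 15 nt move to the degraded
#' sink; nucleotide bookkeeping is exact.
#'
#' @param pool a `molecule_pool`.
#' @param dt time step (h).
#' @param config a [sim_config].
#' @param refs the `reference_set` used at release.
#' @param index optional precomputed [pool_index()]-style lookup (internal
#'   reuse across steps).
#' @return the advanced `molecule_pool`.
#' @export
step_degradation <- function(pool, dt, config, refs, index = NULL) {
  stopifnot(inherits(pool, "molecule_pool"), dt > 0)
  if (is.null(index)) index <- pool_index(refs, config)
  act <- config$activity_levels[[config$level]]
  m <- pool$molecules
  sink <- pool$sink_nt
  if (!nrow(m) || act == 0)
    return(new_pool(m, pool$time + dt, sink))

  n <- nrow(m)
  info <- lapply(m$parent_id, get, envir = index)
  pseq <- vapply(info, `[[`, "", "seq")
  len <- m$end - m$start
  is_full_trna <- m$biotype == "trna" & m$start == 0L &
    m$end == vapply(info, `[[`, 0L, "len")

  nsites <- integer(n); site_pool <- vector("list", n)
  for (i in seq_len(n)) {
    if (m$protected[i]) { nsites[i] <- 0L; next }
    if (is_full_trna[i] && !is.null(info[[i]]$full_sites)) {
      site_pool[[i]] <- info[[i]]$full_sites
    } else {
      # interior cytosine cuts: positions p in [start, end-2]
      cum <- info[[i]]$cum
      a <- cum[m$start[i] + 1L]; b <- cum[m$end[i]]  # Cs in [start, end-1)
      if (b > a) site_pool[[i]] <- info[[i]]$cpos0[(a + 1L):b]
    }
    nsites[i] <- length(site_pool[[i]])
  }

  mult <- vapply(info, `[[`, 0, "mult")
  h_cut <- act * mult * nsites
  trim_on <- config$s_half_route %in% c("both", "trimming")
  is_L <- m$biotype == "trna" & m$start <= 1L & len >= 33 & len <= 35 &
    !m$protected
  h_trim <- ifelse(trim_on & is_L, act * mult * config$trim_factor, 0)
  h_tot <- h_cut + h_trim
  p_evt <- 1 - exp(-h_tot * dt)
  k <- stats::rbinom(n, m$copies, p_evt)
  m$copies <- m$copies - k
  ktrim <- ifelse(h_tot > 0 & k > 0L,
                  stats::rbinom(n, k, ifelse(h_tot > 0, h_trim / h_tot, 0)), 0L)
  kcut <- k - ktrim

  prods <- list()
  add_products <- function(row_idx, s0, e0, kk) {
    # event-level vectors -> aggregated product rows; short products sink
    plen <- e0 - s0
    short <- plen < 15L
    sink <<- sink + sum(kk[short] * plen[short])
    keep <- !short
    if (!any(keep)) return()
    row_idx <- row_idx[keep]; s0 <- s0[keep]; e0 <- e0[keep]; kk <- kk[keep]
    key <- paste(row_idx, s0, e0)
    first <- !duplicated(key)
    rs <- rowsum(kk, key)
    tot <- rs[key[first], 1L]
    ri <- row_idx[first]; s0 <- s0[first]; e0 <- e0[first]
    bt <- m$biotype[ri]
    prot <- logical(length(ri))
    cand <- which(bt == "trna" & (e0 - s0) >= 18L &
                    (e0 - s0) <= config$protect_max_len)
    if (length(cand)) {
      sq <- substr(pseq[ri[cand]], s0[cand] + 1L, e0[cand])
      prot[cand] <- vapply(sq, is_protected_seq, logical(1),
                           protect_max_len = config$protect_max_len,
                           USE.NAMES = FALSE)
    }
    prods[[length(prods) + 1L]] <<-
      molecule_row(m$parent_id[ri], bt, s0, e0, tot, prot)
  }

  # trimming events: L (33-35 nt, 5'-anchored) -> S of 30 or 31 nt
  ti <- which(ktrim > 0L)
  if (length(ti)) {
    erow <- rep(ti, ktrim[ti])
    newlen <- sample(c(30L, 31L), length(erow), replace = TRUE)
    sink <- sink + sum(len[erow] - newlen)
    add_products(erow, m$start[erow], m$start[erow] + newlen,
                 rep(1L, length(erow)))
  }

  # cleavage events: one uniformly drawn cytosine site per event
  ci <- which(kcut > 0L)
  if (length(ci)) {
    erow <- rep(ci, kcut[ci])
    pick <- floor(stats::runif(length(erow)) * nsites[erow]) + 1L
    cut0 <- vapply(seq_along(erow), function(e)
      site_pool[[erow[e]]][pick[e]], integer(1))
    one <- rep(1L, length(erow))
    add_products(erow, m$start[erow], cut0 + 1L, one)   # 5' products
    add_products(erow, cut0 + 1L, m$end[erow], one)     # 3' products
  }

  m <- m[m$copies > 0, , drop = FALSE]
  if (length(prods)) m <- aggregate_pool(rbind(m, do.call(rbind, prods)))
  new_pool(m, pool$time + dt, sink)
}

#' Run a full release + degradation scenario
#'
#' Presets named after the wet protocols they emulate:
#' `wash_ri` (short wash, RI added: no degradation), `its_1h` (1 h in
#' serum-free medium, endogenous RNases), `serum_24h` (24 h with serum-level
#' RNase A activity) and `cf_24h` (cell-free maturation: 24 h of endogenous
#' activity, no further release).
#'
#' @param preset one of `"wash_ri"`, `"its_1h"`, `"serum_24h"`, `"cf_24h"`.
#' @param seed seed (overrides the config default).
#' @param refs a `reference_set`.
#' @param config optional [sim_config] to use instead of the preset's.
#' @param timepoints pool-recording times (h); defaults per preset.
#' @return list with `config`, `refs`, `pools` (named by time), `final`
#'   (the last pool).
#' @export
run_scenario <- function(preset = c("serum_24h", "wash_ri", "its_1h", "cf_24h"),
                         seed = NULL, refs = synthetic_reference_set(),
                         config = NULL, timepoints = NULL) {
  preset <- match.arg(preset)
  if (is.null(config)) {
    config <- switch(preset,
      wash_ri = sim_config(ri_enabled = TRUE, duration_h = 1,
                           timepoints = timepoints %||% c(0, 1)),
      its_1h = sim_config(level = "endogenous", duration_h = 1,
                          timepoints = timepoints %||% c(0, 1)),
      serum_24h = sim_config(level = "serum", duration_h = 24,
                             timepoints = timepoints %||% c(0, 1, 2, 6, 12, 24)),
      cf_24h = sim_config(level = "endogenous", duration_h = 24,
                          timepoints = timepoints %||% c(0, 6, 12, 24)))
  } else if (!is.null(timepoints)) {
    config$timepoints <- sort(unique(timepoints))
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  index <- pool_index(refs, config)
  pool <- simulate_release(config, refs)
  pools <- list()
  if (0 %in% config$timepoints) pools[["0"]] <- pool
  t <- 0
  while (t < config$duration_h - 1e-9) {
    dt <- min(config$dt_h, config$duration_h - t)
    pool <- step_degradation(pool, dt, config, refs, index)
    t <- t + dt
    hit <- config$timepoints[abs(config$timepoints - t) < 1e-9]
    if (length(hit)) pools[[as.character(hit[1])]] <- pool
  }
  list(config = config, refs = refs, pools = pools, final = pool)
}

#' Emit sequencing reads (with truth labels) from a molecule pool
#'
#' Reads are drawn multinomially by copy number; per-base substitution
#' errors are applied at `error_rate`. Truth labels carry the parent,
#' interval and taxonomy class of the molecule each read came from.
#'
#' @param pool a `molecule_pool`.
#' @param refs the `reference_set`.
#' @param depth number of reads.
#' @param error_rate per-base substitution probability.
#' @param max_read_len sequencer read length (default 200, as in a
#'   200-cycle run): molecules longer than this yield a 5'-anchored
#'   truncated read, and the truth interval is the read's actual interval.
#' @param seed optional seed (set by the caller otherwise).
#' @param fastq,truth_tsv optional output paths; written when given.
#' @return list with `reads` (a [read_set]) and `truth` (data.frame `seq`,
#'   `count`, `parent_id`, `family`, `biotype`, `start`, `end`,
#'   `taxonomy_class`).
#' @export
emit_reads <- function(pool, refs, depth = 1e5, error_rate = 0, seed = NULL,
                       max_read_len = 200L, fastq = NULL, truth_tsv = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- pool$molecules
  if (!nrow(m) || sum(m$copies) == 0) stopf("empty pool: nothing to sequence")
  m$end <- pmin(m$end, m$start + as.integer(max_read_len))
  draw <- as.integer(stats::rmultinom(1L, depth, m$copies))
  rows <- which(draw > 0L)
  bodylen <- vapply(rows, function(i)
    if (m$biotype[i] == "trna") nchar(ref_sequence(refs, m$parent_id[i], cca = FALSE))
    else NA_integer_, integer(1))
  base_seq <- vapply(rows, function(i)
    substr(ref_sequence(refs, m$parent_id[i], cca = TRUE),
           m$start[i] + 1L, m$end[i]), character(1))
  cls <- vapply(seq_along(rows), function(j) {
    i <- rows[j]
    if (m$biotype[i] == "trna") classify_interval(m$start[i], m$end[i], bodylen[j])
    else "INTERNAL"
  }, character(1))

  fam <- ifelse(m$biotype[rows] == "trna",
                anticodon_family(m$parent_id[rows]), m$parent_id[rows])
  if (error_rate == 0) {
    truth <- data.frame(seq = base_seq, count = draw[rows],
                        parent_id = m$parent_id[rows], family = fam,
                        biotype = m$biotype[rows],
                        start = m$start[rows], end = m$end[rows],
                        taxonomy_class = cls)
  } else {
    seq_l <- vector("list", length(rows)); cnt_l <- vector("list", length(rows))
    for (j in seq_along(rows)) {
      kk <- draw[rows[j]]; sq <- base_seq[j]; L <- nchar(sq)
      nerr <- stats::rbinom(kk, L, error_rate)
      out_seqs <- character(0); out_cnts <- integer(0)
      k_clean <- sum(nerr == 0L)
      if (k_clean > 0L) { out_seqs <- sq; out_cnts <- k_clean }
      for (e in which(nerr > 0L)) {
        ch <- strsplit(sq, "")[[1]]
        pos <- sample.int(L, nerr[e])
        for (p in pos)
          ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
        out_seqs <- c(out_seqs, paste(ch, collapse = ""))
        out_cnts <- c(out_cnts, 1L)
      }
      seq_l[[j]] <- out_seqs; cnt_l[[j]] <- out_cnts
    }
    nvar <- lengths(seq_l)
    truth <- data.frame(seq = unlist(seq_l), count = unlist(cnt_l),
                        parent_id = rep(m$parent_id[rows], nvar),
                        family = rep(fam, nvar),
                        biotype = rep(m$biotype[rows], nvar),
                        start = rep(m$start[rows], nvar),
                        end = rep(m$end[rows], nvar),
                        taxonomy_class = rep(cls, nvar))
  }
  rownames(truth) <- NULL
  reads <- read_set(truth$seq, truth$count)

  if (!is.null(fastq)) {
    idx <- rep(seq_len(nrow(truth)), truth$count)
    nm <- sprintf("@read_%07d", seq_along(idx))
    sq <- as_dna(truth$seq[idx])
    con <- file(fastq, "w")
    writeLines(paste(nm, sq, "+", strrep("I", nchar(sq)), sep = "\n"), con)
    close(con)
  }
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(reads = reads, truth = truth)
}

#' Render a molecule pool as a synthetic SEC chromatogram
#'
#' Species are mapped to elution centers by hydrodynamic size:
#' ribosome-scale RNA (>= 1000 nt) to the void peak (7.5 ml), full-length
#' tRNAs and duplex-protected fragments to 15.0 ml, monomeric short ssRNA
#' to 16.5 ml; an optional BSA amount elutes at 13.0 ml. Peaks are
#' Gaussian; channel amplitudes follow the pure-component 260/280 ratios,
#' so the trace round-trips through [unmix()] and [quantify_rna()].
#'
#' @param pool a `molecule_pool`.
#' @param refs the `reference_set` (unused beyond interface symmetry).
#' @param refs_ratios a [reference_ratios].
#' @param ug_per_nt_copy mass scale: micrograms per nucleotide-copy.
#' @param sigma_ml Gaussian peak width (ml).
#' @param grid elution-volume grid (ml).
#' @param bsa_ug protein amount eluting at the BSA position.
#' @param centers named centers (ml) for the `P0`, `BSA`, `P1`, `P2` classes.
#' @return a [chromatogram]; attribute `injected_rna_ug` holds the true
#'   RNA mass per center (named numeric).
#' @export
emit_chromatogram <- function(pool, refs = NULL,
                              refs_ratios = reference_ratios(),
                              ug_per_nt_copy = 2e-5, sigma_ml = 0.25,
                              grid = seq(4, 20, by = 0.02), bsa_ug = 0,
                              centers = c(P0 = 7.5, BSA = 13.0, P1 = 15.0,
                                          P2 = 16.5)) {
  m <- pool$molecules
  len <- m$end - m$start
  center_of <- ifelse(len >= 1000, centers[["P0"]],
                      ifelse(m$protected | len >= 60, centers[["P1"]],
                             centers[["P2"]]))
  mass <- m$copies * len * ug_per_nt_copy
  rna_ug <- tapply(mass, center_of, sum)
  a260 <- numeric(length(grid)); a280 <- numeric(length(grid))
  for (cn in names(rna_ug)) {
    c0 <- as.numeric(cn)
    area <- rna_ug[[cn]] * refs_ratios$ext260_rna  # AU.ml at 260 nm
    a260 <- a260 + area * stats::dnorm(grid, c0, sigma_ml)
  }
  a280 <- a260 / refs_ratios$ratio_rna
  if (bsa_ug > 0) {
    area280 <- bsa_ug * refs_ratios$ext260_protein / refs_ratios$ratio_protein
    prot280 <- area280 * stats::dnorm(grid, centers[["BSA"]], sigma_ml)
    a280 <- a280 + prot280
    a260 <- a260 + prot280 * refs_ratios$ratio_protein
  }
  out <- chromatogram(grid, a260, a280,
                      meta = sprintf("synthetic chromatogram at t = %g h", pool$time))
  inj <- as.numeric(rna_ug); names(inj) <- names(rna_ug)
  attr(out, "injected_rna_ug") <- inj
  out
}
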