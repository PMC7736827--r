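# Release and degradation kinetics, read emission, synthetic chromatograms.

test_that("release draws the configured fraction of cellular RNA", {
  cfg <- sim_config(release_fraction = 0, seed = 1)
  expect_equal(nrow(simulate_release(cfg, REFS)$molecules), 0L)
  expect_error(sim_config(release_fraction = 0.02), "plausible wash range")

  set.seed(2)
  cfg <- sim_config(release_fraction = 0.003, fragment_mrnas = FALSE, seed = 2)
  pool <- simulate_release(cfg, REFS)
  m <- pool$molecules
  # per species: released/cellular within 5 binomial standard errors
  sp <- cfg$species
  for (i in seq_len(nrow(sp))) {
    k <- sum(m$copies[m$parent_id == sp$id[i]])
    n <- sp$cellular_copies[i]
    se <- sqrt(n * 0.003 * 0.997)
    expect_lt(abs(k - n * 0.003), 5 * se + 1)
  }
  # full-length molecules, tRNAs on the CCA-appended axis
  gly <- m[m$parent_id == "Gly-GCC-2", ]
  expect_equal(gly$start, 0L)
  expect_equal(gly$end, nchar(GLY$sequence) + 3L)
})

test_that("RNase inhibition freezes the pool", {
  sc <- run_scenario("wash_ri", seed = 3)
  expect_identical(sc$pools[["0"]]$molecules, sc$final$molecules)
  expect_equal(sc$final$sink_nt, 0)
})

test_that("single-molecule cleavage matches the closed-form event probability", {
  # one species with a known cytosine count, one step of length dt
  seqs <- c(X = paste0(strrep("A", 10), strrep("C", 4), strrep("A", 10)))
  refs1 <- reference_set(list(), seqs, c(X = "mrna"))
  sp <- data.frame(id = "X", biotype = "mrna", cellular_copies = 1L)
  cfg <- sim_config(species = sp, level = "endogenous", fragment_mrnas = FALSE,
                    seed = 5)
  pool <- structure(list(time = 0,
                         molecules = data.frame(parent_id = "X", biotype = "mrna",
                                                start = 0L, end = 24L,
                                                copies = 1e5, protected = FALSE),
                         sink_nt = 0),
                    class = "molecule_pool")
  set.seed(5)
  dt <- 0.2
  stepped <- step_degradation(pool, dt, cfg, refs1)
  h <- cfg$activity_levels[["endogenous"]] * 4   # 4 cytosine sites
  p_true <- 1 - exp(-h * dt)
  p_obs <- 1 - sum(stepped$molecules$copies[stepped$molecules$start == 0L &
                                              stepped$molecules$end == 24L]) / 1e5
  expect_lt(abs(p_obs - p_true), 4 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("nucleotide mass is conserved exactly through degradation", {
  for (preset in c("serum_24h", "cf_24h")) {
    sc <- run_scenario(preset, seed = 7)
    released <- attr(sc$pools[["0"]], "released_nt")
    final <- pool_mass(sc$final)
    expect_equal(final$total_nt, released)
  }
})

test_that("serum exposure destroys full-length glycine tRNA and leaves only short 5' halves", {
  for (seed in 1:3) {
    sc <- run_scenario("serum_24h", seed = seed)
    m0 <- sc$pools[["0"]]$molecules
    mF <- sc$final$molecules
    app <- nchar(GLY$sequence) + 3L
    full0 <- sum(m0$copies[m0$parent_id == "Gly-GCC-2" & m0$start == 0 & m0$end == app])
    fullF <- sum(mF$copies[mF$parent_id == "Gly-GCC-2" & mF$start == 0 & mF$end == app])
    expect_lt(fullF, 0.01 * full0)
    # surviving 5'-anchored glycine fragments are all <= 31 nt
    g5 <- mF[mF$parent_id == "Gly-GCC-2" & mF$start <= 1, ]
    expect_true(all(g5$end - g5$start <= 31))
    expect_gt(sum(g5$copies[(g5$end - g5$start) %in% 30:31]), 0)
  }
})

test_that("with RI the modal tRNA read length is full length; in serum it is 30-31", {
  sc_ri <- run_scenario("wash_ri", seed = 11)
  em <- emit_reads(sc_ri$final, sc_ri$refs, depth = 2e4, error_rate = 0)
  ann <- match_reads(em$reads, sc_ri$refs)
  h <- size_distribution(ann, "trna")
  expect_gte(h$length[which.max(h$rpm)], 74L)

  sc_s <- run_scenario("serum_24h", seed = 11)
  em <- emit_reads(sc_s$final, sc_s$refs, depth = 2e4, error_rate = 0)
  ann <- match_reads(em$reads, sc_s$refs)
  h <- size_distribution(ann, "trna", family = "Gly-GCC",
                         classes = c("FIVE_HALF_S", "FIVE_HALF_L"))
  expect_true(h$length[which.max(h$rpm)] %in% 30:31)
})

test_that("per-species susceptibility reproduces the stability ordering", {
  # lower per-molecule hazard -> more surviving full-length, fewer
  # fragments; multipliers are per SITE, so normalize by each tRNA's
  # loop-cytosine count to set the per-molecule cleavability directly
  sp <- default_species_table()
  nsites <- vapply(sp$id, function(id) {
    if (sp$biotype[sp$id == id][1] != "trna") return(1)
    nrow(predict_cleavage_sites(exrna:::trna_by_id(REFS, id), motifs = NULL))
  }, numeric(1))
  weight <- c(`Lys-TTT-3` = 2, `iMet-CAT-1` = 4.5, `Gly-GCC-2` = 8)
  sp$hazard_mult <- ifelse(sp$id %in% names(weight),
                           weight[sp$id] / nsites, 1)
  cfg <- sim_config(species = sp, level = "endogenous", duration_h = 6,
                    timepoints = c(0, 6), seed = 13)
  sc <- run_scenario("cf_24h", config = cfg, seed = 13)
  m0 <- sc$pools[["0"]]$molecules; mF <- sc$final$molecules
  surv <- function(id) {
    app <- nchar(exrna:::trna_by_id(REFS, id)$sequence) + 3L
    f0 <- sum(m0$copies[m0$parent_id == id & m0$start == 0 & m0$end == app])
    sum(mF$copies[mF$parent_id == id & mF$start == 0 & mF$end == app]) / f0
  }
  s <- vapply(c("Lys-TTT-3", "iMet-CAT-1", "Gly-GCC-2"), surv, numeric(1))
  expect_true(s[["Lys-TTT-3"]] > s[["iMet-CAT-1"]])
  expect_true(s[["iMet-CAT-1"]] > s[["Gly-GCC-2"]])

  frag <- function(id) {
    sum(mF$copies[mF$parent_id == id]) - {
      app <- nchar(exrna:::trna_by_id(REFS, id)$sequence) + 3L
      sum(mF$copies[mF$parent_id == id & mF$start == 0 & mF$end == app])
    }
  }
  f <- vapply(c("Lys-TTT-3", "iMet-CAT-1", "Gly-GCC-2"), frag, numeric(1))
  # fragment yield relative to release is inverse to stability
  rel0 <- vapply(c("Lys-TTT-3", "iMet-CAT-1", "Gly-GCC-2"), function(id)
    sum(m0$copies[m0$parent_id == id]), numeric(1))
  fy <- f / rel0
  expect_true(fy[["Lys-TTT-3"]] < fy[["iMet-CAT-1"]])
  expect_true(fy[["iMet-CAT-1"]] < fy[["Gly-GCC-2"]])
})

test_that("read emission is multinomial, error-free by default, and seeded", {
  sc <- run_scenario("its_1h", seed = 17)
  em <- emit_reads(sc$final, sc$refs, depth = 1e4, error_rate = 0, seed = 18)
  # every read is a verbatim pool molecule subsequence
  mol_seqs <- unique(vapply(seq_len(nrow(sc$final$molecules)), function(i) {
    m <- sc$final$molecules[i, ]
    substr(exrna:::ref_sequence(sc$refs, m$parent_id), m$start + 1L,
           min(m$end, m$start + 200L))
  }, character(1)))
  expect_true(all(em$reads$seq %in% mol_seqs))
  expect_equal(em$reads$total_reads, 1e4)

  # class frequencies track pool frequencies (chi-square, not significant)
  em2 <- emit_reads(sc$final, sc$refs, depth = 1e5, error_rate = 0, seed = 19)
  m <- sc$final$molecules
  m$end <- pmin(m$end, m$start + 200L)
  cls_pool <- tapply(m$copies, vapply(seq_len(nrow(m)), function(i)
    if (m$biotype[i] == "trna")
      classify_interval(m$start[i], m$end[i],
                        nchar(exrna:::trna_by_id(sc$refs, m$parent_id[i])$sequence))
    else "INTERNAL", character(1)), sum)
  cls_obs <- tapply(em2$truth$count, em2$truth$taxonomy_class, sum)
  shared <- names(cls_pool)[cls_pool / sum(cls_pool) > 5e-4]
  p_exp <- cls_pool[shared] / sum(cls_pool[shared])
  o <- cls_obs[shared]; o[is.na(o)] <- 0
  expect_gt(suppressWarnings(chisq.test(o, p = p_exp)$p.value), 0.001)

  # identical seeds give byte-identical FASTQ output
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  emit_reads(sc$final, sc$refs, depth = 2000, error_rate = 0.01, seed = 21, fastq = f1)
  emit_reads(sc$final, sc$refs, depth = 2000, error_rate = 0.01, seed = 21, fastq = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("synthetic chromatograms place classes at their elution centers", {
  # ribosome-scale RNA only: single void peak at 7.5 ml
  pool <- structure(list(time = 0,
                         molecules = data.frame(parent_id = "28S", biotype = "rrna",
                                                start = 0L, end = 5070L,
                                                copies = 100, protected = FALSE),
                         sink_nt = 0), class = "molecule_pool")
  ch <- emit_chromatogram(pool)
  pk <- detect_peaks(ch, 260, max(ch$a260) / 10, 0.2)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_ve - 7.5), 0.021)

  # at a pure-RNA peak apex the 260/280 ratio equals the RNA reference ratio
  apex <- which.max(ch$a260)
  expect_equal(ch$a260[apex] / ch$a280[apex], reference_ratios()$ratio_rna)
})

test_that("chromatogram emission and unmixing round-trip the injected RNA mass", {
  sc <- run_scenario("wash_ri", seed = 23)
  ch <- emit_chromatogram(sc$final, bsa_ug = 40)
  inj <- attr(ch, "injected_rna_ug")
  pk <- assign_peak_labels(detect_peaks(ch, 260, max(ch$a260) / 200, 0.2))
  u <- unmix(ch)
  for (lbl in intersect(c("P0", "P1"), pk$label)) {
    ve <- c(P0 = 7.5, P1 = 15.0)[[lbl]]
    got <- quantify_rna(u, pk[pk$label == lbl, ])
    expect_lt(abs(got - inj[[as.character(ve)]]) / inj[[as.character(ve)]], 0.02)
  }
  # protein at the BSA position must not leak into the RNA channel
  bsa_win <- u$volume >= 12.5 & u$volume < 13.5
  expect_lt(max(u$rna_signal[bsa_win]),
            0.02 * max(u$rna_signal))
})
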