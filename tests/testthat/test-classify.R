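# Read-set IO, parent assignment, taxonomy, and profiling summaries.

test_that("read sets collapse duplicates and enforce the length floor", {
  rs <- read_set(c("ACGUACGUACGUACGU", "ACGUACGUACGUACGU", "ACGU"), c(2L, 3L, 1L))
  expect_length(rs$seq, 1L)        # the 4-mer is below the 15-nt floor
  expect_equal(rs$count, 5L)
  expect_equal(rs$total_reads, 5L)
  expect_error(read_set("ACGUACGUACGUACGU", 0L), "counts")
})

test_that("FASTQ, collapsed FASTA and SAM inputs load equivalently", {
  seqs <- c(substr(GLY$cca_appended, 1, 31), substr(GLY$cca_appended, 40, 74))
  dna <- chartr("U", "T", seqs)

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c(rbind(paste0("@r", 1:2), dna, "+", strrep("I", nchar(dna)))), fq)
  rs_fq <- read_fastq(fq)
  expect_setequal(rs_fq$seq, as_rna(seqs))

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1_x5", dna[1], ">s2_x2", dna[2]), fa)
  rs_fa <- read_collapsed_fasta(fa)
  expect_equal(rs_fa$total_reads, 7L)

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:ref\tLN:100",
               sprintf("r1\t0\tref\t1\t60\t%dM\t*\t0\t0\t%s\t%s",
                       nchar(dna[1]), dna[1], strrep("I", nchar(dna[1]))),
               sprintf("r2\t0\tref\t5\t60\t%dM\t*\t0\t0\t%s\t%s",
                       nchar(dna[2]), dna[2], strrep("I", nchar(dna[2])))),
             sam)
  rs_sam <- read_sam(sam)
  expect_setequal(rs_sam$seq, as_rna(seqs))
})

test_that("reads match by substring with hierarchy and family collapse", {
  # positions 1-31 of the glycine tRNA
  r31 <- substr(GLY$cca_appended, 1, 31)
  ann <- match_reads(read_set(r31), REFS)
  expect_equal(ann$family, "Gly-GCC")
  expect_equal(ann$start, 0L)
  expect_equal(ann$end, 31L)
  expect_equal(ann$taxonomy_class, "FIVE_HALF_S")

  # a read present in both a tRNA and an rRNA resolves to tRNA
  shared <- substr(GLY$cca_appended, 10, 40)
  seqs2 <- REFS$seqs
  seqs2[["28S"]] <- paste0(substr(seqs2[["28S"]], 1, 2000), shared,
                           substr(seqs2[["28S"]], 2001, 5070 - nchar(shared)))
  bt <- REFS$biotype
  refs2 <- reference_set(REFS$trnas, seqs2, bt)
  ann <- match_reads(read_set(shared), refs2)
  expect_equal(unique(ann$biotype), "trna")

  # an unmatched random sequence is UNASSIGNED
  set.seed(53)
  ann <- match_reads(read_set(random_rna(30)), REFS)
  expect_equal(ann$taxonomy_class, "UNASSIGNED")
  expect_error(match_reads(read_set(r31), reference_set(list())), "empty reference")
})

test_that("one substitution is tolerated when allowed", {
  r <- substr(GLY$cca_appended, 1, 31)
  sub <- strsplit(r, "")[[1]]
  sub[16] <- setdiff(c("A", "C", "G", "U"), sub[16])[1]
  mutated <- paste(sub, collapse = "")
  expect_equal(match_reads(read_set(mutated), REFS)$taxonomy_class, "UNASSIGNED")
  ann <- match_reads(read_set(mutated), REFS, max_mismatches = 1L)
  expect_equal(ann$family, "Gly-GCC")
  expect_equal(ann$taxonomy_class, "FIVE_HALF_S")
})

test_that("taxonomy follows the published length windows", {
  B <- nchar(GLY$sequence)  # 71
  expect_equal(classify_interval(0L, 31L, B), "FIVE_HALF_S")
  expect_equal(classify_interval(0L, 34L, B), "FIVE_HALF_L")
  expect_equal(classify_interval(0L, 32L, B), "FIVE_FRAGMENT_OTHER")  # 32 nt: neither window
  expect_equal(classify_interval(0L, B + 3L, B), "FULL_LENGTH_CCA")
  expect_equal(classify_interval(B + 3L - 40L, B + 3L, B), "THREE_HALF")
  expect_equal(classify_interval(B + 3L - 20L, B + 3L, B), "THREE_FRAGMENT")
  expect_equal(classify_interval(10L, 40L, B), "INTERNAL")
  expect_error(classify(list(biotype = "rrna"), GLY), "tRNA-mapped")
})

test_that("taxonomy is a pure function of the interval: full grid vs oracle", {
  for (B in c(71L, 76L)) for (start in 0:5) for (len in 15:80) {
    end <- start + len
    if (end > B + 3L) next
    expect_equal(classify_interval(start, end, B), oracle_class(start, end, B))
  }
})

test_that("size distributions normalize to RPM of mapped reads", {
  r31 <- substr(GLY$cca_appended, 1, 31)
  ann <- match_reads(read_set(r31), REFS)
  h <- size_distribution(ann, "trna")
  expect_equal(h$length, 31L)
  expect_equal(h$rpm, 1e6)

  # sums track the biotype share of mapped reads
  full <- GLY$cca_appended
  ann <- match_reads(read_set(c(r31, full, REFS$seqs[["SNORD-A"]]),
                              c(3L, 1L, 4L)), REFS)
  h <- size_distribution(ann, "trna")
  expect_equal(sum(h$rpm), 1e6 * 4 / 8, tolerance = 1e-9)
})

test_that("isoacceptor shares sum to one and follow read mass", {
  r_gly <- substr(GLY$cca_appended, 1, 31)
  glu <- exrna:::trna_by_id(REFS, "Glu-CTC-1")
  r_glu <- substr(glu$cca_appended, 1, 31)
  ann <- match_reads(read_set(c(r_gly, r_glu), c(3L, 1L)), REFS)
  tab <- isoacceptor_table(ann)
  expect_equal(sum(tab$share), 1.0)
  expect_equal(tab$share[tab$family == "Gly-GCC"], 0.75)
  expect_equal(tab$share[tab$family == "Glu-CTC"], 0.25)
  expect_error(isoacceptor_table(ann[0, ]), "no tRNA-mapped reads")
})

test_that("rRNA start profiles report the modal 1-based start", {
  s58 <- REFS$seqs[["5.8S"]]
  reads <- c(substr(s58, 1, 40), substr(s58, 1, 35), substr(s58, 20, 60))
  ann <- match_reads(read_set(reads, c(5L, 3L, 2L)), REFS)
  pr <- rrna_start_profile(ann, "5.8S")
  expect_equal(pr$mode, 1L)
  expect_equal(sort(pr$histogram$start), c(1L, 20L))

  # a shifted read population moves the mode with it
  reads2 <- c(substr(s58, 13, 52), substr(s58, 13, 60))
  ann2 <- match_reads(read_set(reads2, c(9L, 4L)), REFS)
  expect_equal(rrna_start_profile(ann2, "5.8S")$mode, 13L)

  empty <- rrna_start_profile(ann, "18S")
  expect_equal(nrow(empty$histogram), 0L)
  expect_true(is.na(empty$mode))
})

test_that("mRNA RPKM applies the length and count filters", {
  m1 <- REFS$seqs[["MRNA-5"]]  # 1000 nt
  reads <- substring(m1, seq(1, 901, by = 100), seq(1, 901, by = 100) + 24L)
  ann <- match_reads(read_set(reads), REFS)  # 10 reads of 25 nt
  tab <- mrna_rpkm(ann, REFS)
  expect_equal(tab$id, "MRNA-5")
  # 10 reads, 1-kb transcript, 10 mapped reads in total
  expect_equal(tab$rpkm, 10 / 1 / (10 / 1e6))

  # four supporting reads at min_count 5: excluded
  ann4 <- match_reads(read_set(reads[1:4]), REFS)
  expect_equal(nrow(mrna_rpkm(ann4, REFS)), 0L)
  # 18-nt reads fall below the 19-nt filter
  short <- substring(m1, seq(1, 901, by = 100), seq(1, 901, by = 100) + 17L)
  ann_s <- match_reads(read_set(short), REFS)
  expect_equal(nrow(mrna_rpkm(ann_s, REFS)), 0L)
})

test_that("random fragmentation preserves the injected mRNA rank order", {
  cfg <- sim_config(seed = 71)
  sc <- run_scenario("wash_ri", seed = 71)
  em <- emit_reads(sc$final, sc$refs, depth = 5e4, error_rate = 0)
  ann <- match_reads(em$reads, sc$refs)
  tab <- mrna_rpkm(ann, sc$refs, min_count = 1L)
  inj <- cfg$species[cfg$species$biotype == "mrna", ]
  inj$conc <- inj$cellular_copies  # equal lengths-scaled? rank on copy number
  got <- tab$rpkm[match(inj$id, tab$id)]
  keep <- !is.na(got)
  expect_gt(cor(rank(inj$cellular_copies[keep]), rank(got[keep])), 0.8)
})

test_that("expression correlation behaves at the identity and under permutation", {
  set.seed(61)
  rpkm <- data.frame(id = paste0("G", 1:1000),
                     rpkm = 10 ^ rnorm(1000, 1, 0.8))
  self <- correlate_expression(rpkm, setNames(rpkm$rpkm, rpkm$id))
  expect_equal(self$r, 1.0, tolerance = 1e-12)

  perm <- correlate_expression(rpkm, setNames(sample(rpkm$rpkm), rpkm$id))
  expect_lt(abs(perm$r), 0.1)

  expect_error(correlate_expression(rpkm, c(OTHER = 1.0)), "shared")
})

test_that("fragment-to-parent ratios handle the degraded endpoint", {
  r31 <- substr(GLY$cca_appended, 1, 31)
  full <- GLY$cca_appended
  ann <- match_reads(read_set(c(r31, full), c(10L, 5L)), REFS)
  fr <- fragment_to_parent_ratio(ann, "Gly-GCC")
  expect_equal(fr$ratio, 2.0)
  expect_false(fr$denominator_zero)

  ann0 <- match_reads(read_set(r31, 10L), REFS)
  fr0 <- fragment_to_parent_ratio(ann0, "Gly-GCC")
  expect_true(fr0$denominator_zero)
  expect_equal(fr0$ratio, Inf)
})
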