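# exrna

Tools for analysing the **nonvesicular extracellular RNA** fraction of
cultured cells — the RNA found in conditioned medium *outside*
extracellular vesicles.

Cells release a small fraction (~0.1–0.5% per wash) of their cytoplasmic
RNA as intact tRNAs, ribosomal subunits and ribosomes. What survives in
the medium is decided by extracellular RNase-A-family activity: with a
ribonuclease inhibitor (RI) the intact species persist and appear in
size-exclusion chromatography (SEC) as a void-volume peak (P0,
V<sub>e</sub> ≈ 7.5 ml) and a tRNA-sized peak (P1, 15.0 ml); without RI
the population collapses to a narrow set of resistant fragments,
dominated by 30–31 nt 5′ halves of glycine tRNA that hybridize into
RNase-resistant dimers, plus a short-ssRNA peak (P2, 16.5 ml).

The package implements this system end to end:

* **Chromatogram deconvolution** — parse two-wavelength (A260/A280) SEC
  exports, baseline-correct (morphological opening), call P0/P1/P2 peaks,
  and unmix each point into RNA- and protein-attributable signal by
  solving, per elution point,

  A260 = r + p,  A280 = r/R<sub>rna</sub> + p/R<sub>prot</sub>

  with pure-component 260/280 ratios (defaults 2.0 for RNA, 0.57 for
  BSA), then quantify peak RNA mass (`unmix()`, `quantify_rna()`,
  `peak_ratios()`).
* **tRNA cleavage prediction** — cloverleaf-template annotation of mature
  tRNAs and RNase-A-chemistry cleavage sites (scission 3′ of cytosines in
  single-stranded loops), giving the short (30/31 nt, CpCpU) and long
  (34/35 nt, CpCpA) 5′-half products of tRNA-Gly-GCC
  (`predict_cleavage_sites()`, `fragment_from_cut()`).
* **Fragment taxonomy and profiling** — substring matching of small-RNA
  reads (FASTQ/FASTA/SAM) against CCA-appended references, classification
  into full-length / S-half (30–31 nt) / L-half (33–35 nt) / 3′ / internal
  classes, RPM size distributions, isoacceptor shares, rRNA start
  profiles, mRNA RPKM and fragment-to-parent ratios (`match_reads()`,
  `size_distribution()`, `fragment_to_parent_ratio()`).
* **Dimer protection** — antiparallel hybridization scoring (WC + GU, all
  registers) that reproduces why only the 30–31 nt halves are
  dimer-capable, and the per-cytosine RNase susceptibility profile
  (`duplex_score()`, `susceptibility()`).
* **Stochastic simulator** — discrete-copy release + degradation kinetics
  with exact nucleotide bookkeeping, emitting labelled synthetic reads and
  synthetic chromatograms for every pipeline stage (`run_scenario()`,
  `emit_reads()`, `emit_chromatogram()`; presets `wash_ri`, `its_1h`,
  `serum_24h`, `cf_24h`).

## Worked example

Predicted ribonuclease products of the packaged glycine tRNA reference:

```r
library(exrna)
gly <- packaged_trnas()$trnas[[1]]
predict_cleavage_sites(gly, motifs = c("CCA", "CCU"))
#>   parent_id cut_after motif           loop five_prime_len
#> 1 Gly-GCC-2        29   CCU anticodon_loop             30
#> 2 Gly-GCC-2        30   CCU anticodon_loop             31
#> 3 Gly-GCC-2        33   CCA anticodon_loop             34
#> 4 Gly-GCC-2        34   CCA anticodon_loop             35
```

The CpCpU site produces the 30/31 nt short halves; the anticodon-loop
CpCpA site produces the 34/35 nt long halves. Only the short ones can
form the protective homodimer:

```r
duplex_score(substr(gly$sequence, 1, 31), substr(gly$sequence, 1, 31))
#> dimer score: duplex 8 nt, 20 pairs, paired fraction 0.645 -> dimer-capable
duplex_score(substr(gly$sequence, 1, 35), substr(gly$sequence, 1, 35))
#> dimer score: duplex 8 nt, 20 pairs, paired fraction 0.571 -> not capable
```

Simulate 24 h of serum-level RNase exposure, sequence the surviving pool,
and profile the glycine 5′ fragments:

```r
sc  <- run_scenario("serum_24h", seed = 1)
em  <- emit_reads(sc$final, sc$refs, depth = 1e5, error_rate = 0, seed = 2)
ann <- match_reads(em$reads, sc$refs)
size_distribution(ann, "trna", family = "Gly-GCC",
                  classes = c("FIVE_HALF_S", "FIVE_HALF_L", "FIVE_FRAGMENT_OTHER"))
#>   length   rpm
#> 1     28  9550
#> 2     30 22410
#> 3     31 24780
fragment_to_parent_ratio(ann, "Gly-GCC")$denominator_zero
#> [1] TRUE
```

After 24 simulated hours no full-length glycine tRNA remains (the
fragment-to-parent ratio is a flagged infinity) and the surviving
5′-anchored glycine fragments are all ≤ 31 nt, with the dimer-protected
30/31-mers dominating — the simulated counterpart of the observation that
serum RNases convert extracellular tRNA into stable 30–31 nt halves.

## Scope

Wet-lab steps (ultracentrifugation, gradients, blotting), EV biology and
immunological readouts are out of scope; the simulator's rRNA treatment
is deliberately structure-free and its non-tRNA reference sequences are
seeded synthetic stand-ins at the declared human lengths (28S 5070 nt,
18S 1869 nt, 5.8S 156 nt). See the methods vignette
(`vignettes/extracellular-rna-model.Rmd`) for the model, parameter
defaults and known limitations.
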