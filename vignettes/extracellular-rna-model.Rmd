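---
title: "Modelling the nonvesicular extracellular RNA fraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the nonvesicular extracellular RNA fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exrna)
```

## The biological picture

Cultured cells shed a small fraction of their cytoplasmic RNA into the
medium even during washes of a few seconds: full-length tRNAs, ribosomal
subunits and ribosomes (with their mRNAs), all outside extracellular
vesicles. What is actually *detected* in conditioned medium depends on the
extracellular ribonuclease activity. With an RNase-A-family inhibitor (RI)
added, intact tRNAs and ribosome-scale complexes survive and can be
observed by size-exclusion chromatography (SEC) as a void-volume peak (P0,
V_e = 7.5 ml on a Superdex 200) and a tRNA-sized peak (P1, 15.0 ml).
Without RI, single-strand-specific RNases convert this population into a
narrow set of resistant fragments — most prominently 5' halves of glycine
tRNA of exactly 30-31 nt, which hybridize into RNase-resistant dimers and
elute in P1, plus a short-ssRNA degradation peak (P2, 16.5 ml).

`exrna` implements this system end to end as testable code: chromatogram
deconvolution, cleavage prediction on mature tRNAs, small-RNA read
taxonomy and profiling, a dimer-protection score, and a stochastic
simulator that generates every input the pipeline consumes, with ground
truth.

## Two-wavelength chromatogram unmixing

SEC traces are recorded at 260 and 280 nm. For pure components the
absorbance ratio A260/A280 is characteristic: about 2.0 for RNA, about
0.57 for serum albumin. Writing `r` for the RNA-attributable A260 and `p`
for the protein-attributable A260 at one elution point,

$$A_{260} = r + p, \qquad
  A_{280} = \frac{r}{R_\mathrm{rna}} + \frac{p}{R_\mathrm{prot}},$$

a 2x2 linear system solved point-wise (`unmix()`). RNA is reported in
A260-equivalents and protein in A280-equivalents. The system is singular
only when the two reference ratios coincide. Negative solutions (possible
under noise near zero signal) are clamped to zero and flagged per point
rather than re-fit under constraints: clamping is local, auditable, and
does not propagate along the trace. The default reference ratios are the
textbook pure-component values and should be replaced by empirically
determined ratios when a calibration standard is available
(`reference_ratios()`).

Quantitation divides the integrated RNA signal by a response coefficient;
the default 0.025 AU per ug/ml is the standard ssRNA conversion
(1 AU = 40 ug/ml).

### Baseline and peaks

The baseline estimator is a morphological opening: a rolling minimum
followed by a matching rolling maximum over a volume window (default
2 ml). It removes flat offsets exactly, follows linear drifts without the
half-window bias of a plain rolling minimum, and never digs into a peak
narrower than the window. Its known limitation is a bias proportional to
the drift slope in the immediate vicinity of a peak; at realistic drifts
(a few mAU per ml) the induced area error stays below 2%.

Peak calling keeps local maxima by topographic prominence (shoulders
whose saddle is shallower than `min_prominence` are absorbed into the
taller neighbour), bounds each peak at the outermost point of its
flanking-minimum plateaus, and integrates both channels by trapezoid on
the native grid — no resampling, intervals half-open on the volume axis.
Labels (P0/BSA/P1/P2) are assigned by nearest expected elution volume
(7.5, 13.0, 15.0, 16.5 ml by default), not by rank, so a missing peak
does not shift the labels of the others.

## Mature tRNA references and cleavage chemistry

The package ships the mature human sequences (without the nontemplated 3'
CCA) of the four tRNAs relevant to the assay: Gly-GCC (isodecoder 2),
Glu-CTC, Lys-TTT and initiator iMet-CAT. A CCA-appended shadow of each is
used for read matching, so read coordinates live on the appended axis and
a full-length read is recognizable by its terminal CCA. The cloverleaf is
annotated by a positional template: the anticodon arm is found by scanning
for a 7-nt loop flanked by a 5-bp complementary stem (GU wobble allowed);
acceptor stem, D-loop and T-loop are placed at their canonical positions.
The annotation is deterministic and is cross-checked against the
anticodon encoded in the tRNA's name.

Cleavage prediction follows RNase A chemistry: scission of the
phosphodiester bond 3' of a pyrimidine, restricted here to cytosines
because the two motifs observed at the glycine anticodon loop (CpCpA and
CpCpU) each produce two product lengths — one per C. On the packaged
Gly-GCC-2 reference (71-nt body, anticodon loop C31-U32-G33-C34-C35-A36-C37,
1-based):

```{r cleavage}
gly <- packaged_trnas()$trnas[[1]]
predict_cleavage_sites(gly, motifs = c("CCA", "CCU"))
```

The CpCpU site yields the 30- and 31-nt short halves (S-tRNAh) — exactly
the species that dominates RNase-rich extracellular samples. The CpCpA
site in the anticodon loop yields 34- and 35-nt long halves, inside the
published L-tRNAh window (33-35 nt). Note that cutting 3' of a cytosine
can never produce a 33-mer here, because position 33 of this tRNA is the
anticodon's G; a drawing that marks the CpCpA products as 33/34 nt is off
by one with respect to its own motif. We keep the chemistry and the real
sequence and report 34/35.

A cut at the boundary between a stem and a loop is allowed when the motif
extends into the loop: terminal base pairs fray. This is what admits the
CpCpU site, whose first C is the last paired position of the anticodon
stem.

## Dimer protection

Only the 30-31 nt short halves form RNase-resistant homo-/heterodimers;
the 33-35 nt long halves do not. The package scores dimer-forming
capacity by the best antiparallel ungapped hybridization register between
two strands (Watson-Crick plus GU wobble; no intramolecular structure, no
gaps). Three thresholds gate capability, all exposed in the score:

* `best_duplex_len >= 8` — a contiguous nucleation helix;
* `paired_fraction >= 0.62` — near-complete coverage of the shorter
  strand, because long single-stranded overhangs leave cleavable
  pyrimidines exposed;
* `paired_count >= 18` — enough total pairs for a stable duplex, which
  keeps short spurious fragments from qualifying.

A single threshold on the longest contiguous duplex cannot reproduce the
S-versus-L contrast for a principled reason: the short half is a prefix of
the long half, so every register alignment available to S is also
available to L and any substring-monotone score is at least as large for
L. The discriminating quantity is the paired *fraction*: the glycine
S-halves score 0.645-0.667 against themselves, the L-halves 0.571-0.588,
with the default 0.62 between the two. This coverage criterion is a
sequence-level proxy for the structural model in which the extra
anticodon-proximal nucleotides of the L-half prevent the blunt duplex;
the proxy is deliberately simple (no nearest-neighbour free energies, no
concentration dependence) and its thresholds are recorded in the
configuration rather than hidden.

`susceptibility()` converts a sequence plus an optional dimer state into
a per-position hazard profile: 1 at unpaired cytosines, 0 elsewhere.

## The degradation simulator

The simulator is a discrete-copy stochastic model; copies are integers
and every nucleotide is accounted for (surviving molecules plus a
degraded sink), so mass conservation is exact, not approximate.

**Release.** Each species releases `Binomial(cellular copies, f)`
full-length molecules per wash, with `f = 0.003` by default — the middle
of the plausible 0.1-0.5% range for the fraction of cellular RNA found in
a wash. Default cellular copy numbers are a desk-scale caricature
(2e5 Gly-GCC down to 5e4 iMet; equimolar rRNAs at 4e4; sparse mRNAs) —
they preserve the rank structure of a cytoplasm, not absolute counts.
Released mRNAs are optionally pre-fragmented uniformly at random, which is
the assumption under which extracellular mRNA abundances are later
summarized as RPKM.

**Degradation.** Per time step (1 h), each molecule copy draws a
first-event competing risk over its cleavage sites with probability
`1 - exp(-(H_cut + H_trim) dt)`. Full-length tRNAs expose only loop
cytosines (cloverleaf stems are paired); every other molecule — any
fragment, and long RNAs whose secondary structure we do not model —
exposes all its cytosines. This treatment of rRNA is declared crude: real
rRNA is heavily structured, and the model consequently overestimates how
uniformly it is chewed. Dimer-capable tRNA fragments are exempt from
cleavage entirely (the protected state), a simplification of duplex
equilibrium that matches the qualitative observation that the S-halves
accumulate while everything else disappears. Products shorter than 15 nt
(the sequencing detection floor) move to the sink.

Long (33-35 nt) 5' halves can convert to short ones by two routes, both
available and both on by default: direct cleavage at their internal CpCpU
cytosines, and 3'-exonucleolytic trimming to 30/31 nt. Which route
operates in vivo is an open question; the simulator exposes
`s_half_route` so either hypothesis can be run alone.

**Activity levels.** Rates are ordinal, not fitted: RI = 0 exactly
(complete inhibition), endogenous secreted RNases = 0.05 per site per
hour, serum = 2.0. The serum value makes one hour sufficient to convert
essentially all full-length glycine tRNA (survival with ~8 exposed loop
cytosines: `exp(-16)`), matching the observation that serum converts the
full-length band to S-halves within an hour; the endogenous value leaves
full-length tRNA clearly visible after 1 h and mostly gone after a 24-h
cell-free maturation. No absolute rate constants are claimed.

**Presets.** `wash_ri` (short wash, RI added), `its_1h` (1 h serum-free,
endogenous RNases), `serum_24h` (24 h at serum activity), `cf_24h`
(cell-free maturation, 24 h endogenous).

**Read emission.** Reads are drawn multinomially by copy number, truncated
at 200 nt (a 200-cycle run; molecules longer than that yield 5'-anchored
truncated reads), with optional per-base substitution errors. Truth labels
carry the parent, interval and taxonomy class of the originating molecule.
With a fixed seed the FASTQ is byte-identical across runs.

**Chromatogram emission.** Pool species map to elution centers by
hydrodynamic size — >= 1000 nt to the void peak, full-length tRNA and
duplex-protected fragments to 15.0 ml, short monomeric ssRNA to 16.5 ml —
as Gaussian peaks (sigma 0.25 ml) whose two channel amplitudes follow the
pure-component ratios, so `unmix()` plus `quantify_rna()` recover the
injected masses.

## Read taxonomy and profiling

Reads (FASTQ, collapsed FASTA, or SAM) are matched as substrings of the
references, exactly by default. Matching uses pigeonhole seeding: with at
most one substitution, at least one of two disjoint read windows is
error-free, so candidate positions come from hashed reference 12-mers
(half-length windows for reads under 24 nt) and are verified by Hamming
distance. Hits resolve by the hierarchy tRNA > rRNA > snoRNA/other >
mRNA; within tRNA, hits that agree at the anticodon level collapse to the
isoacceptor family, and genuinely ambiguous cross-family reads (the
conserved T-arm is shared verbatim between the packaged Gly and Glu
references) split their count fractionally. The default remains exact
matching: with mismatches enabled the matcher is complete up to one
substitution.

tRNA-mapped reads are classified on the CCA-appended axis:

| class | rule |
|---|---|
| `FULL_LENGTH_CCA` | starts at 0, ends at the appended 3' end |
| `FIVE_HALF_S` | 5'-anchored (start <= 1), 30-31 nt |
| `FIVE_HALF_L` | 5'-anchored, 33-35 nt |
| `FIVE_FRAGMENT_OTHER` | 5'-anchored, any other length |
| `THREE_HALF` / `THREE_FRAGMENT` | reaches the 3' end, >= 30 / < 30 nt |
| `INTERNAL` | anywhere else |

Length 32 deliberately belongs to neither half window — the literature
uses both "33-35" and "34-35" for the long halves and never assigns 32,
and keeping it out preserves the S/L dichotomy. The one-nucleotide 5'
tolerance absorbs common ligation/trimming artifacts while keeping the
halves anchored.

Summaries: size histograms in reads per million mapped (RPM), isoacceptor
shares (fractions of tRNA-mapped read mass), rRNA start-position
histograms with the modal 1-based start, mRNA RPKM (reads >= 19 nt,
transcripts supported by >= 5 reads), and the fragment-to-parent ratio —
fragment-class read mass over full-length read mass per family, with a
flagged infinity when no full-length reads remain. The expression
correlation uses Pearson on `log10(x + 0.1)` by default (Spearman
available); the pseudocount keeps unobserved transcripts finite on the
log scale.

## What the synthetic data does and does not establish

The generator emulates: release of a fixed small fraction of a mixed
cellular pool; progressive single-strand-specific fragmentation that RI
suppresses and serum accelerates; survival of duplex-protected 30-31 nt
5' halves; and the P0/P1/P2 peak structure with component-specific
260/280 ratios. Tests passing on it demonstrate internal consistency of
the pipeline — truth-label recovery, conservation laws, monotone
degradation statistics, round-trip quantitation — under a model whose
sequences (for rRNA/snoRNA/mRNA) are random stand-ins at the correct
lengths, whose RNase is cytosine-only, and whose structure model is a
positional cloverleaf template. They do not establish performance on real
libraries: no modification-driven mismatches or stops, no ligation
biases, no genuine rRNA structure, no EV compartment, and only four tRNA
species. Parameters most worth revisiting against real data are the
activity levels (ordinal here), the dimer thresholds, and the mRNA
fragmentation rate.

## Numerical and interface conventions

Coordinates are 0-based half-open internally and 1-based inclusive in
every written report. Volume intervals are half-open. All randomness
flows from a single integer seed per run; scenario runs, read emission
and the pipeline record the seed in their outputs, and the run manifest
carries a parameter hash (output paths excluded) so reruns are
verifiable. Desk-scale problem sizes used throughout the test-suite and
the acceptance analysis: sequencing depth 1e5, three seeds for stochastic
endpoints, five time points for kinetics — sizes at which every
documented check completes in seconds to a couple of minutes on one core.
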