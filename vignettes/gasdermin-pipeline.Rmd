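---
title: "Methods: gasdermin family discovery, phylogeny, and cleavage-site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gasdermin family discovery, phylogeny, and cleavage-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasderminevo)
```

## The analysis this package implements

Gasdermins are pore-forming executioners of pyroptosis: an N-terminal pore
domain is held inactive by a C-terminal autoinhibitory domain, and the two
are joined by a linker whose proteolytic cleavage activates the protein.
Inflammatory caspases such as caspase-1 cleave after an aspartate (the P1
residue) and read the three residues upstream (P4--P2) plus the downstream
P1'/P2' context; apoptotic caspases such as caspase-3 prefer an aspartate
at P4 as well (the DxxD motif). Which gasdermin carries a caspase-1
tetrapeptide in its linker, and in which vertebrate clades, is therefore an
evolutionary question that can be asked directly from sequence.

`gasderminevo` implements that comparative analysis as a reusable,
deterministic desk-scale pipeline:

1. **Curation** — redundancy removal by greedy identity clustering,
   1-to-1 orthology by reciprocal best hits, and removal of partial rows
   from the family alignment.
2. **Family discovery** — a profile hidden Markov model built from a
   curated alignment, used to scan proteins or six-frame-translated
   contigs in log-odds bits.
3. **Phylogeny** — Poisson-corrected protein distances, neighbor joining,
   midpoint rooting, and exact monophyly tests for clade labels.
4. **Linker and motif analysis** — projection of reference structural
   boundaries (end of strand β11, start of helix α5) through the
   alignment, extraction of a P4..P1 tetrapeptide for every linker
   aspartate, rule-based caspase classification, sequence-logo information
   content, per-clade summaries, and Kyte--Doolittle hydropathy profiles
   of the α7′--α8 interhelix region.
5. **Synthetic data** — a generator with complete ground truth, so every
   stage is testable without any download.

## Models and procedures

### Pairwise and multiple alignment

Pairwise alignment is affine-gap dynamic programming over BLOSUM62 (a gap
of length $L$ costs $11 + L$, the BLAST convention; `X` scores 0 against
everything). Traceback ties are resolved deterministically
(diagonal, then up, then left), so all downstream results are reproducible
to the byte. The multiple aligner is progressive: a UPGMA guide tree on
shared 3-mer distances, then profile--profile alignment at each internal
node with average-linkage column scores in which gap characters contribute
zero. This is a deliberate desk-scale stand-in for production aligners;
the downstream contract is only that conserved domains align column-wise,
and the test suite checks behaviour on alignments with planted structure.

### Profile HMM

The profile follows the standard match/insert/delete architecture. Columns
with gap fraction ≤ 0.5 become match states; emissions are
background-weighted pseudocount-smoothed column counts
($(c + \tau\,b)/(n + \tau)$ with pseudocount weight $\tau = 1$); transition
probabilities are pseudocount-smoothed counts of the state paths implied by
each row. The background is uniform ($1/20$), which keeps every analytic
check closed-form. Scoring is local in the sequence and global in the
model: free flanking states (log-odds 0 per background residue) let the
family model match anywhere inside a protein or ORF. Viterbi gives the
best path in bits; forward gives total log-odds and always dominates
Viterbi — both are verified against exhaustive path enumeration on small
models. The default reporting threshold is 20 bits; on the synthetic
conditions below, family members score several hundred bits and decoys
score deeply negative, so the threshold separates them completely and is
not a tuned quantity.

### Phylogeny

Distances are Poisson-corrected mismatch fractions,
$d = -\ln(1 - p)$, computed over pairwise-complete (both-ungapped)
columns, with $p$ capped at 0.95 so distances stay finite (the cap is
reported when applied). Trees come from Saitou--Nei neighbor joining with
the Studier--Keppler criterion; negative branch lengths are clamped to
zero and the deficit reported. Monophyly of a label set is exact
leaf-descendant equality at some node of the rooted (midpoint-rooted)
tree. Bayesian time calibration is deliberately out of scope: the
package's claims are restricted to topology, where NJ on corrected
distances is consistent on additive matrices — a property the tests verify
on 50 random additive matrices.

### Linker delimitation and tetrapeptide classification

The linker is defined structurally: the residues strictly between the end
of β11 and the start of α5 of a chosen reference, projected through the
alignment into every row's own coordinates (1-based inclusive throughout,
so a tetrapeptide ending at residue 244 occupies 241--244). Rows with no
residue in the projected window receive a null annotation rather than an
error. Every linker aspartate yields one site: the P4..P1 window
(left-padded with `X` within the first three residues of the protein) plus
P1′/P2′ read from the full protein so sites at the linker's C-edge get
their true downstream context.

Classification is rule-based and total over the 8,000 D-terminal
tetrapeptides: `DxxD` is caspase-3-like; otherwise a bulky P4
(F, W, Y, L, I, V, M) is caspase-1-like; anything else is `other_asp`. The
bulky set is configurable; methionine and tryptophan are included on
physicochemical grounds. A small additive score
(bulky P4 +2, small P1′ +2, glycine P1′ +1, proline P2′ +1) ranks sites
within a class but never changes the class. "YVAD-likeness" — used for the
per-clade summaries — is operationalised as summed position-wise BLOSUM62
similarity to `YVAD` of at least 15 (YVAD itself scores 21; YIAD 20 passes,
FVSD 14 does not). The threshold is exposed so sensitivity can be explored.

### Sequence logos

Per position, relative frequencies over the 20 amino acids (unknown
residues excluded, remainder renormalised) and information content
$IC = \log_2 20 - H - e_n$, with $H$ the Shannon entropy in bits and
$e_n = (s-1)/(2 n \ln 2)$, $s = 20$, the small-sample correction
(optional). IC is floored at zero. A fully conserved position with the
correction disabled gives $\log_2 20 \approx 4.3219$ bits; a uniform
position gives 0.

### Hydropathy

Sliding-window means of the Kyte--Doolittle scale (window 9 by default,
odd, centred); the α7′--α8 interhelix windows shipped as defaults are
residues 347--380 (human GSDMD) and 314--347 (chicken GSDMA).

## The synthetic generator: what it emulates and what it does not

The generator emulates the features of the real data that the pipeline's
correctness depends on: a clade-structured species tree (per-clade
pure-birth trees joined at the root by stem branches), proteins built as
conserved N-domain + poorly conserved variable-length linker + conserved
C-domain, clade-specific tetrapeptides planted in a configurable fraction
of linkers followed by a `GP` P1′/P2′ context, unrelated decoy proteins,
1-to-1 ortholog copies, and optionally nucleotide contigs embedding
back-translated members in known frames.

Substitution follows the 20-state Jukes--Cantor analog: along a branch of
$d$ expected substitutions per site each site differs from its parent with
probability $p(d) = \tfrac{19}{20}(1 - e^{-20d/19})$, replacement uniform
over the 19 alternatives. The closed form makes every statistical test
analytic — distances can be inverted exactly and biases measured against
a known truth — which is the point: the generator tests pipeline
correctness, not empirical realism. It does **not** emulate site-rate
heterogeneity, indels inside domains, codon structure, gene
duplication/loss, or database annotation noise, so green tests demonstrate
algorithmic correctness under the stated model, not performance on real
proteomes.

Filler linker sequence is rejection-sampled so that no unplanted aspartate
carries a bulky or aspartate P4 (the N-domain tail is included in the
check so junction sites cannot arise). Planted sites are therefore the
*only* caspase-like linker sites, which makes scanner precision exactly
measurable.

Default conditions, chosen once as a realistic desk-scale analog of a
vertebrate gasdermin family: four clades (bird, reptile, amphibian,
mammal) of 8 taxa, clade motifs YVAD / FVSD / FASD / FLTD planted in every
linker; N-domain 90 and C-domain 110 residues; linkers uniform 15--30
residues; stem branches of 0.3 expected substitutions per site between
clades (the separation regime in which distance methods are expected to
recover clades) and within-clade pure-birth trees contributing roughly
0.1; 12 uniform-composition decoys of 150--300 residues. Ortholog copies
diverge by a further 0.02 substitutions per site. The tests and the
acceptance script run a two-clade reduction (bird/reptile, 4 taxa each,
40+50-residue domains, 10--16-residue linkers) across 20 seeds, plus one
100-taxon bird simulation with a planted YVAD fraction of 0.30 — the
desk-scale analog of the observed prevalence of YVAD-like tetrapeptides in
bird GSDMA linkers; these problem sizes keep a full suite run around a
minute while leaving every statistical check well-powered.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive everywhere.
* Trimming of partial alignment rows applies *strict* inequalities
  (non-gap count < 50% of columns, or gap fraction > 50%); a row sitting
  exactly at the boundary is retained. Trimming never changes the column
  set and is idempotent.
* Identity uses the shorter-sequence denominator (the CD-HIT convention);
  the default clustering threshold is 0.95.
* Reciprocal-best-hit scoring uses raw local-alignment scores with a
  default floor of 50; score ties are broken by lexicographic id and
  reported. E-value calibration is out of scope.
* NJ tie-breaks (lowest index pair) and the diagonal>up>left alignment
  traceback order are fixed for determinism; all generator output is
  byte-identical under a fixed seed.
* Probability vectors are validated to sum to 1 within 1e-9 at profile
  construction; all probabilities are positive after pseudocounts.
* Back-translation uses the alphabetically first codon per residue, which
  is deterministic and never introduces stop codons.

## Design decisions that were genuinely open

* **Boundary projection vs. re-prediction.** Structural boundaries are
  inputs (a small YAML config), not hard-coded and not re-derived from
  structure prediction; only the α7′--α8 hydropathy windows ship as
  defaults.
* **Projection uncertainty.** Because linkers are unconserved (and in the
  generator outright non-homologous), the placement of insertions adjacent
  to a boundary column is ambiguous under any sum-of-pairs alignment
  objective: a random linker residue that happens to match the domain's
  edge residue will be pulled into the domain block. Projected boundaries
  therefore carry an uncertainty of one or two residues at the linker
  edges. The quantities the analysis rests on — which tetrapeptides exist
  in the linker and how they classify — are robust to this, and the tests
  assert interval overlap plus exact site recovery rather than exact
  interval equality.
* **One vote per record.** Clade summaries count a sequence once however
  many qualifying sites it carries, and clade labels are free-form
  metadata rather than tree-derived groups (summaries must be computable
  for non-monophyletic groups such as paraphyletic "other" bins).
* **Worked-example fixtures are synthetic.** The shipped
  `synthetic_worked_example.fasta` stand-ins place the validated motifs
  (FASD ending at residue 244; FLTD ending at 275) at the documented
  coordinates inside otherwise random sequences. They exercise positional
  bookkeeping end to end; they are not the real proteins, and are named
  and documented accordingly.

## Known limitations

The aligner is a desk-scale progressive implementation (≈200 rows), not a
production MSA tool; the profile HMM does not read or write HMMER formats
and has no extreme-value E-value calibration; the phylogeny module does no
maximum-likelihood optimisation, bootstrap, or divergence-time estimation;
and SpeB or granzyme cleavage preferences are not modelled. Splice-aware
gene prediction is out of scope — the six-frame scan flags ORFs on
unspliced contigs only.
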