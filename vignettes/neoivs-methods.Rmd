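---
title: "Methods: from somatic variant calls to tandem minigenes and clonotype tracking"
author: "neoivs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from somatic variant calls to tandem minigenes and clonotype tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoivs)
```

# Scope

`neoivs` implements the computational stages that sit around an in vitro
stimulation (IVS) screen for neoantigen-reactive memory T cells: deciding
which tumor somatic variants deserve a neoepitope, constructing the mutant
long peptides and the tandem minigene (TMG) constructs that encode them,
and quantifying known reactive TCRβ clonotypes across sorted T-cell
subsets. The wet-lab stages (dendritic-cell culture, RNA transfection,
41BB/OX40 sorting, ELISPOT) and the upstream read-level bioinformatics
(alignment, the callers themselves, functional annotation) are out of
scope: the package consumes caller outputs and sequence tables, and ships
a ground-truthed simulator so every stage is testable without any external
data.

# The consensus variant filter

Exome SNVs are expected from four callers (Mutect, Strelka, Varscan2,
SomaticSniper) and insertions/deletions from two (Strelka, Varscan2).
Calls sharing a variant key — chromosome/transcript, position, and
minimal-representation alleles — are merged into one evidence record whose
caller set is the union of reporting callers. A variant passes when all
of the following hold, every comparison inclusive:

* tumor coverage ≥ 10 and normal coverage ≥ 10,
* tumor variant reads ≥ 4,
* tumor variant allele fraction (VAF) ≥ 7%,
* for SNVs only, ≥ 2 callers (indels have no caller criterion).

A variant catalogued in COSMIC passes regardless of the cutoffs; when it
would otherwise have failed it is flagged as a *rescue* so downstream
reports can distinguish evidence-passing from catalogue-rescued variants.
RNA support (Varscan on RNA-seq, no cutoffs) is carried as an annotation
and never gates the decision.

Two merging choices deserve comment, because the underlying procedure
leaves them open:

* **Evidence source.** When callers disagree on read counts, the merged
  record takes its counts from one caller in the fixed priority order
  Mutect > Strelka > Varscan2 > SomaticSniper. Any deterministic choice
  would do; a fixed priority keeps decisions reproducible and auditable.
* **Allele normalization.** Variant identity uses minimal representation
  (trim the shared allele suffix, then the shared prefix, keeping one
  anchor base). True left-alignment against a reference genome is not
  possible here because the package never sees one; for the anchored,
  transcript-space indels it consumes, the two normalizations coincide.

The filter is deliberately monotone: raising any threshold can only
shrink the non-COSMIC pass set. The test suite checks this property, and
checks the whole rule set against an independent brute-force boolean
re-evaluation on >1,000 simulated variants.

# Neoepitope extraction

Peptides are extracted in CDS space from transcript cDNA. For an SNV at
protein position $p$ of an $L$-residue protein, the peptide is the mutant
residue with 12 wild-type amino acids on either side where possible:

$$\mathrm{len} = \min(12, p-1) + 1 + \min(12, L-p) \le 25$$

so an interior substitution yields a 25-mer with the mutant residue at
position 13, and a position-12 substitution (the KRAS-G12 geometry)
yields a 24-mer — the length at which mutant KRAS long peptides are
screened. Synonymous SNVs are rejected; stop-gaining SNVs are rejected
with a warning since they leave no mutant residue to present.

For indels the corresponding change is made to the cDNA and the edit is
re-translated. In-frame indels present the altered residue block (all
inserted residues, or the junction residue of a deletion) with up to
12-aa flanks. Frameshifts keep up to 12 wild-type residues before the
first divergent position and then every novel residue up to, but
excluding, the first stop codon; when no stop occurs the neo-ORF reads
through the CDS end into the 3′ cDNA, to the end of the transcript, and
the peptide is flagged `reached_transcript_end`. Three degenerate cases
are resolved as package policy: a stop-loss SNV is treated as a
frameshift-style tail (flagged by its protein-change label); a frameshift
whose first novel codon is already a stop is rejected with a warning,
symmetric with nonsense SNVs; and duplicate peptides arising from
multiple transcripts are deduplicated by exact peptide string, first
transcript winning.

The frameshift path is validated against a spec-level oracle: translate
the fully edited cDNA from the CDS start, find the first residue that
diverges from the wild-type protein, and slice 12 residues before it.
Module output must equal that slice on hundreds of random indels,
including read-through cases.

# Tandem minigene assembly

Peptides are packed, order-preserving, into TMGs of at most 16 minigenes
each (so 201 minigenes make $\lceil 201/16 \rceil = 13$ TMGs; the
capacity reproduces that screening layout and is configurable). Each TMG
records its amino-acid concatenation and a nucleotide realization. The
back-translation reuses the native codons of the edited cDNA — each
extracted peptide carries the codons it was read from — falling back to a
fixed most-frequent-human-codon table for sequences without a nucleotide
hint. An ATG is prepended when the first residue is not methionine, and a
single stop codon (TAA by default) is appended.

Because TMGs are cloned with EcoRI and BamHI, the realized sequence must
contain neither GAATTC nor GGATCC. Sites are removed by scanning left to
right and applying the first synonymous codon swap that destroys the
occurrence without creating a new one; the stop codon may swap within
{TAA, TAG, TGA}. For these two 6-mers a synonymous fix always exists in
practice; the implementation still verifies convergence and that the
final translation is unchanged, and raises a design error otherwise.

# Repertoire tracking and clonality

Repertoires are read from immunoSEQ-style TSVs (or AIRR-C rearrangement
TSVs), aggregated by (CDR3 nucleotide, V gene, J gene) with template
counts summed. Out-of-frame rearrangements are retained but every
frequency and clonality computation uses only productive templates.

Known reactive TCRs are tracked across sorted subsets (TN, TCM, TEM,
TEMRA, bulk PBL, TIL) as
$100 \times \text{matched productive templates} / \text{total productive templates}$,
with two match modes: `nt` (exact CDR3 nucleotide identity, the default
for deep-sequencing-derived clones) and `aa_v` (CDR3 amino acid plus V
gene, for Sanger-derived TCRs whose exact rearrangement may be unknown).
Undetected clones are reported as a minus sign, matching how such
tracking tables are conventionally displayed; a sample with no productive
templates yields per-cell error markers rather than an error.

Per sample, over the $R$ unique productive rearrangements with
frequencies $p_i$,

$$H = -\sum_i p_i \ln p_i, \qquad \text{clonality} = 1 - H/\ln R,$$

i.e. one minus Pielou evenness in natural logarithms — the standard
immunoSEQ-style definition; the analyzer used for such data does not
publish its exact formula, so this choice is stated explicitly here.
$R = 1$ is defined as clonality 1.0 (the limit of maximal dominance).
Clonality is invariant to template rescaling and clone relabeling and
strictly increases when templates move from the smallest to the largest
clone; the suite checks all three numerically. Subset comparisons use a
classical paired t-test on per-patient differences; zero-variance
differences are flagged degenerate with no p-value rather than producing
a spurious one.

Single-cell wells (e.g. 41BB-sorted cells after peptide co-culture) are
aggregated by β-chain call with per-subset well counts; each β is paired
with its most frequent co-occurring α chain, and α ties are reported,
never broken silently.

# The synthetic-data generator

The generator produces ground-truthed inputs with the statistical
structure the analysis assumes; its defaults are fixed once and encode
the study conditions rather than being tuning knobs.

**Transcripts.** Random ATG-initiated, internal-stop-free CDS of 300–900
nt (stop codon included), followed by a 120-nt 3′ tail so frameshift
neo-ORFs can read past the CDS.

**Variants and callers.** Non-synonymous SNVs (60 by default) and indels
(10 insertions, 10 deletions, ~30% in-frame) are planted at known CDS
positions. Tumor/normal depth is negative binomial (means 120/80,
dispersion 8 — exome-like depth with realistic overdispersion); tumor VAF
is Beta(20, 30) (clonal variants around 40% with moderate spread);
variant reads are binomial given depth and VAF. Each caller detects each
true variant independently with sensitivities 0.95/0.90/0.85/0.80
(Mutect/Strelka/Varscan2/SomaticSniper — better callers slightly more
sensitive) and emits false positives at 2% per variant slot. False
positives carry weak evidence by construction (≤3 variant reads, single
caller), so the filter's effect is visible in ROC terms. Five percent of
true variants are flagged as COSMIC. Caller errors are simulated
independently across callers; real ensembles have correlated errors, so
simulated consensus performance is optimistic in that respect — a
documented limitation.

**Repertoires.** Per patient and subset, clone sizes follow a Zipf law
with subset-specific exponents (TN 1.05, TCM 1.30, TEM 1.55, TEMRA 1.60,
bulk 1.30) over subset-specific clone pools (20000/8000/4000/3000/10000),
chosen so realized clonality orders TEMRA ≈ TEM > TCM > TN — the
hierarchy observed across sorted memory subsets. Reactive clones are
spiked only into memory subsets (never TN) at true frequencies drawn
uniformly from 0.0007%–0.02% of the subpopulation, and templates are
drawn multinomially at 10^5 templates per sample (sequenced T-cell inputs
in such screens span roughly 2×10^4–10^6 cells). About 10% of background
clones are rendered out-of-frame so productive filtering is exercised.
The simulator does not model CDR3 sequencing error, V(D)J recombination
biology, or cross-subset clone sharing; passing tests therefore
demonstrate correctness of the estimators under sampling noise, not
robustness to those real-data complications.

All randomness derives from one integer seed; each generator stage uses
its own derived stream, so regenerating one stage never perturbs another,
and identical configurations produce byte-identical output files.

# Problem sizes used in the automated checks

The test suite and the acceptance script re-derive their quantities at
sizes chosen to make the statistical checks sharp while keeping runs
quick on a single CPU: the filter oracle runs on >1,000 merged variants;
the peptide length law on 500 random SNVs; the frameshift oracle on 200
random indels over short (22–60 codon) transcripts with 15–60-nt tails so
the read-through branch is exercised; spike recovery on 100 simulations
at depths 10^5–10^6 with a 95% binomial interval (expected coverage ≈95%,
required ≥93%); and the clonality hierarchy on 50 seeded repertoire sets
at depth 2×10^4 with proportionally scaled clone pools, keeping the
default Zipf exponents.

# Known limitations

* HLA-binding prediction is a stub: externally predicted minimal epitopes
  can be attached to a neoepitope, never computed.
* Genomic-to-CDS coordinate mapping is the caller's duty; the package
  works in transcript space.
* COSMIC membership is supplied as a key set, not queried live, keeping
  results independent of catalogue versions.
* Whether deep-sequencing tracking should match by nucleotide or by
  amino acid + V gene is data-dependent; both modes are provided and the
  default (`nt`) is logged with every report.
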