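# neoivs

Computational companion to in vitro stimulation (IVS) screens for
neoantigen-reactive memory T cells in the peripheral blood of cancer
patients.

Such screens identify tumor-specific somatic mutations from exome/RNA
sequencing, express the mutant peptides in antigen-presenting cells via
tandem minigenes (TMGs), and use activation-marker sorting plus TCRβ
sequencing to find and track the reactive T-cell clones — which circulate
at frequencies as low as a few in a million, almost exclusively in the
memory compartment. `neoivs` implements the computational stages of that
workflow:

1. **Consensus variant filtering** — merge an ensemble of somatic callers
   (four for SNVs: Mutect, Strelka, Varscan2, SomaticSniper; two for
   indels: Strelka, Varscan2) and keep variants with tumor and normal
   coverage ≥ 10, tumor variant reads ≥ 4, VAF ≥ 7%, and (SNVs only) ≥ 2
   callers; COSMIC-catalogued variants pass regardless and are flagged as
   rescues.
2. **Neoepitope and TMG design** — for an SNV at protein position *p* of
   an *L*-residue protein, extract the mutant peptide of length
   min(12, p−1) + 1 + min(12, L−p) ≤ 25 (12-aa wild-type flanks where
   possible; a position-12 mutation like KRAS G12 gives a 24-mer). For
   indels, edit the cDNA and keep 12 wild-type residues before the
   mutation plus all novel residues up to the first stop codon, or to the
   transcript end if none occurs. Peptides are packed in order into TMGs
   of ≤ 16 minigenes and back-translated into nucleotide sequences free
   of EcoRI/BamHI sites (GAATTC/GGATCC) for cloning.
3. **Repertoire tracking** — read immunoSEQ-style or AIRR rearrangement
   TSVs, report known reactive TCRs as percent of productive templates
   per sorted subset (TN/TCM/TEM/TEMRA/bulk/TIL, "−" when absent), and
   compute productive clonality 1 − H/ln R (Shannon entropy over
   productive clone frequencies, normalized by log richness), with paired
   t-tests between subsets and single-cell-well TCR aggregation.
4. **Synthetic data** — a seeded generator producing transcriptomes,
   ground-truthed caller ensembles, and subset-structured repertoires
   with reactive clones spiked at 0.0007–0.02% into memory subsets, so
   the whole pipeline is testable offline.
5. **Pipeline** — a YAML-configured orchestrator (`validate_config()` /
   `run_pipeline()`) writing per-stage outputs and a JSON run manifest,
   plus a thin CLI at `inst/cli/neoivs` (subcommands `simulate`,
   `filter-variants`, `design-epitopes`, `track-tcr`, `run-all`).

## Worked example

Simulate a small screen, filter the variant calls, design TMGs, and track
the spiked reactive clones across sorted subsets:

```r
library(neoivs)

cfg <- sim_config(seed = 42, n_transcripts = 12, n_snv = 30,
                  n_insertion = 4, n_deletion = 4,
                  n_patients = 1, repertoire_depth = 2e4,
                  n_clones = c(TN = 4000L, TCM = 1600L,
                               TEM = 900L, TEMRA = 700L))

tx  <- gen_transcriptome(cfg)
sim <- gen_variants_and_calls(cfg, tx)
ev  <- merge_calls(sim$calls, sim$cosmic_keys, sim$rna_keys)
dec <- apply_filters(ev)                     # default thresholds 10/10/4/7%/2
sum(dec$passed)
#> [1] 38

cv     <- sim$coding_variants[
  sim$coding_variants$variant_key %in% dec$variant_key[dec$passed], ]
design <- design_neoepitopes(tx, cv)
tmgs   <- assemble_tmgs(design$epitopes, capacity = 16)
design$epitopes[[1]]
#> <neoepitope TX001:324:A>C GENE001 E108D: 25 aa, mutant 13-13>
tmgs[[1]]
#> <TMG-1: 16 minigenes, 391 aa, 1179 nt>
```

The first passing SNV (E108D, an interior substitution) yields the full
25-mer with the mutant residue at position 13; sixteen such minigenes
concatenate into TMG-1, whose 1179-nt realization starts with ATG, ends
with a stop codon, and contains no EcoRI/BamHI site.

```r
reps   <- gen_repertoires(cfg)
track_known_tcrs(reps$samples, reps$known, match_mode = "nt")
#> Known-TCR tracking (nt match), % of productive templates
#>                  P01_TN P01_TCM P01_TEM P01_TEMRA
#> P01_reactiveTCR1 −      −       −       −
#> P01_reactiveTCR2 −      0.01074 0.01564 0.01011

cl <- sapply(reps$samples, function(s) productive_clonality(s)$clonality)
round(setNames(cl, sapply(reps$samples, `[[`, "subset")), 3)
#>    TN   TCM   TEM TEMRA
#> 0.200 0.458 0.578 0.585
```

Reactive clone 2 was spiked at ~0.01% and is recovered in every memory
subset but — by construction, and as observed in patients — never in the
naive (TN) compartment; clone 1's spike frequency fell below this
sample's detection floor. Clonality rises monotonically from naive to
terminally differentiated effector memory cells.

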