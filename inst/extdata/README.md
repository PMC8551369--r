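# Packaged reference tables

Small plain-text fixtures holding published summary values for the
*Dinizia jueirana-facao* (Fabaceae) stand at Reserva Natural Vale, Brazil —
the small, spatially mapped population of a critically endangered
hermaphroditic tree whose ddRAD SNP study motivates this package. They let
the classification, coefficient-of-variation and dispersal-algebra routines
be exercised against real published outputs without the underlying genotype
data (deposited elsewhere; not required by this package).

- `djf_md_maf_sensitivity.tsv` — per-cell summary of the 35 data sets of the
  missing-data (0–20%) by minor-allele-frequency (0.05–0.35) filter grid:
  SNP counts, first-distance-class kinship F1, regression slope b (stored
  signed; the source prints magnitudes), R², and Sp for the Loiselle,
  Ritland and Queller–Goodnight estimators (n = 50 individuals).
- `djf_parentage_assignments.tsv` — the published maximum-likelihood
  parentage table for the 16 seedlings: the two top candidate parents with
  LOD scores, significance flags (`*` in the source), maternal flags (the
  nearer parent, bold in the source) and the pair-LOD significance flag
  (pair LOD printed as 0 when no pair met the criterion).
- `djf_sgs_cohorts.tsv` — cohort-level SGS summary (inbreeding F, F1, SE,
  Sp, Nb, sigma) with the census densities (ind/ha) and the Ne/N ratio 0.30.
- `djf_direct_dispersal.tsv` — direct-gene-flow summary constants: pollen
  and seed dispersal distance means/SDs, sigma_rt, the smallest combined
  parent-pair non-exclusion probability and the candidate-parent count.
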