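# wophage

Spectral-counting proteomics of *Wolbachia* WO prophage regions.

Arthropod-associated *Wolbachia* genomes carry WO prophages — integrated
phage genomes with head, baseplate, tail, recombination, replication,
DNA-modification and virulence modules. Shotgun LC–MS/MS of infected
cells yields *peptide evidence* (confident peptide identifications per MS
data set, matched to protein databases from several sequenced genomes),
and the question is whether the expressed proteins span entire prophage
modules — the signature of an intact, potentially lytic element — and how
abundant each protein is. `wophage` implements that analysis for anyone
working with label-free spectral counts and prophage annotation:

* **Matching**: in-silico tryptic digestion; exact-substring
  peptide-to-protein matching across homolog databases, with shared
  peptides credited to every containing protein (mosaic detections);
  sequence coverage as the union of peptide occurrence intervals;
  stringent (≥2 peptides in one data set) and relaxed (any peptide)
  detection filters; refined-search augmentation against new sequences;
  homolog-group aggregation.
* **Abundance**: the relative abundance level (RAL) — mean unique-peptide
  count over the K data sets — and the mass-normalized SR score: for
  observations across proteins i and data sets d,

  `log10(count_id) = b0 + b1·log10(mass_i) + class_i + set_d + e_id`

  is fit by least squares and each observation is scored by its
  externally studentized residual `t_id = e_id / (s_(id)·sqrt(1 − h_id))`;
  a protein's SR is the mean of its t values (0 = average abundance for
  its mass).
* **Classification**: locus-tag ranges assign proteins to prophage
  regions (WOMelA/B1/B2, WOPip1–5, orphan categories); a
  region-by-functional-class tally with margins and percentage roll-ups.
* **Sequence comparison**: global/local percent identity with
  BLASTn/BLASTp-like scoring, concatenated syntenic-array identity,
  intergenic layout (gaps/overlaps), and a maximal direct-repeat finder.
* **Synthetic data**: a generator with known ground truth (four data
  sets, Poisson detection increasing with true abundance and protein
  mass, homolog groups, confidence flags) so the whole pipeline is
  testable offline.

## Worked example

Classify the packaged proteome table (a synthetic per-protein
transcription of the published region-by-class cell counts) and roll it
up:

```r
library(wophage)
ann <- wo_proteome_classes()
cls <- data.frame(locus_tag = ann$locus_tag,
                  region = assign_region(ann$locus_tag), class = ann$class)
t <- region_tally(cls)
t
#>                HEAD BP TAIL REC REP MOD VIR UK Total
#> MelA              2  2    0   1   0   1   1  3    10
#> MelB1             4  0    4   0   3   2   4  9    26
#> Rick              0  0    0   0   0   0   5  4     9
#> MelB2             0  2    0   1   0   0   1  0     4
#> Pip1              0  0    0   1   1   0   1  5     8
#> Pip2              2  1    0   0   0   1   0  0     4
#> Pip3              3  1    0   0   0   0   2  1     7
#> Pip4              3  2    2   1   1   2   1  5    17
#> Pip5              3  1    3   0   0   1   2  7    17
#> MelOrphans        0  0    0   0   0   0   1  4     5
#> PipOrphans        1  0    0   2   0   0   0  1     4
#> Ana/SimOrphans    2  0    1   1   0   0   1  2     7
#> Total            20  9   10   7   5   7  19 41   118
class_percentages(t, c("HEAD", "BP", "TAIL"))   # structural share
#> [1] 33
class_percentages(t, c("REC", "REP", "MOD"))    # DNA-metabolism share
#> [1] 16
```

Head + baseplate + tail proteins make up a third of the detected prophage
proteome — all structural modules are expressed. (The printed cells of
the transcribed table sum to 118 proteins even though its printed grand
total says 119; the tally reports what the cells sum to.)

Simulate a proteome with known abundances, run the spectral-counting
pipeline on it, and check recovery:

```r
cfg <- sim_config(n_proteins = 200, seed = 1)
p   <- generate_proteome(cfg)
ev  <- simulate_detection(p, cfg)
dm  <- map_peptides(ev, p$db)
agg <- aggregate_by_group(dm, p$groups)
rep <- abundance_report(agg, db = p$db)
head(rep[order(-rep$sr), c("locus_tag", "mass_kda", "total_peptides", "ral", "sr")], 5)
#>     locus_tag mass_kda total_peptides  ral   sr
#> 152   SYN0152     33.4             51 47.0 2.25
#> 92    SYN0092     41.3             65 62.8 2.10
#> 79    SYN0079     37.9             63 45.8 2.01
#> 183   SYN0183     66.7             99 92.8 1.93
#> 30    SYN0030     51.9             85 68.2 1.86

m <- merge(rep, p$truth, by.x = "locus_tag", by.y = "group")
cor(m$sr, m$log10_abundance, method = "spearman", use = "complete.obs")
#> [1] 0.944
```

The SR ranking recovers the true abundance ranking (Spearman ≈ 0.94)
even though raw counts are confounded with protein mass. Sequence
utilities follow the same style:

```r
find_direct_repeats("ACGTACGT", min_len = 4)
#>   pos1 pos2 length mismatches
#> 1    1    5      4          0
align_identity("ACGT", "ACGA")$identity_pct
#> [1] 75
```

A thin command-line wrapper over the same stages ships in
`inst/scripts/wophage.R` (subcommands `simulate`, `match`, `score`,
`classify`, `pipeline`).

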