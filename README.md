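# POHselect

Mate selection and forward-in-time simulation for conservation breeding,
built around the **probability of offspring heterozygosity (POH)**.

## The problem

Small closed populations — endangered livestock breeds, zoo stocks, companion
breeds with narrow founder bases — lose heterozygosity to drift and
inbreeding. Genetic management traditionally picks matings that minimise a
parental relatedness measure. POHselect implements and studies an
offspring-centred alternative: score every eligible sire × dam pair by the
probability that a Mendelian offspring is heterozygous at a panel of unlinked
biallelic SNPs, and breed the top pairs. The intended users are conservation
geneticists and breed managers who have SNP dosage data (PLINK `.raw`-style
0/1/2 coding) for their candidate breeders, and methods researchers who want
to probe how the criterion behaves over many generations.

## The statistic

For one biallelic locus with genotypes coded as the dosage of allele B
(0 = AA, 1 = AB, 2 = BB), Mendelian segregation gives, for a parental pair
(g₁, g₂):

- POH = 1 if {g₁, g₂} = {0, 2} (opposite homozygotes — every offspring AB),
- POH = 0 if g₁ = g₂ ∈ {0, 2} (identical homozygotes),
- POH = 0.5 whenever at least one parent is heterozygous.

For a panel of L unlinked SNPs, the pair score is the mean over loci. The
comparator criterion is the proportion of shared alleles,
ASp = 0.25 × (number of shared alleles), averaged over loci and *minimised*;
a `random` mode is the drift control. Population status is tracked by
observed heterozygosity H_OBS (fraction of heterozygous calls) and expected
heterozygosity H_EXP = mean over loci of 2pq (gene diversity, ≤ 0.5 for
biallelic loci). Each generation, the BP top-ranked pairs are seated greedily
under two constraints — no littermate matings, each individual at most once —
and replaced by their BP × Li offspring (non-overlapping generations).

See `vignettes/poh-selection.Rmd` for the full model description, design
choices and limitations.

## Worked example

Score a small cohort (a bundled synthetic 8-dog table) into a mating plan,
seat three breeding pairs, and run a replicated long-horizon simulation:

```r
library(POHselect)

pop <- loadPopulation(system.file("extdata", "synthetic_cohort.tsv",
                                  package = "POHselect"))
pop
#> Population: 8 individuals (4 M / 4 F) x 6 loci, generation 0
#>   hObs = 0.5208, hExp = 0.4701

head(matingPlan(pop), 5)
#>    maleId femaleId   POH   ASp
#> 15 F0_003   F0_008 0.667 0.167
#> 7  F0_003   F0_006 0.583 0.250
#> 1  F0_001   F0_005 0.583 0.292
#> 12 F0_004   F0_007 0.583 0.333
#> 9  F0_001   F0_007 0.500 0.250

set.seed(7)
selectPairs(pop, 3, "POH")
#> SelectionOutcome: 3 pairs, mode POH, mean POH score 0.6111
#>   male female maleId femaleId       poh       asp     score
#> 1    3      8 F0_003   F0_008 0.6666667 0.1666667 0.6666667
#> 2    4      7 F0_004   F0_007 0.5833333 0.3333333 0.5833333
#> 3    1      5 F0_001   F0_005 0.5833333 0.2916667 0.5833333
```

The plan ranks every non-littermate sire × dam pair by mean POH (0.667 here
means two thirds of this pair's offspring genotype calls are expected to be
heterozygous across the 6 loci); `selectPairs()` then seats disjoint pairs
greedily, so the second-best pair for an already-seated male is skipped.

```r
base <- synthesizeBase(seed = 1)          # 29 M + 41 F, 51 SNPs, MAF ~ U(0.4, 0.5]
res <- runReplicates(base, SimCondition(51, 10, 4, 200, "POH", seed = 1), 10)
res
#> TrajectoryResult: M51-BP10-Li4-Ge200, mode POH, 10 replicate(s)
#>   final generation 200: mean hObs = 0.5468, mean hExp = 0.4672

round(aggregated(res)[c(1, 2, 101, 201), ], 4)
#>     generation   hObs   hExp meanPairPOH
#> 1            0 0.4801 0.4891          NA
#> 2            1 0.6022 0.4820      0.5980
#> 101        100 0.5428 0.4689      0.5440
#> 201        200 0.5468 0.4672      0.5441
```

With ten breeding pairs and litters of four, POH selection lifts observed
heterozygosity above its founder value in one generation and holds it there:
`hObs` stays near 0.54 — above the base population's 0.48 — while gene
diversity `hExp` is roughly maintained. The `meanPairPOH` column is the mean
score of the breeders seated *from* each generation, i.e. the expected
`hObs` of the next one.

The same experiments run from the shell:

```sh
Rscript inst/scripts/pohsel simulate --cond M51-BP10-Li4-Ge1000 \
    --mode POH --runs 50 --seed 1 --base synthetic --out runs/bp10
Rscript inst/scripts/pohsel plan --table my_cohort.tsv --out plan.tsv
Rscript inst/scripts/pohsel compare --cond M51-BP5-Li4-Ge1000 \
    --modes POH,ASp,random --runs 50 --seed 1 --out runs/cmp5
```

Each output directory gets a `manifest.tsv`; `rerunManifest()` replays it
bit for bit.

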