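# mitolineage

Tracing a maternally inherited mitochondrial point mutation through a
livestock population — and asking whether its carriers differ.

When a homoplasmic mtDNA variant is found in a closed breed (here, the
motivating case is an ND4L substitution in a local cattle breed that is
homologous to a human mutation causing Leber's hereditary optic
neuropathy), the analytical chain looks like this:

1. **Pedigree**: mtDNA travels along dam links only, so the carrier set is
   a *matriline* — the dam-edge connected component of a founder cow.
   `mitolineage` parses ragged herd-book pedigrees, finds matriline
   founders and lineages, counts lineage births per year against the whole
   cohort, extracts maternal paths across generations, infers expected
   carriers from a handful of genotyped animals (surfacing conflicts), and
   computes longevity in completed calendar months.
2. **Sequence evidence**: per-site base counts are classified as
   homoplasmic or heteroplasmic (`classify_site()`; a site is
   heteroplasmic when the minor allele clears a fraction, a count and a
   depth threshold simultaneously), coding consequences are annotated
   under the vertebrate mitochondrial genetic code (TGA→Trp, AGA/AGG→stop,
   ATA→Met), positions are lifted between species' mitogenomes by global
   alignment, diagnostic primers are checked by in-silico PCR on the
   circular molecule, and whole mitogenomes are diffed with
   heteroplasmy-aware classification.
3. **Breeding values**: the carrier group's mean estimated breeding value
   per trait is placed against the distribution of means of 10,000 random
   equally sized subsets of non-carriers; the equal-tailed 95% interval of
   that null distribution is the credibility interval, and the report
   records whether the observed mean falls inside, and on which tail.
4. **Synthetic data**: a generator produces pedigrees with strict maternal
   haplotype transmission (plus a ground-truth birth ledger), pileups with
   binomial sequencing noise, and Gaussian breeding-value tables, so the
   whole chain is testable without herd data.

The model notation, parameter defaults and design choices are documented
in the methods vignette (`vignettes/mitolineage-methods.Rmd`).

## Worked example

```r
library(mitolineage)

# a synthetic herd: 10 founder dams, recorded window 1997-2020
sim <- simulate_pedigree(pedigree_sim_params(n_founder_dams = 10, seed = 11))
ped <- sim$pedigree
ped
#> Pedigree with 276 animals ( 0 synthesized founder records )
#>  females: 129  males: 147  unknown: 0

lin <- maternal_lineage(ped, "F001")
lin
#> Maternal lineage of F001 - founder F001 - 17 members

tail(lineage_annual_stats(ped, lin, 1997:2020), 3)
#>    year lineage_births total_births proportion
#> 22 2018              1           24 0.04166667
#> 23 2019              0           23 0.00000000
#> 24 2020              1           25 0.04000000

# the classic mixed-allele pileup: 2317 A vs 3970 G reads at one site
classify_site(data.frame(position = 11081, A = 2317, C = 0, G = 3970, T = 0),
              ref_base = "G")
#> pos 11081  ref G  major G  heteroplasmic  minor A (0.3685)  depth 6287

# breeding values: one trait carries a planted -0.5 SD carrier shift
bv <- simulate_bv(bv_sim_params(lineage_shift = c(body_frame = -0.5), seed = 11))
run_all_traits(bv$mutant, bv$normal, c("withers_height", "body_frame"),
               resampling_config(reps = 10000, seed = 11))
#> Breeding-value comparison, 2 trait(s), 10000 replicates, level 0.95
#> withers_height: observed mean 0.103, 95% CI [-0.273, 0.300] -> within (tail inside, 0.2746)
#> body_frame: observed mean -0.465, 95% CI [-0.315, 0.268] -> outside (tail left, 0.0016)
```

Reading the output: the lineage's share of each birth cohort is the
fraction of that year's calves born into the matriline; the pileup call
says the site carries a genuine two-allele mixture (minor fraction 0.37 of
6287 reads, far above the error-rate floor); and the trait report shows
the unshifted trait sitting comfortably inside the 95% credibility
interval while the shifted trait falls outside it on the left tail, with a
tail fraction of 0.0016 (share of null means at or beyond the observed
mean, with the +1 correction).

A YAML-driven orchestration layer (`read_run_config()` / `run_pipeline()`
with subcommands `lineage`, `variant`, `consequence`, `pcr`, `map`,
`bvtest`, `simulate`, `report`) writes TSV/JSON artifacts that embed the
seed and a configuration digest; `inst/cli/mitolineage.R` is a thin
Rscript wrapper around it.

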