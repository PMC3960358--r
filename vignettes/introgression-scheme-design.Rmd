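---
title: "Designing marker-assisted backcross schemes for introgression-line populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing marker-assisted backcross schemes for introgression-line populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsim)
```

## The problem

An introgression library is a panel of lines that each carry one short,
marker-defined chromosome segment from an exotic donor in an otherwise
recurrent-parent (recipient) background, with the segments jointly tiling
the donor genome. Such panels are built by marker-assisted backcrossing
followed by line fixation, and they are expensive: every generation costs
field capacity and high-throughput (HT) genotyping assays, and with
realistic population sizes the final panel always deviates from the ideal
(segments are lost, extra donor fragments drag along, and with selfing the
lines retain residual heterozygosity). `ilsim` simulates complete crossing
programs so that the trade-offs between crossing depth, population sizes,
selection strategy and line-development method can be quantified before any
seed is sown.

## Genetic model

The default genome is maize-like: 10 chromosomes of 200 cM, fully
polymorphic codominant markers every 1 cM, and 20 cM target segments tiling
each chromosome (100 segments, 10 per chromosome). Markers sit at
segment-interior positions 0.5, 1.5, ..., 199.5 cM. The interior phase is a
design choice the map does not force: it gives every target segment exactly
20 markers and leaves no marker ambiguously on a boundary between two
segments or chromosome halves. All geometry is configurable through
`il_map()` as long as segments divide chromosomes and the marker spacing
divides the segment length.

Meiosis follows the Haldane model: per chromosome the crossover count is
Poisson with mean equal to the map length in Morgans (2.0 for a 200 cM
chromosome), crossover positions are independently uniform, the starting
strand is chosen with probability 1/2, and there is no interference and no
obligate chiasma. The implied recombination fraction between markers $d$ cM
apart is $r = (1 - e^{-2d/100})/2$, which the test suite verifies
empirically at 1–100 cM. Backcrosses to the recipient skip meiosis on the
recipient side (a fully homozygous parent transmits a constant gamete).
Doubled haploids (DH) double one simulated gamete — one viable DH line per
backcross individual, the conservative rate for *in vivo* maternal haploid
induction in maize. F3 lines are produced by two selfing generations: one
F2 and one F3 individual per family slot.

## Selection machinery

Selection operates on *regions*: 10 complete chromosomes (strategy letter
C), 20 chromosome halves (H) or the 100 target segments (S). For a
genotype and region $R$ the index is

$$ i_R = d(R) + \bigl(1 - d(B)\bigr), $$

where $d(\cdot)$ is the donor allele dosage (heterozygous markers count
1/2) of the region and of the background $B$ — all markers outside $R$,
genome-wide. Both terms carry unit weight, so donor content of the region
and recovery of the recipient background count equally; the weight pair is
exposed (`weights`) for sensitivity analysis. The index ranges over
$[0, 2]$: the recipient scores exactly 1, and 2 requires homozygous donor
across the region in an otherwise clean background.

Three structural choices shape how truncation selection is applied; all
three were settled by reproducing the published behaviour of entire scheme
families rather than by any single number:

* **Distinct winners.** The best individuals per region are taken greedily
  in decreasing index order and *one individual can be selected for at most
  one region*. For DH derivation this is physically forced (one backcross
  plant yields one line); we apply it in all generations, because an
  individual carrying donor material across two regions would otherwise
  found both sub-programs and make the resulting populations more uniform
  than real programs are. `select_per_region(distinct = FALSE)` restores
  independent per-region selection.
* **Branch confinement without pre-splitting.** After the first selected
  generation the program is branched: each selected individual is
  backcrossed to found the sub-population of its region, and later
  selection for a region considers its containing branch's full
  sub-population. We do not pre-split a branch into smaller per-region
  sub-pools when the selection system becomes finer (`split_finer = FALSE`
  by default); pre-splitting weakens selection measurably and is available
  as a sensitivity switch.
* **Library assembly pools by sub-program.** The final population takes, for
  each of the 100 target segments, the line with the highest segment index
  $i_S$, each physical line serving at most one segment (greedy matching in
  score order, seeded random tie-breaks). Candidates for a segment are the
  lines of the chromosome- or half-level lineage branch containing it;
  segment-level selection in the last backcross generation structures
  parents within a branch but does not narrow the library pool. Exhausted
  or absent pools fall back to the best unused line overall.

## The scheme catalogue

`scheme_catalogue()` reconstructs 32 crossing schemes: four series × two
line-development methods × the strategy sets shown by
`builtin_scheme()`. Population-size profiles per backcross generation:

| series            | sizes            | selection                      | lines |
|-------------------|------------------|--------------------------------|-------|
| `basic`           | 360 / 360 (/360) | all but final BC               | 360   |
| `high_intensity`  | 720 / 720 / 720  | all but final BC               | 720   |
| `final_selection` | 360 (/360) / 720 DH or 360 F3 | every BC          | 360   |
| `increasing`      | 120 / 240 / 720  | every BC                       | 360   |

One HT assay genotypes one individual at all markers; `ht_count()` sums the
genotyped generations (selected backcross generations plus the line
generation) in closed form, and the simulation ledger reproduces it
exactly. Intermediate selections take one individual per region; where the
final backcross generation is selected, DH schemes take
`lines/regions` per region (remainders to the lowest-indexed regions) while
F3 schemes take one per region and allot equal F2 family slots summing to
the line-generation size — selfing produces many progeny per selected
plant, which is exactly the economic advantage of F3 over DH schemes in
this setting. One catalogue entry is knowingly approximate: the published
increasing-size F3 scheme with segment selection consumes 40 fewer assays
than our 120/240/720/360 profile implies; the exact composition behind that
number is not recoverable from the stated size rules, so the common profile
is used and the difference documented.

## The nine measures

`measure_report()` evaluates a final population with the conventional
measures: donor genome coverage $C_D$ (% of markers carried by at least one
IL), coverage depth (mean carrier count per locus, averaged over all loci;
a donor-covered-only variant is exposed as a flag), the number of disjunct
genome segments $N_D$, resolution $R = L/N_D$ for total map length $L$,
donor segments per IL $S_D$ and their mean length $L_D$, and the donor
genome proportions genome-wide ($\lambda_D$), on the carrier chromosome
($Z_C$) and within the assigned target segment ($Z_S$). Carrier status is
presence-based (a heterozygous marker carries donor); proportions are
dosage-based (heterozygous = 1/2). This split makes the DH identity
$\text{depth} = N_{IL}\,\lambda_D/100$ exact for homozygous populations
while letting F3 populations show larger depths.

$N_D$ is formalised as the number of maximal marker intervals within which
the joint genotype pattern of every haplotype of every IL is constant (per
chromosome: distinct internal breakpoints + 1). This reproduces
$R = L/N_D$ by construction, is breakpoint-sharing aware, and rises sharply
with residual heterozygosity, as the published F3 results show. Because the
source defines $N_D$, $S_D$ and $L_D$ only verbally, these three are
validated against brute-force oracles on small random populations rather
than against printed values.

## Replication, determinism, problem sizes

`run_replications()` runs each scheme on deterministic per-replicate seed
substreams derived from one master seed: the whole experiment is
bit-reproducible, and any single replicate can be re-run in isolation via
`replicate_seed()`. All randomness (crossover counts and positions, strand
choices, tie-breaks) flows through R's RNG, so a seed fixes every path
through C++ and R alike.

The published study aggregates 1000 replicates per scheme. The package's
own acceptance checks use 200 replicates per scheme across the full
32-scheme catalogue, chosen so that the Monte-Carlo standard errors of the
reported means (about 0.02 for $\lambda_D$, about 0.1 for $Z_S$) sit well
below the 0.1/1-unit precision at which the reference values are printed.
Property checks (Haldane fractions, backcross dosage $2^{-(t+1)}$,
selfing heterozygosity) use $10^4$–$4\times 10^4$ gametes or individuals
and 3-standard-error bands.

## What the simulation does and does not emulate

The generator reproduces the study conditions: equal chromosome lengths, a
perfectly even fully informative marker grid, error-free genotyping,
no interference, guaranteed DH success, and non-overlapping 20 cM targets.
Real programs face unequal chromosomes, marker dropout and genotyping
error, crossover interference, DH induction failure, and physical/genetic
map distortions — none of which are modelled. Passing tests therefore
demonstrate fidelity to the idealised model, not field performance;
measured on real data, coverage would be lower, backgrounds dirtier and HT
budgets higher than simulated. Within the model, the known remaining gaps
to the published table are small and systematic: the basic BC2-F3
half-selection scheme runs about half to one point high in $Z_S$, and the
increasing-size F3 segment scheme discussed above sits about 2.5 points low
in $Z_S$ and just under 2 points low in $Z_C$ at its reconstructed sizes;
all other schemes reproduce the published $\lambda_D$, $Z_C$, $Z_S$ and
$N_D$ within a few tenths of their printed values.

## A worked example

```{r example, eval = FALSE}
library(ilsim)

ex <- run_replications(c("basic-bc3-dh-cc", "incr-bc3-dh-hhh"),
                       n_replicates = 200, seed = 1)
measure_table(ex)
plot_zs_distribution(ex)

run <- run_scheme(builtin_scheme("incr-bc3-dh-hhh"), seed = 1)
autoplot(run$ils, ils = 41:70, chroms = 3:7)   # graphical genotype
```
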