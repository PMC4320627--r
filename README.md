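# chipregulon

Downstream analysis of transcription-factor ChIP-seq experiments on
gene-dense bacterial genomes, written for microbial regulatory genomicists
who have per-replicate peak calls (or aligned read starts) and a genome
annotation, and want to go from those to a defensible regulon map: which
peaks reproduce across replicates, which genes they likely regulate, whether
their placement is non-random, which functional categories and curated gene
lists are enriched among the targets, and what binding motif the sites
share.

The pipeline mirrors the classic analysis of a CRP-family regulator in a
myxobacterium, where >90% of the chromosome is coding sequence, so naive
"peaks fall between genes" reasoning needs an explicit randomized null.

## What it computes

**Peak calling (optional).** Strand-shifted read starts are smoothed with a
Gaussian kernel density (`stats::density`, bandwidth *h* = 30 bp, shift 50
bp); peaks are local maxima where chip density exceeds a fold threshold over
a depth-scaled control plus a pseudocount floor. The false-positive rate of
the procedure is estimated by partitioning the control in half and calling
one half against the other.

**Replicate concordance.** For replicate peak lists *A*, *B* the package
computes nearest-neighbour distance distributions and retains mutual
nearest-neighbour pairs with |x_A − x_B| ≤ 65 bp; each merged peak gets the
averaged coordinate and an overall rank from the mean replicate enrichment.

**TSC annotation.** Every merged peak is classified coding/non-coding
against the half-open coding spans, given a signed distance *d* to the
nearest predicted translation start codon (TSC; *d* < 0 is upstream in the
gene's reading orientation), and assigned to genes whose promoter window
[−400, +100] around the TSC contains it — including divergently transcribed
gene pairs that share the site, and with operon-aware collapsing of gene
lists to promoter regions.

**Placement null.** A Monte Carlo null draws the same number of uniform
random coordinates and measures the same quantities; the observed vs random
coding/non-coding split is tested with Fisher's exact test.

**Enrichment.** For a category or gene list with *n* genes genome-wide, the
expected number near a binding site is *n* × (near_total / genome_total),
and significance is the two-sided Fisher's exact test on the gene-level 2×2
table (gene counted once regardless of how many peaks hit it).

**Motif discovery and scanning.** Sequences of 2×50+1 bp around the
top-ranked peak maxima are searched by expectation-maximization under the
OOPS model (one occurrence per sequence, both strands, 0-order background
from input composition, Dirichlet-pseudocount M-step, ±1 column-shift
refinement). The resulting position weight matrix is summarised by
per-column information content (bits) and a degenerate IUPAC consensus,
which can be scanned over arbitrary sequence on both strands
(`Biostrings` matching).

A first-class synthetic-data generator (`synthesize_study()`) builds a 1 Mb,
800-gene, 90%-coding genome with 150 planted TGTYN₈RAC-motif sites, jittered
replicate peak lists, functional categories with one planted enriched
category and gene lists with one planted 1.7× list, so the whole pipeline is
testable with recorded ground truth.

## Worked example

```r
library(chipregulon)
demo <- demo_pipeline(seed = 1)

demo$study
#> <synthetic_study> 800 genes / 1,028,951 bp, 150 true sites (112 shared), 181+181 peaks

demo$result
#> <pipeline_result> 112 merged peaks (73 coding / 39 noncoding); 89 promoter sites, 24 divergent, 117 genes
#>   motif: TGTYNNNNNNNNRAC (total IC 11.7 bits)

demo$result$report
#>   n_rep1 n_rep2 n_merged cutoff retained_fraction median_distance   f30
#> 1    181    181      112     65             0.619               6 0.605
```

Of the 181 peaks per replicate, 112 mutual nearest-neighbour pairs survive
the 65-bp cutoff (the 112 shared true sites; every planted shared site is
recovered), with a median replicate distance of 6 bp. 89 of the 112 merged
peaks sit in a promoter window, 24 of them between divergent genes, linking
117 distinct genes.

```r
glance(demo$result$null)
#>   n_sites n_replicates fisher_p  mean_coding_prop ...
#> 1     112            1 9.81e-06             0.902

demo$result$list_enrichment
#>   label             n_genome n_observed n_expected_raw n_expected p_value
#> 1 up_regulated            45         13           6.58          7  0.0144
#> 2 down_regulated          45          5           6.58          7  0.664
#> 3 directly_involved       20          2           2.92          3  0.754
```

Random placement puts 90% of sites in coding sequence (the genome's coding
fraction) versus 65% observed — Fisher p ≈ 1e-5 — and the planted
"up_regulated" list shows 13 observed vs 7 expected promoter-hit genes, the
most significant of the three lists. The discovered motif's consensus is
exactly the planted imperfect palindrome TGTYN₈RAC; `autoplot(demo$result$motif)`
draws the information-content logo.

For real data, replace the generator with your own files:

```r
genome <- read_gff3("genome.gff3", category_table = "categories.tsv",
                    sequence = "genome.fasta")
rep1 <- read_peaks("peaks_rep1.tsv", "rep1")
rep2 <- read_peaks("peaks_rep2.tsv", "rep2")
res <- run_pipeline(rep1, rep2, genome,
                    config = analysis_config(rng_seed = 1),
                    out_dir = "results/")
```

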