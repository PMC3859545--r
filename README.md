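# plateletseq

Comparing what two RNA-seq library chemistries say about the same
transcriptome — here, the platelet transcriptome, where one unstranded
oligo-dT (polyA+) library is set against three strand-specific
rRNA-depleted total RNA libraries. Oligo-dT capture concentrates read
starts towards each transcript's 3′ end, so raw counts and FPKM-style
units are not comparable across the two protocols: without correction,
length-dependent "differential expression" appears out of thin air. The
package is for analysts who need to model that bias explicitly, quantify
both library types on a common scale, and test for differential
expression with small replicate numbers.

Everything runs on a seeded synthetic dataset shaped like the study
design (one polyA+ sample S0, three total RNA samples S1–S3, one of them
female; massive mitochondrial over-representation), so the whole pipeline
is exercised end to end with no external data.

## The model

Read-start density at distance *u* upstream of a polyA site:

    f(u) ∝ exp(−λ·u),   λ = 0.0027638 per bp by default
                        (half-decay ln2/λ ≈ 251 bp)

which yields, for a transcript of length *L*:

- capture deficit `1 − exp(−λL)` — short transcripts are under-counted;
- **NRC** (normalized read count, polyA+): `count · (1 + exp(−λL))`;
- **FPKM** (total RNA): `count · 1e9 / (L · N)`;
- **adjusted counts** for cross-protocol testing: NRC for polyA+ columns,
  reads-per-kilobase (`count · 1e3 / L`) for total RNA columns, with
  sequencing depth handled once, by median-of-ratios size factors.

λ is estimated by OLS of log count on position over the transcript body
(`fit_decay()`), polyA sites are called from drops in binned log10
coverage (`detect_polya_sites()`), isoform usage is deconvolved from
segment coverage under the decay model (`isoform_abundance_ratio()`), and
differential expression uses an exact-style conditioned negative-binomial
test with a fitted mean-dispersion curve (`nb_test()`), BH-adjusted at a
10% FDR.

## Worked example

```r
library(plateletseq)

cfg <- simulation_config(seed = 1)          # 60 genes, 2e5 reads/sample
ann <- generate_annotation(cfg)
reads <- simulate_read_starts(ann, cfg)

# decay fit on the long single-site reference gene of the polyA+ sample
ref <- ann$transcripts[["ACTB.t1"]]
prof <- simulate_polya_profile(ref, 2e5, lam = cfg$lam, seed = 1)
fit_decay(prof)
#> <decay_fit> lam=0.0027600 per bp (half-decay 251.1 bp)
#>   slope=0.0027600  SE=0.0000128  t=215.62  p=2e-49  r=1.000  n=32  trims=130/100
```

The refit recovers the generating rate (0.0027638/bp) within one standard
error; coverage halves about every 250 bp. Running the numbered analysis
scripts from the repository root:

```sh
Rscript analysis/01_simulate_data.R      # GTF + BED + counts under results/
Rscript analysis/02_decay_model.R        # decay fit, polyA calls
Rscript analysis/03_quantification.R     # contig/MT accounting, NRC/FPKM, correlation
Rscript analysis/04_sex_differential_expression.R
Rscript analysis/05_protocol_comparison.R
```

prints, among other things:

```
per-sample MT read share: S0=63.6%  S1=9.0%  S2=8.9%  S3=9.0%
polyA sites called at 800, 1300 (truth: 708, 1307); usage ratio 110:1
replicate FPKM correlation S1 vs S2: Pearson(log) 0.99, Spearman 1.00 (n=41 genes)
2 genes differ between the sexes at 10% FDR:
  UTY      log2FC   -Inf  padj 2.4e-10
  DDX3Y    log2FC   -Inf  padj 1.8e-09
study-like data: 21 significant genes adjusted vs 50 unadjusted (10% FDR)
bias-only data: 3 significant genes adjusted vs 77 unadjusted (10% FDR)
```

Read bottom-up: the polyA+ sample is dominated by mitochondrial reads
(63.6% vs ~9% in total RNA); the two-site gene's polyA sites are located
to one 100-bp bin and its short isoform is ~100× the long one; total RNA
replicates correlate at 0.99; the only sex-differential genes are the
Y-linked ones, absent in the female sample; and the length-and-method
adjustment removes most protocol-artifact DE (77 → 3 significant genes on
data whose *only* systematic difference is the library chemistry).

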