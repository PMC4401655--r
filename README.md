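# hostpref

Statistical analysis of host-plant preference and community structure of
root-associated fungi from amplicon survey data.

Root samples collected along a transect yield a sample × fungal-OTU
read-count table and a host-plant OTU per sample (host barcodes clustered
at nested similarity cutoffs: 99.8, 99, 98, 97%). Because hosts are
sampled unevenly, raw co-occurrence counts confound preference with
sampling effort. `hostpref` answers "does this fungus associate with
particular hosts more often than chance?" with a Bayesian
Dirichlet-multinomial model, and "does fungal community composition track
host genetic distance?" with null-model β-diversity and matrix
permutation tests. It is aimed at fungal/microbiome ecologists working
with OTU tables from root or soil surveys.

## The model

For fungal OTU *i* and plant OTU *j*, the occurrence counts
*y*<sub>i,·</sub> (number of samples of each host containing the fungus,
out of *N*<sub>i</sub> total occurrences) are multinomial with a conjugate
Dirichlet prior encoding random host selection in proportion to sampling
effort *T*<sub>j</sub>:

> α<sub>i,j</sub> = T<sub>j</sub> N<sub>i</sub> / Σ<sub>j</sub> T<sub>j</sub>

Per posterior draw, the normalized deviation from random selection is

> D̄<sub>i,j</sub> = (π<sub>i,j</sub> − E(π<sub>i,j</sub>)) /
> √( Σ<sub>j</sub> (π<sub>i,j</sub> − E(π<sub>i,j</sub>))² ),
> with E(π<sub>i,j</sub>) = T<sub>j</sub> / Σ<sub>j</sub> T<sub>j</sub>

which lies in [−1, 1]; D̂ is its posterior mean, credible intervals come
from the draw quantiles, and D̂max = max<sub>j</sub> D̂<sub>i,j</sub>
summarizes each fungus's strongest apparent preference. Posterior draws
come from the exact conjugate posterior by default, or from an MCMC
sampler (`mode = "gibbs"`) that serves as an independent cross-check, with
Gelman–Rubin convergence diagnostics.

Around the model: exact rarefaction with per-sample seeds,
presence/absence conversion, plant × fungal association matrices at each
clustering level, OTU accumulation curves, Table-style taxon frequency
tables with Fisher–Holm contrasts, Raup–Crick null-model β-diversity,
Mantel / partial Mantel tests (Spearman, permutation p), Moran's I along
the transect, and a synthetic-data generator with known ground truth.

## Worked example

Simulate a 240-sample transect where each of 120 fungal OTUs prefers one
of 8 host plant OTUs (weight 1 on the focal host, 0.25 elsewhere), then
recover the preferences:

```r
library(hostpref)

cfg0 <- simulation_config(n_samples = 240, n_plant_otus = c(8, 4, 2, 1),
                          n_fungal_otus = 120, host_frequencies = rep(1, 8),
                          abundance_ratio = 0.95, rng_seed = 20)
hosts <- generate_hosts(cfg0)
W <- preference_exclusive(120, 8, focal = rep_len(1:8, 120), background = 0.25)
cfg <- simulation_config(n_samples = 240, n_plant_otus = c(8, 4, 2, 1),
                         n_fungal_otus = 120, host_frequencies = rep(1, 8),
                         abundance_ratio = 0.95, preference_matrix = W,
                         rng_seed = 20)
sim <- generate_counts(cfg, hosts)

rar <- rarefy(sim$counts, depth = 100, seed = 20)
occ <- to_presence_absence(rar$counts)
assoc <- filter_min_occurrences(
  build_association(occ, hosts$hosts, level = "99.8"), min_n = 5)

pref <- compute_D(sample_posterior(assoc, draws = 5000, seed = 20))
tab <- as.data.frame(pref)
head(tab[order(-tab$D_hat), ], 5)
```

```
      otu     host     D_hat   ci95_lo   ci95_hi     ci99_lo   ci99_hi flag
585 F0070 P998.006 0.7952261 0.4503412 0.9199387  0.26923817 0.9286668    *
273 F0067 P998.003 0.7869459 0.4596497 0.9164385  0.30030095 0.9254754    *
801 F0080 P998.008 0.7682540 0.3955902 0.9175643  0.20237707 0.9265296    *
569 F0054 P998.006 0.7451673 0.3516076 0.9116001  0.13365767 0.9239055    *
101 F0105 P998.001 0.7228362 0.1211223 0.9280364 -0.04262996 0.9320229    +
```

Each row is one fungus–host pair: `D_hat` near 0.8 means the fungus is
found on that host far more often than its sampling share predicts; `*`
and `+` mark 99% and 95% credible intervals excluding zero. In this run
50 of 240 samples fall below the 100-read rarefaction depth and are
dropped, and 103 of the 120 fungi pass the 5-occurrence filter. For 85%
of the modelled fungi the host with the largest D̂ is the true simulated
focal host (the misses are the rarest fungi, whose few occurrences carry
little evidence):

```r
best_host <- colnames(pref$D_hat)[max.col(pref$D_hat)]
true_host <- sprintf("P998.%03d", rep_len(1:8, 120)[
  as.integer(sub("F", "", rownames(assoc)))])
mean(best_host == true_host)
#> [1] 0.8543689
```

Community-level structure follows the same grammar — with only 8 plant
OTUs the Mantel test has little power, but the positive rank correlation
between community dissimilarity and host genetic distance is visible:

```r
units <- pool_by_plant_otu(occ, hosts$hosts, "99.8")
rc    <- raup_crick(units, n_null = 999, seed = 1)
gdist <- generate_host_distances(hosts, cfg)
mantel_test(as.matrix(rc), gdist, n_perm = 9999, seed = 1)
#> r = 0.501, p = 0.088 (9999 permutations, one-sided)
```

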