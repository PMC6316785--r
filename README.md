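# lepisurv

Tools for comparing butterfly survey data-gathering approaches: trained-volunteer
transect counts (Pollard walks), passive Malaise trapping, and crowd-sourced
incidental observations (iNaturalist-style records). The package is aimed at
community ecologists and biodiversity-informatics practitioners who need to put
these incommensurable designs — sample-based presence/absence surveys versus
presence-only observation streams — on a common footing for species richness and
diversity comparison.

It provides:

- validated readers/writers for long-format survey tables and Darwin Core style
  occurrence records, with configurable column-name dialects;
- a staged occurrence-filtering pipeline (quality grade, family, date window,
  bounding box, coordinate uncertainty) with a per-stage audit trail, plus
  taxonomy reconciliation against a synonym map;
- richness and diversity statistics: per-site richness and Shannon's *H*, paired
  *t*-tests between methods, and incidence-derived summaries (source richness,
  singletons, source-exclusive species);
- a seeded bootstrap for comparing **pooled** species richness across designs,
  resampling whole sites for structured surveys and individual observations for
  incidental data;
- an occupancy–detection simulator that generates survey and occurrence data
  with known ground truth, so every pipeline stage is testable without any
  download.

## The statistics

For site *j* with abundance vector *n<sub>ij</sub>*, Shannon diversity is
*H<sub>j</sub>* = −Σ<sub>i</sub> *p<sub>ij</sub>* ln *p<sub>ij</sub>* with
*p<sub>ij</sub>* = *n<sub>ij</sub>*/Σ<sub>i</sub>*n<sub>ij</sub>* (natural log,
so *H* is in nats). Methods are compared site-by-site with the paired *t*-test
on differences *d<sub>j</sub>* = *x<sub>j</sub>* − *y<sub>j</sub>*:
*t* = mean(*d*) / (sd(*d*)/√*n*), df = *n* − 1.

Mean per-site richness can be recovered from a species × source incidence table
alone: the mean over sites of per-site richness equals the column sum of species
site-incidences divided by the number of sites.

For pooled richness across a whole study area, each source is bootstrapped with
its own resampling unit: a pseudoreplicate redraws the observed number of units
with replacement (16 sites for the structured methods, each observation for
incidental data) and records the pooled richness — the size of the species
union. Two bootstrap distributions are then compared with a pooled-variance
two-sample *t*-test; the resulting p-values are flagged as anti-conservative,
because pseudoreplicates are not independent samples.

## Worked example

The package ships the species × source incidence table of a published 16-site
urban butterfly survey (Los Angeles Basin, 15 March – 15 July 2015):

```r
library(lepisurv)

inc <- load_incidence_summary()
#> Species-by-source incidence summary: 30 species, 16 sites per method

source_richness(inc, "pollard")   # 27 of the 30 species seen on walks
source_richness(inc, "malaise")   # 18 in traps
source_richness(inc, "inat")      # 22 in incidental observations

mean_richness_from_incidence(inc, "pollard")  # 11.3125 species per site
mean_richness_from_incidence(inc, "malaise")  #  5.9375
singleton_count(inc, "pollard")               # 8 species at exactly one site
exclusive_species(inc, "inat")$species
#> "Adelpha californica" "Limenitis lorquini"
```

A calibrated synthetic world reproduces this table end-to-end from raw records,
including the realistic defects: 105 raw incidental records of which one (a
2,600,000 m coordinate-uncertainty blunder) falls at the uncertainty stage, and
two platform-synonym names repaired by reconciliation:

```r
world <- simulate_benchmark_world(seed = 1)
kept <- filter_records(reconcile_taxonomy(world$incidental),
                       filter_config(bbox = world$model$bbox))
filter_report(kept)[, 1:3]
#>   stage        n_in n_out
#> 1 quality       105   105
#> 2 family        105   105
#> 3 date_window   105   105
#> 4 bbox          105   105
#> 5 uncertainty   105   104

b_pol  <- bootstrap_site_richness(site_species_sets(world$survey, "pollard"),
                                  n_boot = 1000, seed = 2, source = "pollard")
b_inat <- bootstrap_observation_richness(kept$scientific_name,
                                         n_boot = 1000, seed = 3, source = "inat")
compare_bootstrap(b_pol, b_inat)
#> two-sample t-test (pooled variance): bootstrap richness of 'pollard' vs 'inat'
#> t = 65.94, df = 1998, p = 0, mean difference = 3.851
#> note: p-value is anti-conservative: bootstrap pseudoreplicates are not independent samples
```

The walk distribution sits well above the incidental one (mean pseudoreplicate
richness 24.0 vs 20.1 species), so even though 16 resampled sites never quite
reach the full pooled 27 species, the ordering of the sources is unambiguous.
`tidy()`/`glance()` methods return tibbles for all results, and `autoplot()`
draws the incidence frequency distribution and bootstrap histograms.

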