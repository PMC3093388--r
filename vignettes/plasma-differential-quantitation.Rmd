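---
title: "Methods: isotope-pair quantitation and confounder-aware differential calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-pair quantitation and confounder-aware differential calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaquant)
```

## The measurement model

In a heavy/light acrylamide experiment, case and control plasma pools
are labeled on cysteines with 13C and 12C acrylamide respectively,
combined, fractionated, and analysed together. Each quantified pair of
isotopic peptide signals — an *MS event* — yields a case/control
intensity ratio whose logarithm is the quantity of interest:

$$ r_{gij} = \log_2 \frac{I^{H}_{gij}}{I^{L}_{gij}} \approx \delta_g + \varepsilon_{gij}, $$

where $\delta_g$ is the true log2 abundance shift of protein (gene
symbol) $g$ and $\varepsilon$ is measurement noise across peptides $i$
and events $j$. The working assumptions are that noise is symmetric
around 0 on the log2 scale, approximately exchangeable across a
protein's events, and that the protein-level shift is shared by all its
peptides (isoform-specific shifts are not modelled — see Limitations).

The protein ratio is the unweighted mean of its quantitation-grade
event ratios. Protein groups are combined by common gene symbol,
case-sensitively after whitespace trimming, with no alias resolution:
upstream protein inference has already resolved groups, and an alias
table would silently merge distinct identifiers.

## The dual significance rule

Two tests address two failure modes:

* the **one-sample t-test** on a protein's event ratios (two-sided,
  $H_0: \mathrm{E}[r]=0$) asks whether the mean shift is resolvable
  given the protein's own event-to-event spread; it needs at least two
  events and nominally assumes approximate normality of the event
  ratios;
* the **empirical-null test** scores each event against the observed
  ratio distribution of a *control-control* experiment (one pool,
  split, labeled both ways — so every true ratio is 1). A protein
  passes when *every* event is individually extreme. This route needs
  no replication within the protein and is the only one open to
  single-event proteins, but it borrows its null from a separate
  experiment and assumes the noise scale carries over.

A protein is significant when either fires; the criterion that fired is
recorded per protein (`ttest`, `all-events`, `both`, `none`) so that
stricter readings (t-test only, or conjunction) can be reproduced from
the output without rerunning. The disjunction was chosen because the
two tests are presented as complementary coverage — the t-test for
multi-event proteins, the event rule for the remainder — rather than as
a joint requirement.

The empirical p-value is two-sided on $|r|$ with add-one smoothing,

$$ p = \frac{1 + \#\{r_0 \in \text{null} : |r_0| \ge |r|\}}{n_0 + 1}, $$

so increased and decreased proteins are treated symmetrically, $p$ is
never 0 from a finite null, and under the null $P(p \le x) \le x +
1/(n_0+1)$ (super-uniformity, which the test suite checks by
simulation). The t-test is two-sided for the same symmetry reason. With
zero variance and a nonzero mean the t statistic is unbounded; the
smallest representable positive double is reported with a warning
rather than 0, keeping $p \in (0, 1]$.

## Differential calling and thresholds

`filter_config()` collects the thresholds:

* `min_peptide_prob_quant = 0.75` — PeptideProphet probability gating
  quantitation; inclusive, so a probability of exactly 0.75 counts.
* `min_peptide_prob_ident = 0.2` — the identification-level threshold.
  It feeds only the "identified" tally; quantitation is gated by 0.75
  alone. The interaction between the two thresholds is genuinely
  underdetermined; recording 0.2 while letting 0.75 gate quantitation
  reproduces both tallies without conflating them.
* `max_protein_error_rate = 0.05` — protein-level identification error,
  applied as `protein_confidence >= 0.95` when that column exists.
  Error-rate modelling itself is upstream; when the column is absent
  the filter is skipped with a logged notice, and an event with a
  missing confidence is not penalised.
* `min_fold = 1.25`, `alpha = 0.05` — a protein is called increased
  when significant and $\bar r \ge \log_2 1.25 \approx 0.322$,
  decreased when $\bar r \le -\log_2 1.25$. The threshold is applied on
  the log2 scale and ties count as changed ("1.25-fold or greater").
* `rollup = "event"` — the protein mean and t-test run over all
  qualifying events. The alternative `"peptide"` averages within each
  peptide sequence first; it downweights peptides observed in many
  fractions but discards the within-peptide replication the t-test
  uses. Event-level is the default because the significance machinery
  is defined over events.

No multiple-testing correction enters the calls — the procedure filters
at raw p < α by design — but a Benjamini–Hochberg column (`p_bh`) is
emitted for information.

## Cross-model comparison

* **Universe.** Mass-spectrometry sampling is stochastic, so a gene
  missing from a model may simply be unsampled. Overlap percentages are
  therefore computed on a shared universe (by default the genes
  quantified in all compared models), while three-way Venn diagrams of
  differential calls deliberately do *not* restrict — both conventions
  are useful and both are first-class (`universe` argument / config
  flag).
* **Overlap.** "Percent overlap" is operationalised as the Jaccard
  index $100\,|A \cap B| / |A \cup B|$ of the altered (increased ∪
  decreased) sets; `method = "smaller"` gives the
  intersection-over-smaller-set alternative, and the pipeline reports
  both.
* **Correlation.** Pearson r of mean log2 ratios over genes quantified
  in both profiles; invariant to genes seen in only one.
* **Patterns.** Genes are classed A (up in ≥ 1 confounder, up in ≥ 1
  cancer model), B (up in confounders, down in cancer), C (down in
  confounders, up in cancer), or other; a gene unquantified in a model
  contributes no evidence there. When opposite calls across models make
  several labels apply, the gene is flagged as a conflict and all
  labels are listed — per-model evidence is never forced into a
  consensus.
* **Prioritization.** Genes altered in ≥ 1 cancer profile and in no
  confounder profile form the cancer-restricted candidate list, ordered
  by the maximum |mean log2 ratio| across cancer profiles (ties broken
  alphabetically); genes also altered in a confounder go to a separate
  "confounded" list rather than being dropped silently.

Cancer-side profiles may be supplied as reduced, already-called tables
(`read_differential_table()`), since their raw events typically belong
to earlier studies.

## The synthetic generator

`synth_config()` describes a simulated experiment with a
protein → peptide → event hierarchy and known truth:

* Each protein is increased (probability 0.12), decreased (0.30) or
  null; a 450-protein experiment then yields roughly a third altered
  with decreases outnumbering increases two-to-three-fold, matching the
  scale and class balance of deep plasma studies of inflammation and
  angiogenesis models (≈ 380–510 quantified proteins per model).
* True shifts are $\delta = \pm|N(0.65, 0.3)|$ log2 units — mostly
  above the 1.25-fold call threshold, as called alterations are.
* Counts are shifted-Poisson (minimum 1): mean 3 peptides/protein and 2
  events/peptide. No field-standard distribution exists for these; the
  shifted Poisson is the simplest count model with the right support.
  `min_events_per_protein` tops up short draws when a floor is needed.
* Event noise is Normal on the log2 ratio directly
  (`noise_sd = 0.3` log2 units), the pipeline's sufficient statistic;
  heavy = light · 2^ratio, so the drawn ratio is recovered exactly — a
  closed-form identity the tests rely on. A `two_channel_noise` mode
  adds independent lognormal noise per channel for robustness checks.
* Light intensities are lognormal (meanlog log(1e6), sdlog 1); peptide
  probabilities are Beta(8, 1), so a realistic minority of events falls
  below the 0.75 quantitation gate; protein confidences cluster near 1.
* `generate_multi_model()` assigns altered genes to designed Venn
  regions (which models, which direction) before event generation, with
  one shared shift magnitude per gene floored at 0.4 log2 units so the
  design is recoverable at low noise.
* One global seed; substream seeds are derived from it by a fixed
  `sample.int` draw so partial reruns reproduce.

What the generator does **not** emulate: correlated noise across a
protein's peptides, intensity-dependent ratio variance, missingness
that depends on abundance, shared-peptide ambiguity between proteins,
and isoform structure. Passing end-to-end tests therefore demonstrate
the pipeline's statistical behaviour under exchangeable log-scale
noise, not robustness to every artefact of real spectra.

## Numerical and implementation choices

* Empirical p-values use a sorted-|null| `findInterval` search —
  ties (|r₀| equal to |r|) count toward the extreme side, matching the
  ≥ in the definition.
* Profile TSVs serialise numerics with 17 significant digits, so a
  write/read round trip reproduces values to 1e-12.
* Ratio histograms use an odd number of equal-width bins placed
  symmetrically so the central bin straddles 0; counts conserve the
  event total.
* Degenerate inputs are warnings, not crashes, wherever the empty
  result is well-defined: an all-filtered event table, an empty
  profile, a single-ratio null.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: property checks use 10⁴ null draws against a ~2,400-event
empirical null, type-I error uses 1,000 all-null proteins, parameter
recovery 500 proteins at noise 0.2 with ≥ 5 events each, and the
end-to-end recovery a 450-protein study at the same settings — sizes
chosen to keep Monte-Carlo error small relative to the asserted bounds
(3 standard errors) while matching the scale of a real plasma study.

## Limitations

* Gene-symbol grouping inherits upstream protein-inference decisions
  and cannot distinguish protein isoforms.
* The empirical null transfers a noise distribution from a separate
  control-control run; batch differences in spread bias event p-values.
* Single-event proteins rest entirely on the empirical route and one
  observation; their calls deserve less trust than multi-event calls
  (the per-protein `criterion` column makes them easy to filter).
* Raw-spectrum processing, probability modelling and pathway analysis
  are out of scope; the pipeline begins at the event table.
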