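# affectscales

Composite depression and anxiety rating scales for rodent behavioural
phenotyping, with a tested analysis pipeline and a synthetic cohort
generator.

## The problem

Preclinical studies of affective comorbidity — for example, whether a
chronic-migraine model makes rats depression- or anxiety-like — measure many
weak behavioural readouts at once: body weight, sucrose preference (a
two-bottle anhedonia assay), open-field locomotion and rearing, open-field
inner-zone avoidance, elevated-plus-maze open-arm avoidance, and periorbital
von Frey withdrawal thresholds. No single index is decisive, so the readouts
are integrated into composite rating scales, the rodent analogue of the
Hamilton scales used in the clinic:

- **Depression scale (0–25):** weight (0–5, unimodal with its plateau at
  330–360 g, the normal weight of a 9–10-week-old rat), sucrose preference
  (0–10; `preference % = 100·s/(s+w)`), open-field travel distance (0–5) and
  rearing count (0–5). Fewer points = more depression-like.
- **Anxiety scale (0–28):** inner-zone distance percent
  `ID% = 100·d_inner/d_total`, inner-zone time percent `IT% = 100·t_inner/300 s`,
  open-arm time percent `OT% = 100·t_open/300 s` and open-arm entry percent
  `OE% = 100·e_open/(e_open+e_closed)`, each scored 0–7 on half-open interval
  bins. Fewer points = more anxiety-like.

`affectscales` encodes these scales as validatable interval tables (shipped
as editable CSV, not hard-coded), computes every underlying index from raw
data (drinking masses, von Frey response series, tracking trajectories),
compares treatment groups with one-way ANOVA + Student–Newman–Keuls
post-hoc tests, and correlates total depression with total anxiety. A
synthetic generator emulates the four-group chronic-migraine design
(CON, IS, IS+AMI, AMI; n = 10/group over 21 days) so the entire pipeline is
testable without animal data.

## Worked example

Score one rat from its eight indices:

```r
library(affectscales)
score_rat(list(weight = 345, sucrose_pct = 97, distance_m = 22, rearing = 25,
               id_pct = 8.2, it_pct = 12.5, ot_pct = 9.8, oe_pct = 34),
          rat_id = "CON_01")
#>   rat_id weight_pts sucrose_pts distance_pts rearing_pts id_pts it_pts ot_pts
#> 1 CON_01          5          10            5           5      2      3      2
#>   oe_pts total_depression total_anxiety flags
#> 1      4               25            11
```

This rat is behaviourally normal on the depression side (25/25: weight on
the 330–360 g plateau, >95% sucrose preference, >20 m travelled, >20
rearings) but mid-range on the anxiety side (11/28).

Run the full simulate → metrics → score → statistics pipeline:

```r
run_pipeline(run_config(seed = 1))
#> Run report: 40 rats
#>   weight       F =   0.43, p = 0.7334 ns
#>   sucrose_pct  F =  32.70, p = 2.216e-10 ***
#>   distance_m   F =  24.82, p = 6.999e-09 ***
#>   rearing      F =  14.54, p = 2.308e-06 ***
#>   id_pct       F =   4.99, p = 0.005386 **
#>   it_pct       F =   1.26, p = 0.3022 ns
#>   ot_pct       F =   1.13, p = 0.3514 ns
#>   oe_pct       F =   6.28, p = 0.001544 **
#>   threshold_g  F =  92.01, p = 6.048e-17 ***
#>   depression-anxiety correlation: r = 0.374 (n = 40, p = 0.01751)
```

The F tests reproduce the generator's stated world: the inflammatory-soup
group differs on sucrose preference, distance, rearing, ID%, OE% and the
withdrawal threshold, while weight, IT% and OT% stay null; depression and
anxiety totals correlate positively across rats. Per-endpoint SNK pairwise
decisions live in `report$comparisons[[endpoint]]$snk`.

A file-based CLI (`inst/cli/affectscales`) exposes the stages
(`simulate`, `metrics`, `score`, `stats`, `report`, `run`,
`validate-scales`) over plain CSV tables.

## Scale validation

The printed scale tables and their prose restatements disagree in two
places (the weight extremes and the OE% increment rule). The package takes
the tables as normative and *reports* the conflicts instead of silently
fixing them:

```r
validate_builtin_scales()$conflicts
#>     item from     to table_points rule_points
#> 1 weight    0 299.95            1           0
#> 2 weight  390 400.00            1           0
#> 3     oe    6  44.95            1           2
```

`score_weight(..., mode = "prose")` applies the prose reading.

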