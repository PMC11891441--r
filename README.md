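# bofkit

Build mass- and charge-balanced biomass objective functions (BOFs) for
genome-scale metabolic models (GEMs) from biomass composition data.

## The problem

Constraint-based analysis of a GEM (e.g. flux balance analysis, FBA)
maximizes flux through a *biomass objective function*: a pseudo-reaction
that consumes every metabolite needed to produce 1 g of cell dry weight
(gDW). Turning measured biomass composition — protein, DNA, lipid, and
carbohydrate content in whatever units the assay produced — into the
stoichiometric coefficients of such a reaction involves repeated unit
conversions and a global mass normalization, which are tedious and
error-prone by hand. `bofkit` does this mechanically, for modellers who have
composition data (from the literature, from experiments, or from upstream
tools) and want a structurally valid, balanced BOF inserted into an existing
SBML or COBRA-JSON model.

## The model

A BOF is organized into up to three levels of pseudo-reactions:

```
s1 DNA + s2 PROTEIN + s3 LIPIDS + ...  ->  1 BIOMASS      (level 1, s_i in mmol·gDW⁻¹)
s1 dATP + s2 dCTP + ...                ->  1 DNA          (level 2, s_i in mol·mol⁻¹)
s1 PC(14:0/14:0) + ...                 ->  1 PC           (level 3, s_i in mol·mol⁻¹)
```

Composition data arrive as one sheet per pseudo-reaction (a directory of TSV
files, or an XLSX workbook), each sheet holding a composition table and an
optional maintenance table. Units may differ between sheets but not within
one sheet's composition table. Level-1 data are normalized so that the total
recovered mass equals exactly 1 g of dry weight, then converted to
mmol·gDW⁻¹ via molar masses taken from the model's formulas:

```
coefficient_i = mass_fraction_i · 1000 / M_i        [mmol·gDW⁻¹]
```

Pool sheets (levels 2–3) are converted to mole fractions summing to 1.
Maintenance rows (growth-associated ATP hydrolysis, cofactors) are used as
stoichiometric coefficients directly — never converted, never rescaled.
Polymers are treated as one monomer long. Every generated pseudo-metabolite
receives the net elemental formula and charge of its own reaction, so every
generated reaction is elementally and charge balanced by construction, and
the net mass consumed per unit flux of the top reaction is exactly 1 g.

## Worked example

The package bundles a deterministic toy organism (three-level BOF: PROTEIN,
DNA, LIPIDS→PC/PE, glycogen; level-1 masses summing to 0.97 g/gDW):

```r
library(bofkit)
cfg   <- fixture_config(levels = 3, seed = 1)
model <- make_toy_model(cfg)
make_composition(cfg, model, "composition")

built <- build_bof(model, "composition", tag = "demo", compartment = "c")
built$model
#> <gem_model 'toy_gem_L3': 24 metabolites, 24 reactions, 1 compartment(s)>

built$report[built$report$reaction == "BIOMASS_demo", ]
#>       species  provenance raw_value     raw_unit coefficient coefficient_unit
#>  PROTEIN_demo composition    0.2491    g_per_gDW     -2.1836     mmol_per_gDW
#>      DNA_demo composition    0.1792    g_per_gDW     -0.3822     mmol_per_gDW
#>   LIPIDS_demo composition    0.2357    g_per_gDW     -0.3572     mmol_per_gDW
#>    glycogen_c composition    0.3061    g_per_gDW     -1.9462     mmol_per_gDW
#>         atp_c maintenance  -35.0000 mmol_per_gDW    -35.0000     mmol_per_gDW
#>  ...
#>  BIOMASS_demo     product        NA         <NA>      1.0000     mmol_per_gDW

attr(built$report, "scale_factor")
#> 1.030928        # 0.97 g recovered -> scaled to 1 g dry weight

balance_check(built$model, "demo")$biomass_mass_g
#> 1.000000000     # grams consumed per unit flux of BIOMASS_demo

growth_check(built$model, "demo")
#> 22.5278 (optimal)   # FBA optimum with the new BOF as objective

save_model(built$model, "model_with_bof.xml")       # SBML L3 + FBC v2
remove_bof(built$model, "demo")                     # clean removal by tag
```

The negative coefficients are consumption in mmol·gDW⁻¹; the reaction
produces exactly 1 unit of the `BIOMASS_demo` pseudo-metabolite. Maintenance
rows passed through untouched. Because the raw masses summed to 0.97 g,
everything was rescaled by 1/0.97 before unit conversion.

### Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/bofkit", package="bofkit"))')
Rscript $CLI template --levels 3 --out my_template/      # blank workbook
Rscript $CLI build --model model.xml --workbook composition \
        --tag demo --compartment c --out-model model_bof.xml \
        --report coefficients.tsv --validation validation.json
Rscript $CLI validate --model model_bof.xml --tag demo
Rscript $CLI remove --model model_bof.xml --tag demo --out-model model_back.xml
```

Distinct exit codes per failure kind (schema 3, validation 4, conversion 5,
collision 6, balance 7, tag-not-found 8, I/O 9).

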