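# prockb

Process-centered knowledge representation and rule-based inference for
metabolic networks, in R.

Molecular databases anchor knowledge to molecules: a protein is annotated
with functions, processes and partners regardless of its state, and an
enzymatic complex often does not exist as an annotatable entity at all, so
its cofactors and activities end up attached to individual subunits.
`prockb` implements the opposite, systems-biology viewpoint: the unit of
description is the **biological process** — metabolic reaction, complex
assembly, post-translational modification, pathway — declared by a handful
of assertions (`has_input`, `has_output`, `mediated_by`, `requires`,
pathway structure via `starts_with` / `has_intermediary_process` /
`ends_with` / `precedes`). Everything else about the molecules is
*inferred* by forward chaining: their types (metabolite, kinase, protein
complex subunit, coenzyme, holoenzyme), complex composition
(`has_molecular_part`), function assignment (`has_function`), contribution
of subunits to a complex's function (`contributes_to`), transient
interactions (`interacts_with`), and pathway participants.

The package provides:

* a compact **core schema** (141 classes under three disjoint roots —
  process / participant / activity — and 27 properties) loaded from a YAML
  config that is the single source of truth;
* a **knowledge base** holding individuals with class and property
  assertions, each flagged `declared` or `inferred` with provenance;
* a **saturation engine**: semi-naive, provenance-tracking forward chaining
  over subsumption, domain/range, inverse/sub-property completion, an
  editable catalog of 27 safe Horn rules (SWRL-style, with a
  `DifferentFrom` builtin under the unique-name assumption), and
  pathway-participant inference with transient-intermediate exclusion. For
  a mediated reaction `r` with `mediated_by(r, p0) ∧ requires(r, a)` the
  flagship rule derives `has_function(p0, a)`; an ATP-dependent assembly
  `proc` with output `p0 ∉ {ADP, P}` and simple-protein input `pi` yields
  `has_molecular_part(p0, pi) ∧ ProteinComplexSubunit(pi)`; and
  `has_function(p0, a) ∧ has_molecular_part(p0, pi) ⇒ contributes_to(pi, a)`;
* **table I/O**: instantiation tables (CSV/TSV, one declared assertion per
  row), Turtle export preserving imported GO/ChEBI identifiers and
  declared-vs-inferred status, metrics and diff reports;
* a **synthetic network generator** that emits instantiation tables with a
  constructive ground-truth ledger — the exact assertion set saturation
  must add — at scales from a dozen reactions to a bacterial cytosolic
  metabolic network (~1.6k reactions, ~1.8k machinery-formation steps,
  ~12k individuals);
* a **command-line interface** (`exec/prockb`) with `validate`, `generate`,
  `load`, `reason`, `export`, `diff` and `report` subcommands.

## Worked example

The phosphorylation of 3-phosphoglycerate by phosphoglycerate kinase,
declared with seven typed individuals and six property assertions (plus the
spontaneous Mg-ATP complexation):

```r
library(prockb)
schema <- load_schema()
rules  <- load_rule_catalog(schema = schema)
kb <- load_instantiation_table(fig3_fixture(), schema)
saturate(kb, rules)
#> <prockb_saturation> 4 rounds, +36 class assertions, +31 property assertions
#>   subsumption          28
#>   prop_schema          28
#>   R2                   2
#>   ...

kb_query(kb, subject = "Phosphoglycerate kinase 1", property = "has_function")
#>                            s            p                                o   status provenance
#> 1: Phosphoglycerate kinase 1 has_function Phosphoglycerate kinase activity inferred        R27

sort(kb_query(kb, individual = "Phosphoglycerate kinase 1")$class)
#> [1] "ActiveEntity" "Chemical"     "Enzyme"       "GeneProduct"  "Kinase"
#> [6] "Participant"  "Transferase"

kb_query(kb, subject = "Mg-ATP", property = "has_molecular_part")
#>         s                  p      o   status provenance
#> 1: Mg-ATP has_molecular_part    ATP inferred         R5
#> 2: Mg-ATP has_molecular_part   Mg2+ inferred         R5
```

From six drawn property assertions, reasoning types the four small
molecules as metabolites (`R2`/`R3`), the enzyme as a kinase (`R14`, and an
enzyme/active entity by subsumption and the range of `mediated_by`), links
the enzyme to its activity by `has_function` (`R27`), and decomposes Mg-ATP
into Mg2+ and ATP (`R5`) — each inferred assertion carrying the rule that
produced it. A second shipped fixture covers RuBisCO assembly and
activation: the holoenzyme ends up typed ActiveEntity, Holoenzyme, Lyase,
Oxidoreductase and ProteinComplex, its subunits are typed
ProteinComplexSubunit and linked to the carboxylase activity by
`contributes_to` only — the function itself belongs to the holoenzyme
alone, and Mg2+ is typed Coenzyme.

From a shell:

```sh
exec/prockb reason --table my_network.csv --out-dir out/
exec/prockb generate --seed 1 --n-metabolic 100 --out net.csv --ledger truth
```

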