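---
title: "Process-centered knowledge representation and rule-based inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-centered knowledge representation and rule-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prockb)
library(data.table)
```

## The model

Most molecular annotation is molecule-centered: functions, processes and
partners are attached to a gene product, whatever state it is in. `prockb`
takes the opposite, process-centered view used in systems biology: the unit
of description is the **biological process** — a metabolic reaction, a
post-translational modification, a complex assembly, a pathway — and the
molecules are described by how they participate in processes. A process is
elementary (defined by its inputs, outputs, optionally a mediator and an
activity) or aggregated (defined by its subprocesses). Knowledge about
molecules (their types, compositions, functions, interactions) then need not
be asserted at all: it is *entailed* by the few assertions that describe the
processes, and materialized by forward chaining.

The terminological layer is deliberately small: 141 classes under three
mutually disjoint roots — `BiologicalProcess` (65 classes, maximum depth 7
counting the root as level 1), `Participant` (51) and `Activity` (25) — with
27 object properties, of which eight are *declarable* by a curator
(`has_input`, `has_output`, `mediated_by`, `requires`, `starts_with`,
`ends_with`, `has_intermediary_process`, and `precedes` for ordering pathway
steps); everything else is derived. The class list is not published as an
enumerable table anywhere we could transcribe, so the shipped
`core_schema.yaml` is a reconstruction assembled from the model's described
structure and the class names its worked examples use; the YAML config is the
single source of truth, so a richer ontology file can replace it verbatim
without touching code. Classes adopted from external ontologies (Gene
Ontology, ChEBI, NCI Thesaurus) keep their original CURIE in an `xref` field.
We deviate from putting the CURIE *in the id*: instance tables and rules
refer to classes by the human-readable names the domain uses
("MetabolicTransference", "Kinase"), and the original identifier is emitted
on export, which preserves interoperability without making the rule catalog
unreadable.

## Entailment semantics

Saturation applies, to fixpoint:

* **subsumption** — an individual typed `C` is typed by every superclass of
  `C`;
* **domain/range typing** — `mediated_by(r, p)` types `p` as `ActiveEntity`,
  etc.;
* **inverse and sub-property completion** — `has_input(r, m)` yields
  `is_input_of(m, r)` and `has_participant(r, m)`;
* the **rule catalog** — 27 safe Horn rules (`R1`–`R27`) over class atoms,
  property atoms and a `DifferentFrom` builtin;
* **pathway participants** — each pathway gains `has_participant` links to
  its subprocesses' inputs, outputs and mediators, excluding transient
  intermediates (produced by one step and consumed by the immediately
  following step, consecutiveness given by `precedes`).

Four rules are transcriptions of published statements — function assignment
(`R27`), ATP-dependent complex composition (`R10`), contribution of subunits
to a complex's function (`R26`), transient interaction (`R25`). The other 23
are reconstructions of the inferences the model is described to make
(metabolite typing from metabolic inputs/outputs, enzyme-family typing from
the required activity class, complex composition for spontaneous and
chaperoned assembly, coenzyme recruitment, state propagation through
modification, part transitivity). They live in an editable YAML catalog;
the engine is rule-agnostic, so the published table can be transcribed in
verbatim when available. Two of the transcribed rules needed a reading
choice, recorded in the catalog comments: the mediator atom of `R27` is
implemented as `Participant(p0)` (the printed class would prevent the rule
from ever firing on the worked example, since the mediator is a molecule,
not a process), and `R26` is implemented with `has_molecular_part(p0, pi)`
(the printed inverse would make the complex contribute to its own subunit's
function).

Three design commitments make this a datalog-style closed world rather than
open-world description logic, mirroring the model's own use of rules to
bypass open-world semantics:

* **Unique-name assumption.** Distinct ids denote distinct individuals;
  `DifferentFrom` is id inequality. The instantiation workflow creates one id
  per molecule state, so this is the intended semantics.
* **Defined classes are compiled into rules** where they yield positive
  entailments (a process with a mediator *is* a mediated reaction; a
  biochemical process with a gene-product input *is* a modification process).
  Universal ("only") conditions — a metabolic process has *only* metabolites
  as inputs — are compiled in the contrapositive-free, closed-world
  direction: every input of a metabolic process is typed `Metabolite`. This
  is also what lets a largely untyped instantiation become fully typed.
* **No negation, no retraction.** All rules are positive and safe and no
  step invents individuals, so the derivable set is finite, saturation
  terminates, and the fixpoint is unique — hence monotone, idempotent and
  independent of rule order, which the test suite asserts directly.

Evaluation is semi-naive: each round joins rule bodies only against the
facts derived in the previous round (with the other atoms against the full
store), so work is proportional to change. The test suite pins this
optimization to a deliberately naive re-evaluate-everything oracle on
generated knowledge bases.

Declared assertions are never deleted or demoted; every inferred assertion
carries the id of the rule or entailment that first produced it. When
several routes derive the same fact (common: spontaneous assembly
composition follows from both the binding rule and the modification rule),
the first producer in catalog order is recorded — provenance is a witness,
not an exhaustive justification set. Inconsistency (an individual entailed
to belong to disjoint classes) aborts saturation with the clashing classes
and their provenance; disjointness violation detection is the only
consistency service offered, by design.

## Interacting with knowledge bases

A knowledge base is loaded from an instantiation table — CSV/TSV with
columns `subject, kind, predicate, object`, one declared assertion per row —
saturated in place (knowledge bases have reference semantics, like
connections; use `kb_clone()` for a snapshot), queried by pattern, and
exported to Turtle with declared and inferred sections and per-triple
provenance comments, so the status distinction survives a round-trip.
Published curation spreadsheets use wide layouts with tool-specific headers;
they should be reshaped mechanically to this two-shape form rather than
guessed at in code. The counting convention for metrics is switchable
(`count_root_typing`): reference reasoner GUIs do not document whether
membership in the top-level roots is counted, so the convention is explicit
rather than hard-coded.

```{r fig3}
schema <- load_schema()
rules <- load_rule_catalog(schema = schema)
kb <- load_instantiation_table(fig3_fixture(), schema)
saturate(kb, rules)
kb_query(kb, property = "has_function")
kb_query(kb, subject = "Mg-ATP", property = "has_molecular_part")
```

## The synthetic-network generator

`generate_network()` emits instantiation tables containing the structural
motifs the rules consume — enzymatic metabolic reactions, spontaneous /
chaperoned / ATP-dependent / nested complex assemblies, covalent
modifications, and `precedes`-chained pathways — together with a
**ground-truth ledger**: the exact assertion set saturation must add,
computed during generation by direct construction (per-motif enumeration
plus independent subsumption/inverse closure), not by running the engine.
The headline test is exact two-sided equality between the saturated store
and the ledger.

Default parameters emulate the composition of the curated plant
carbon-fixation use case the model was first instantiated with: 24
enzymatic metabolic reactions of which 10 form one chained pathway, 58
protein-state-changing steps (46 covalent modifications + 12 assemblies),
38 metabolites. `ecoli_scale_params()` is a preset at the scale of a
curated bacterial cytosolic metabolic network: 1576 metabolic reactions,
1027 metabolites, and 1766 machinery-formation reactions (1109 assemblies +
657 activation modifications); about 12,000 individuals and ~17,000
declared property assertions, which saturation enriches to ~130,000
assertions in a few seconds on one CPU. Half the metabolites are left
undeclared by default, so full typing coverage after reasoning is a real
inference result, not an artifact of complete declaration. Reserved ids
`ATP`, `ADP`, `P`, `Mg2+` have fixed typing because the ATP-dependent
assembly rule names `ADP` and `P` as constants.

Generator distributions are uniform over the stated ranges and carry no
biological claim: the fixtures exercise rule mechanics, not biology. In
particular the generator keeps its subunit, substrate and enzyme pools
disjoint, draws pathway intermediates fresh per chain, and synthesizes no
stoichiometry or kinetics — real curated tables are messier (shared
molecules across roles, cyclic pathways, multi-step activations), so
passing on generated data demonstrates the engine's correctness, not that a
real curation effort would be free of modelling questions.

## Numerical and procedural choices

* Class depth is counted in nodes from the root (root = 1); with
  multi-parent classes, a class sits at the depth of its deepest parent + 1.
* `superclasses()` returns a deterministic topological order (most specific
  first, ties by id); table loading registers individuals in first-mention
  order; generation is byte-identical under a fixed seed.
* `interacts_with` is directed as printed in the transcribed rule; a
  `symmetric_interacts` flag materializes the mirror if wanted.
* A `precedes` cycle among one pathway's subprocesses is a structural error;
  a pathway may still be biologically cyclic through its start/end
  designation, which is unaffected.
* Degenerate inputs: empty tables load to empty knowledge bases and all-zero
  metrics; zero-count generator parameters produce an empty table and an
  empty ledger.

## Known limitations

* The schema and 23 of the 27 rules are reconstructions; quantitative
  metrics of the original curated instantiations (their exact declared and
  inferred counts) depend on the exact published class list, rule table and
  spreadsheets, which are supplementary artifacts not redistributable here.
  The corresponding check in the test suite is left failing rather than
  approximated, and the loaders are written so that transcriptions drop in
  without code changes.
* No owl:sameAs-style identity merging, no negation-as-failure, no
  truth maintenance beyond the declared/inferred flag, and no
  general-purpose description-logic reasoning beyond disjointness-violation
  detection.
* The Turtle writer emits one triple per line (a deliberate subset);
  `read_ontology()` parses that subset, not arbitrary Turtle.
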