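---
title: "A deterministic model of the digenic-to-monogenic transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic model of the digenic-to-monogenic transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xelim)
```

## The biological problem

Digenic species fix sex at fertilisation: females produce sons and
daughters in one brood.  Monogenic species — sciarid fungus gnats are the
classic case — start every zygote with the same chromosome constitution and
re-create the X/autosome signal in the embryo by eliminating paternally
derived X chromosomes; the population is then carried by two female
classes, gynogenic (all-daughter broods) and androgenic (all-son broods).
`xelim` implements a deterministic population-genetic model of how this
machinery can be assembled gene by gene from an ancestral XX/X0 system.

## The model

**State.** Per-sex genotype frequency tables over the configured loci, with
parent-of-origin resolved: male labels keep the maternal allele first at
every locus (`g(X0 eE ss rr gg)` is a male with maternal *e*, paternal *E*,
born to an imprinting mother), females aggregate heterozygote order because
oogenesis is Mendelian and makes the order phenotypically inert.

**Generation map.**  An infinite panmictic population with discrete,
non-overlapping generations, equal female fecundity, and non-limiting male
fertilisation.  Random mating therefore factorises the zygote distribution
into a pooled egg distribution times a pooled sperm distribution.  Eggs
carry two maternal effects: the cytoplasmic inhibitor dose (the count of
*e* alleles in the mother — one dose inactivates one elimination dose;
the enhanced allele *e\** inactivates two per dose) and the imprint mark
(present when the mother is functionally imprinting at *g*).  Sperm follow
three regimes: Mendelian with X- and 0-bearing sperm at 1/2 (no functional
*s*); the intact maternally derived complement only (functional *s* in an
imprinted father — the meiotic-drive regime); or both intact complements at
1/2 with no recombinants (functional *s*, no imprinting).  A father whose
retained X is paternally derived — possible only under unimprinted
elimination — has an X-less maternal complement, and the label grammar
(`0X ...`) represents him.

**Zygote resolution.**  Two-factor model: a zygote functional at *r* holds
two elimination doses (the factor's quantity is the same in every embryo
that makes it; a per-allele dosing was rejected because the worked crosses
always pit 1[e] or 2[e] against 2[r] in *rr* zygotes); the cytoplasmic
capacity is subtracted and each remaining active dose removes one
unprotected X.  One-factor model: the cytoplasmic dose itself removes
unprotected X chromosomes, one per dose.  A marked maternal X is never
removed.  Paternal copies are removed first; when the maternal and a
paternal X are both unprotected and one must go, the mass splits 1/2:1/2
(equivalent to a uniform choice among unprotected chromosomes; the branch
is reachable only in transient non-imprinting states).  Survivors with two
X chromosomes are females, with one males, with none dead; unused doses are
harmless, and autosomal alleles are never touched by elimination.  In the
sciarid presets the sperm contributes two identical X copies (gene *c*) and
the triple-X zygote loses paternal copies first; a triple-X survivor is not
a modelled adult class and raises an error.

**Selection and sex ratio.**  Viability `w` multiplies over regime entries
(carriers of the favoured allele, in the configured fitness dominance
sense, have 1; everyone else `1 − µ`, default µ = 0.1) and applies to the
adults of both sexes.  The sex ratio SR is male over female mass recorded
*after* selection and *before* per-sex renormalisation; this placement is
what makes the heterozygous-female/homozygous-male intermediate state print
SR = 1/0.9 ≈ 1.11.

## Tunable parameters

| parameter | default | meaning |
|-----------|---------|---------|
| introduction frequency | 0.05 | per-allele-copy replacement probability; leaves a monomorphic locus at exact Hardy–Weinberg proportions 0.9025/0.095/0.0025, in linkage equilibrium |
| µ | 0.1 | selection coefficient of every positive-selection regime |
| `tol` | 1e-10 | L∞ convergence tolerance of `run_to_equilibrium()` |
| `max_gens` | 20000 | generation cap; hitting it reports non-convergence |
| loss/presence ε | 1e-6 | allele-loss threshold, class-presence threshold for classification, and the between-stage pruning level |
| `sr_extinct` | 1e-6 | SR below this (or above its reciprocal) declares a sex lost |

## Numerical choices

*Determinism.*  There is no random number generator anywhere; elimination
targets are mass splits and the whole pipeline is bit-reproducible.

*Convergence and loss are asymptotic.*  Deterministic decay never reaches
zero, so three conventions make outcomes decidable.  (i) Stages run to the
L∞ tolerance and the *stable state* handed to the next stage is pruned of
classes below 1e-6 — mirroring stepping analyses that restart each stage
from the printed stable state.  Without pruning, an allele driven out at
one stage survives as a 1e-20 residue and can be regrown by a later stage
that restores its advantage (the imprinting-after-spermatogenesis order
fails to go extinct for exactly that reason).  (ii) An allele is "lost"
below 1e-6, or when it declines monotonically and sits far below its
introduction frequency at a stage's end: a zygotic-lethal recessive (the
elimination gene in an unimprinted population) decays harmonically and
would otherwise stay "polymorphic" forever.  (iii) Extinction by male (or
female) loss is declared at the SR threshold, since the male mass of a
doomed population shrinks geometrically without vanishing.

*Regime persistence.*  The built-in catalogue keeps every gene's viability
regime in force after its stage (an advantage is a property of the gene).
`run_scenario()` itself defaults to stage-only regimes with an opt-in
`carry_forward`, because the published intermediate states are split: the
1/0.9 intermediate SR requires the elimination gene's advantage to persist
through the neutral spermatogenesis stage, while the variant with a
selected spermatogenesis gene prints SR = 1, which requires it not to.
The final neutral-inhibitor stages *need* the carried advantage: without
it the ancestral elimination allele *R* self-perpetuates in females (an
*R*-bearing zygote is never eliminated, so every *R* egg becomes an *R*
daughter) and the run stalls in a stable mixed state rather than the
monogenic one.

## What the scenario grid shows — and one honest discrepancy

The catalogue reproduces the documented qualitative conclusions: no
monogenic state when the spermatogenesis and elimination genes are both
dominant (extinction through male loss), the transition under
dominant-*s*/recessive-*r* and under the fully recessive regime, no
transition ever without imprinting, and failure of every
imprinting-acquisition order (extinction when imprinting follows a fixed
spermatogenesis gene; loss of the elimination gene in unimprinted
populations, where a functional zygote kills itself).

Two findings deviate from published summaries and are reported as
computed.  First, the monogenic state is also reached by the *permuted*
orders of the successful sequences (e.g. inhibitor-then-spermatogenesis-
then-elimination as well as the documented
spermatogenesis-then-elimination-then-inhibitor): the inhibitor's neutral
emergence commutes with the selected stages, so the permuted runs pass
through essentially identical states.  The strict "only these sequences"
reading therefore fails in this implementation, and deliberately so.
Second, two printed intermediate states could not be derived from the
stated rules: the one-factor inhibitor-only state (females 0.625/0.375,
SR = 1.8) — a neutral inhibitor whose carriers have all-male broods
declines rather than equilibrating, although the subsequent stage still
ends at the correct monogenic state once the spermatogenesis gene fixes —
and the unimprinted male-confined elimination-allele plateau (1/6), which
is path-dependent under harmonic decay.  The package exposes the full
trajectories so both can be inspected rather than silently matched.

## What the generator emulates — and does not

The synthetic populations are exact frequency states of an infinite
population.  Passing tests show that the recursion, the elimination
algebra and the classification behave as specified on those states; they
say nothing about finite-population drift, overlapping generations,
mating preference, recombination (all loci are unlinked by construction),
dosage compensation, germline/soma differences, or temperature-dependent
expression of the maternal inhibitor — all outside the model.  The sciarid
presets label the inversion X chromosome but give it no recombination role
(there is nothing to suppress in an unlinked model).

## Degenerate inputs

Zero-X zygotes die; triple-X adults error outside (and inside) the
presets; a population whose male or female mass reaches exactly zero
raises a classed extinction condition that `run_to_equilibrium()` converts
into an outcome; malformed labels and unknown loci are rejected at parse
time; and `freq = 0` or `1` introductions are exact no-ops or fixations.
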