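---
title: "Sire modeling in honeybee genetic evaluation: simulation design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sire modeling in honeybee genetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Honeybee colony phenotypes are shaped by two correlated genetic effects: a
*queen effect* expressed by the colony queen and a *worker effect*
expressed collectively by her workers. Estimating the variances of these
effects and their covariance from colony records requires a relationship
matrix that respects the species' reproductive biology: queens are diploid
and mate once; drones are haploid and produce clonal sperm; a mating
involves several drones that may come from one drone-producing queen (DPQ)
or from a group of sister DPQs; and in field data the *sire side* of a
mating is often recorded only partially — sometimes only the dam of the
DPQ(s) is known, and DPQs themselves are frequently open-mated to an
uncontrolled drone population.

`apisim` simulates a closed breeding program under controlled single-sire
(SS) or pseudo-sire (PS) mating and open mating, re-encodes the sire side
of the true pedigree under deliberately correct or incorrect assumptions,
and estimates the genetic parameters by AI-REML. Comparing estimates with
the simulated truth across replicates quantifies the bias and standard
error that each sire-modeling choice induces.

## The breeding program emulated by the generator

The generator's defaults are the study conditions; they are not tuning
knobs.

* **Founders.** 432 unrelated, non-inbred base queens with breeding values
  $(a_W, a_Q) \sim N(0, G_0)$,
  $G_0 = \begin{pmatrix} \sigma^2_W & \sigma_{WQ} \\ \sigma_{WQ} &
  \sigma^2_Q \end{pmatrix}$. Base drones are haploid with covariance
  $G_0/2$. Four canonical parameter sets are provided:
  $\sigma^2_W \in \{10, 20\}$, $\sigma^2_Q = 10$, $\sigma^2_e = 30$,
  $r_{WQ} \in \{0, -0.5\}$ (so both genetic variances equal one third of
  the residual variance in the base set).
* **Yearly cycle.** Each of 24 selected dams produces 24 candidate
  breeding queens (BQs) and 20 DPQs per year for 10 years. Every cohort
  loses exactly 25% of its colonies per family over winter, leaving 18 BQ
  and 15 DPQ colonies phenotyped per dam — hence
  $432 + 10 \times 24 \times 33 = 8352$ records per replicate. One
  replacement BQ per family is selected on own colony phenotype
  (within-family selection); two thirds of the dams are selected across
  families on the mean phenotype of their DPQ colonies, and 3 of their
  phenotyped DPQs are drawn at random to form the mating group used two
  years later. Years 1–2 are open-mated initialization cohorts; from year
  3 the nucleus is closed. The generation interval is 1.5 years by
  construction (1 year on the dam path, 2 on the sire path).
* **Matings.** Eight drones per mating, contributing equally to the
  worker group. SS: one DPQ drawn uniformly from the group's three
  sisters produces all eight drones. PS: each drone's mother is drawn
  uniformly *with replacement*. Group-to-queen assignment is balanced, so
  each of the 16 groups serves exactly 36 matings.
* **Phenotypes.** $y = \text{year}_t + a_W(\text{worker group}) +
  a_Q(\text{queen}) + e$, with $e \sim N(0, \sigma^2_e)$ and one
  environmental level per year drawn from $N(0, \sigma^2_{\text{year}})$.
  The year variance is set to 10 (a moderate environmental signal of the
  same order as the genetic variances); because year enters the
  evaluation model as a *fixed* effect, its variance only affects the
  realism of the records, not the estimands.
* **Inheritance.** A daughter queen receives
  $a = \tfrac12 a_{\text{dam}} + \psi + g_{\text{drone}}$ with Mendelian
  term $\psi \sim N(0, \tfrac14 (1 - F_{\text{dam}}) G_0)$; a drone
  carries a single maternal gamete $g = \tfrac12 a_{\text{dam}} + \phi$,
  $\phi \sim N(0, \tfrac14 (1 - F_{\text{dam}}) G_0)$, so drone values
  have covariance $G_0/2$ at every inbreeding level. Worker groups take
  the average worker genome, $\tfrac12 a_{\text{queen}} + \bar g$, with no
  finite-group residual (the infinite-worker-group limit). The inbreeding
  coefficient used to scale Mendelian variance is the kinship between the
  dam and the father DPQ computed on the true pedigree; the additional
  $1/D$ chance that two relatives share the very same father drone is
  handled by the relationship module's exact mode (below), not inside
  $F$.
* **Open mating.** Homogeneous: drones from the base distribution.
  Heterogeneous (Set II): two drone subpopulations centred on
  $-\alpha$ and $+\alpha$ with $\alpha$ applied to both traits and scaled
  so the queen-effect gap is exactly one genetic standard deviation
  ($\alpha_q = \sqrt{\sigma^2_Q}/2$); DPQ sister groups are allocated to
  subpopulations at random but balanced 12/12 each year.
* **Mortality** removes exactly $\lfloor 0.25 n \rfloor$ colonies per
  family, guaranteeing the per-dam survivor counts; selecting the three
  group DPQs "after the second winter" is collapsed into a uniform draw
  from the 15 phenotyped sisters, which is distributionally identical
  because the second mortality event is itself uniform.

What the generator does *not* emulate: apiary or spatial structure,
queen lifespan beyond the implicit schedule, finite worker groups,
multiple matings per queen, genotyping, or non-genetic maternal trends.
Tests that pass under this generator validate the estimation machinery
under the stated model; they cannot certify behaviour under violations of
it (e.g. confounded apiary effects or drifting environments).

## Sire models in the estimation pedigree

The pedigree given to the evaluation contains queens, mate entries and
worker groups. The encoder never touches dam links; it re-encodes each
controlled mating as

* `C_SSP` — an identified DPQ: the true one (SS simulation) or a sister
  drawn at random (PS simulation);
* `C_dummySSP_per_DPQdam` — one *dummy* DPQ (an unobserved daughter of
  the true DPQ dam) shared by all 36 matings of the group;
* `C_dummySSP_per_Q` — a fresh dummy DPQ per mating;
* `C_PSP` — a pseudo-sire group entity of $S = 3$ unidentified sisters.

Open matings are represented by an open pseudo-sire group of $S = 100$
unknown, unrelated, non-inbred DPQs shared by all open matings
(`O_SinglePSP`); Set II additionally considers excluding DPQ records
(`O_NoPheno`), one open group per drone subpopulation (`O_TwoPSP`), and a
three-level non-genetic drone-origin effect, fixed (`O_FixedGroup`) or
random (`O_RandGroup`), with controlled colonies as the zero-loading
reference. Dummy DPQs inherit the true DPQ dam and her mate entry as
parents, so their inbreeding and relationships are computed rather than
assumed zero.

## The relationship matrix

Every entity — queen, mate entry, worker group — has at most two parents
with regression coefficients $b$ and a residual variance $d$, giving
$A = T D T'$ and the sparse
$A^{-1} = \sum_i d_i^{-1} (e_i - \sum_p b_{ip} e_p)(\cdot)'$ directly
from the factor; $A$ is never numerically inverted on the production
path. The per-type rules are documented in `?build_factor`; the
distinctive honeybee ingredients are:

* **Father-sharing probabilities.** With $D$ drones from $S$ sister DPQs
  allocated uniformly with replacement, two offspring of one mating share
  their father drone with $p_{dr} = 1/D$ and their father DPQ with
  $p_{DPQ} = 1/D + (1 - 1/D)/S$ — the exact value under the allocation
  model, which stays in $(0, 1]$ for every $S, D$ (the familiar
  approximation $1/D + 1/S$ exceeds 1 at $S = 1$). At $S=3$, $D=8$:
  $p_{DPQ} = 0.4167$.
* **Group entities.** A pseudo-sire group is the *mean* of its $S$
  member genomes: its self-relationship is
  $a_{PP} = \bar a_{mm}/S + (1 - 1/S)\,\bar a_{mm'}$ with member
  self-relationship $\bar a_{mm} = 1 + F_m$ and member-pair relationship
  $\bar a_{mm'}$ including the same-mating correction
  $c_2 = p_{dr}\,(\tfrac12 - \tfrac14 a_{M'M'})$ for sisters sharing a
  father drone (clonal sperm makes that a full paternal identity). An
  open group of 100 unknown DPQs has $a_{PP} = 1/100$ — the small
  diagonal that makes the `O_TwoPSP` inflation mechanism possible.
* **Worker groups** are pedigree entities with
  $d_W = (2 - a_{MM})/(4D)$, the drone-sampling variance of the group
  mean; this keeps $A$ invertible.
* **Three modes.** The production default, `per_mating`, inserts one
  latent sire per mating (the mating's mean drone genome in diploid
  units) carrying the sire side of queen offspring and of pseudo-sire
  group members, so same-mating *queen* covariances are exact — two
  daughters of one SS mating have $a = 0.53125$, the value the
  father-sharing probability $p_{DPQ} = 1$ demands — while worker groups
  stay attached to the shared entry with $d_W > 0$, keeping $A$
  invertible. Whether these within-mating corrections belong in the
  evaluation matrix was a genuinely open design point; they were adopted
  because single-sire matings make $p_{DPQ}$ reach 1, where ignoring the
  correction measurably inflates the recovered genetic variances (the
  parameter-recovery battery under `group_level` showed an upward shift
  of the queen-variance mean of about ten percentage points at the
  12-family scale). `group_level` (no latent sires; all within-mating
  sharing absorbed in $d_W$; sister queens of an SS mating get
  $a = 0.5$) is retained as the simpler pedigree-file-shaped
  alternative, and `exact_per_mating` additionally hangs worker groups on
  the latent sires, reproducing *all* same-mating covariances exactly at
  the price of $d_W = 0$ (non-invertible — the verification mode that
  gene dropping reproduces). Modes differ by at most $1/(2D)$ on any
  entry.
* **Verification.** A gene-dropping oracle drops founder alleles with the
  drone allocation re-sampled per locus (matching the expectation the
  recursion computes) and estimates each pairwise relationship as mean
  IBD sharing; the exact-mode recursion agrees within Monte-Carlo error
  on every pair of a mixed toy pedigree, including queen/worker pairs of
  the same colony. The correction $c_2$ above is the form that survives
  this check; it was derived by direct enumeration of the allocation
  model.

Relationship computations use a dense "core" block only for entities that
ever appear as parents (a few hundred per replicate) and closed-form
per-sibship quantities for everything else, so a full replicate factor
(~20,000 entities) builds in about two seconds.

## Genetic evaluation

The model is $y = Xb + Z_w a_w + Z_q a_q (+ Z_g g) + e$ with
$(a_w, a_q) \sim N(0, G_0 \otimes A)$ over all pedigree entities, fixed
year effects in cell-means coding (collinear columns dropped to a
reference with a warning), and, in Set II, the optional drone-origin
effect. The restricted likelihood is evaluated exactly through the sparse
mixed-model equations,

$$-2\,\log RL = \log|C| + m\,\log|G_0| + 2\,\log|A| + n\,\log\sigma^2_e +
y'Py + \text{const},$$

with one sparse Cholesky factorization (CHOLMOD through the Matrix
package) per evaluation.

Numerical choices:

* **Updates.** The average-information matrix is computed exactly from
  working variates ($Z_k A Z_l' P y$ etc., using $A v = T D T' v$ sweeps)
  and MME solves; the gradient is obtained by central finite differences
  of the exact likelihood. Iterations run on a log-Cholesky
  parameterization of $(G_0, \sigma^2_e, \sigma^2_g)$, which enforces
  positive definiteness by construction and turns the $r_{WQ} = \pm 1$
  boundary into a smooth limit; steps that fail to decrease
  $-2\log RL$ are halved. If a step stalls with the gradient still
  informative (flat ridges of small datasets), a bounded quasi-Newton
  (BFGS) rescue on the exact likelihood is attempted at most twice.
* **Convergence** at maximum relative parameter change $< 10^{-8}$, or
  when the likelihood improvement falls below numerical resolution
  ($10^{-9}$); after 200 iterations the fit is flagged non-converged.
* **Starting values** default to $(\sigma^2_W, \sigma_{WQ}, \sigma^2_Q,
  \sigma^2_e) = (5, 0, 5, 35)$ and $\sigma^2_g = 1$; all are
  configurable.
* **Reported estimates.** $\hat r_{WQ}$ is clamped to $[-1, 1]$ (the
  parameterization already guarantees it); predicted standard errors are
  square roots of the diagonal of the inverse AI matrix at the optimum,
  enabling predicted-vs-realized SE comparisons across replicates.
* **Oracle.** On small datasets the implementation agrees with direct
  Nelder-Mead maximization of the dense $V$-based restricted likelihood —
  an independent formulation — to $10^{-4}$ in the parameters. Datasets
  this small can have boundary or corner optima where components are not
  separately identified; the test fixture is a dataset with an interior
  optimum.

## Replicate metrics

Per scenario, replicate $r$ uses seed $\text{base} + r$. Relative bias is
the mean of $(\hat\sigma^2 - \sigma^2)/\sigma^2$ across converged
replicates (in percent), relative SE its root-mean-square deviation from
the mean, and strong deviations the fraction of replicates off by more
than 20%. The bias of $\hat r_{WQ}$ is reported in absolute units because
the true correlation may be zero. Genetic trends are OLS slopes of
cohort-mean (true or estimated) breeding values over years 5–10 — the
closed-nucleus phase — computed over *all* BQ candidates born each year,
and the trend error is (estimated − true)/true. Non-converged replicates
are excluded from the statistics but reported as a rate. Trend regressions
are unweighted; cohorts are equal-sized by design.

## Problem sizes

Full replicates (24 families; ~22,800 pedigree entities, ~39,000 mixed
model equations) simulate in under a second and fit in 30–60 seconds
each, so the published-scale batteries (200 replicates for each of 12
scenarios) are an overnight run driven by `analysis/04_set1_battery.R`
and `analysis/05_set2_battery.R` with `NREP=200 FAMILIES=24`. The test
suite and the default analysis scripts exercise the identical code paths
at 12 families and a few replicates — sizes chosen so the whole suite
runs in minutes; the 12-family nucleus halves the information content per
replicate (standard errors scale roughly as $1/\sqrt{N}$ in the number of
families) without changing the mechanisms under test.

## Known limitations

* Unknown-parent genetic groups for open-mated *breeding-queen* dams are
  out of scope; open mating is modeled only where it affects worker
  groups (DPQ colonies and the initialization cohorts).
* Probabilistic multi-sire pedigrees (assigning per-DPQ paternity
  probabilities) are not implemented.
* Single trait, no genomic information, no Gibbs/Bayesian alternative to
  REML.
* The exact-per-mating relationship mode is a verification tool; the
  invertible production path is the group-level factor, mirroring how
  evaluation pedigrees are built in practice.
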