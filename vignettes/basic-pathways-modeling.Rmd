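---
title: "Basic-pathways kinetic modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basic-pathways kinetic modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellbp)
```

This vignette explains what `cellbp` computes, the assumptions behind
each stage, the parameters that matter, and the numerical and design
decisions taken where the problem left genuine freedom. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The modeling frame

The cell is a set of homogeneous compartments — cytosol `c`,
mitochondria `m`, nucleus `n`, vacuoles `v`, endoplasmic reticulum `e` —
with fractional volumes $f_k$ summing to 1, an average cell volume
$V_{cell}$ (default $42\times10^{-15}$ L, the median volume of a haploid
yeast cell treated as the population average for respiring
spheroplasts), and an exponential growth rate $\alpha$ (default
0.003333 min$^{-1}$, a respiring wild-type doubling time of roughly
3.5 h). Concentrations are in µM, time in minutes, volumes in liters;
conversions happen only at I/O boundaries. Components are chemically
defined by two conserved elements only: iron, itemized over six center
kinds (heme FH, mononuclear FO, Fe–O–Fe FF, and the [Fe$_2$S$_2$],
[Fe$_3$S$_4$], [Fe$_4$S$_4$] clusters F2/F3/F4 carrying 1, 1, 2, 2, 3, 4
irons), and carbon, deliberately coarse (5 per amino acid or acetyl
unit, 10 per nucleotide or dinucleotide cofactor, 35 per heme, 50 per
phospholipid). Carbon is a housekeeping element: its role is to make
every reaction balanceable, not to model carbon metabolism. Element
balance is enforced per reaction at a tolerance of $10^{-4}$ atoms per
event, because curated coefficients carry 6–7 significant figures and
rounding must not fail validation. Catalysts never enter stoichiometry
or balance — with one deliberate exception to the "never produced" rule:
DNA replication is catalyzed by DNA itself, so a catalyst may coincide
with a *product* (autocatalysis) though never with a reactant.

Protein-group bookkeeping is weighted-average arithmetic: a group's
concentration is the mean of its members' respiring concentrations
(fermenting values times 1, 3 or 9 for mitochondrial proteins), each
member's weight is its share of that mean, and the group's per-center,
iron, amino-acid and carbon coefficients are weight-sums of member
values. Fractional center counts are therefore everywhere and no
integrality is assumed.

Membrane geometry treats the cell, nucleus and vacuole as spheres
(area $4\pi r^2$ from the compartment volume), the nuclear envelope as
a double membrane, mitochondria as long thin cylinders (default radius
0.3 µm, a typical value for yeast; an explicit outer-membrane area can
be supplied instead — the printed total membrane volume, not the
geometry, is the authoritative quantity) with an inner membrane of 3×
the outer area, and the ER membrane as half the ER compartment volume.
Membrane volume over the volume of one phospholipid
($3\times10^{-24}$ L) gives the phospholipid copy number.

## The stoichiometric matrix and the dilution block

All reaction rates share one frame: the rate is the time derivative of
the extent of reaction *per cytosolic volume*, wherever the chemistry
happens. Writing the ODEs for local concentrations then puts the factor
$f_c/f_k$ on every matrix entry of a component homed in compartment
$k$. Growth dilution is a pseudo-reaction $C_i \rightarrow \emptyset$
per component; its cytosol-referenced rate is
$\alpha\,[C_i]_{local}\,f_k/f_c$ so that the entry $-f_c/f_k$
reproduces $d[C_i]_{local}/dt = -\alpha [C_i]_{local}$. The source
text's phrasing about "multiplying the non-cytosol concentration by
$V_{cyt}/V_i$" admits a second reading (the ratio on the concentration
rather than on the matrix entry); we follow the convention that
reproduces the printed mitochondrial ODE coefficients (−6.43 on the
dilution of a mitochondrial pool at $f_c/f_m = 6.43$), and note that
the two readings agree on the product that enters the ODE. Nutrients
are boundary species: they get no matrix row and no dilution, and their
concentrations are model parameters. Ordering is non-dilution reactions
first, then dilutions in component order, which yields the
$(S_0\,|\,-D)$ block structure with no permutation bookkeeping; these
matrices are always full row rank $m$, so the null space has dimension
$r = n - m$.

## Constructing the nonnegative basis

The algebraic basis $G = (I_r;\,D^{-1}S_0)$ annihilates $S$ by
construction; its columns are "run one reaction at unit rate and let
dilution absorb the products", and they carry negative dilution entries
wherever the reaction net-consumes something. The transformation to a
nonnegative basis is a **monotone multi-pass sweep**: a column may only
be repaired by adding positive multiples of columns that are *already
entirely nonnegative*, which removes the targeted negative entry and
can never create a new one — so each column converges in at most one
step per negative row, and multiple passes let upstream columns (e.g.
biosynthesis of an apo protein) converge before the columns that need
them (the metallation step consuming that apo protein). Columns the
sweep cannot clear (mutually dependent conversion loops with no
converged producer) are rebuilt directly as flux-cone vertices by
nonnegative least squares on the full matrix, and if a rebuilt vertex
happens to fall inside the span of the other columns the span is
completed by perturbing a strictly positive interior flux along a
complementary null direction — legitimate because whenever every
reaction carries flux in some cone element, the cone spans the whole
null space. The error path (a reaction through which no nonnegative
steady flux exists) is reported by reaction name rather than guessed
around.

Two numerical points recur throughout this module. First, pathway
columns accumulate their entire upstream supply chain, so entries within
one column legitimately span many orders of magnitude (a unit of protein
biosynthesis drags hundreds of ATP-regeneration events behind it); all
rank decisions are therefore made on max-scaled columns, reduced linear
systems are row/column equilibrated before factorization, and weights in
$[-10^{-10}, 0)$ are clamped to zero. Second, a basis of exactly $r$
generators spans the null space but its *simplicial cone* is a strict
subcone of the full flux cone, so an arbitrary feasible flux can have
negative weights in an arbitrary basis. Where a reference flux is
available (the fixture's wild-type state), `make_nonnegative_basis`
accepts it as an **anchor**: the flux is first decomposed into
nonnegative components with positive weights by greedy support
shrinking (extract a cone vertex supported inside the remaining flux,
subtract the largest multiple keeping the remainder nonnegative — a
conic Carathéodory argument guarantees termination), and those
components are preferred as basis columns. The anchor then has an
exactly nonnegative weight vector, mirroring a basis built around the
wild-type state.

## Steady states from independent rates

Dilution rates are the natural independent set: growth rate times a
measurable steady-state concentration. The helper
`select_independent_set` walks candidates in preference order
(dilutions, then declared zero-rate reactions, then anything else) and
keeps rows that add a dimension, so reverse-reaction pairs and similar
dependencies are resolved automatically — in the fixture, two pure
exchange cycles (vacuolar import/export, sensor metallation/
demetallation) make two dilution rows redundant and pull the two known
zero-rate reactions into the set, directly analogous to the full
model's mixed choice of dilution and assigned non-dilution rates.
Weights are solved singleton-first (each singleton row of $W$ gives
$c_j = R_i/w_{ij}$ immediately; ties broken by lowest row index), then
the singleton-deficient columns from the equilibrated reduced system of
the remaining independent rows; the full independent-row system must
close to $10^{-8}$ relative, negative weights beyond the clamp are an
infeasibility error naming the column, and an insufficient independent
set is reported with the unresolved columns.

## Rate laws, calibration and regulation

Rate-law generation is rule-based, not fitted:

* **Michaelis–Menten** (enzyme-catalyzed): one saturating term
  $[S]/(K_M + [S])$ per substrate with $K_M$ equated to the wild-type
  *local* substrate concentration — local, because the whole ODE frame
  operates on local concentrations — so each term is exactly 1/2 at
  reference; catalysts enter as first-order normalized factors
  $[E]/[E]_w$. Stoichiometric multiplicity does not raise reaction
  order.
* **Mass action** (non-enzymatic): first-order normalized substrate
  factors.
* **Transport**: $k\,([donor]/[receiver] - 1)$ on local concentrations;
  the law may go negative dynamically (net reverse flow) and is passed
  through unclamped, since no clamp is part of its definition. A
  transport step whose wild-type ratio is 1 cannot be calibrated to a
  nonzero rate and says so.
* **Dilution**: $\alpha\,[C]_{local} f_k/f_c$, fixed, never calibrated.

Calibration sets $k_{rxn} = R_{ss}/\text{kernel}(U_{ss})$ — for an
$s$-substrate Michaelis–Menten law, $k = 2^s R_{ss}$ — so every law
returns its steady rate exactly at the reference state. Reactions with
$R_{ss}=0$ get $k=0$ and stay inert unless explicitly overridden, since
calibration from a zero rate is undefined. Regulation multiplies a
rate by $\prod_i \mathrm{lf}(2 - [C_i](t)/[C_i]_{ss})$ with
$\mathrm{lf}(x) = 2/(1+e^{-5(x-1)})$: a factor in $(0,2)$, neutral at
the reference state (so calibration is untouched), damping when the
sensed component doubles, boosting when it is depleted. The steepness 5
is the curve-shape default; regulation factors multiply the rate law
only and are never re-absorbed into $k$ under perturbed parameters.

## Dynamics

The state is the vector of local concentrations of internal components;
nutrients are parameters. Integration is stiff adaptive (`lsoda`) at
relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ µM —
tight, because departure of an unstable steady state from round-off is
itself a phenomenon of interest and must not be swamped by solver
error. Perturbations are applied as exact discontinuities by splitting
the integration at event times (concentration steps scale one state
variable; nutrient steps scale a boundary parameter; rate-constant
steps scale one $k$). Negative excursions within the absolute tolerance
are clamped to zero; anything larger aborts the segment and the partial
trajectory is kept for diagnosis. Outcomes are classified from the
trajectory tail (last 20%): `at_reference_steady_state` when all
normalized deviations stay below $10^{-3}$; `blowup` above $10^3\times$
reference (or on step collapse); `oscillation` on sustained
sign-alternating tails above the deviation threshold; otherwise
`new_steady_state` when the right-hand side has settled, else
`undetermined`. All thresholds are arguments.

## The reduced iron-metabolism fixture

The fixture keeps the curated stoichiometry of the printed
iron-handling reactions — iron import (`ACFT3`), trafficking to
mitochondria and vacuoles (`ACMRS`, `ACCC`), the vacuolar redox pair
(`AF2`/`AF3`) and exporter (`ACFT5`), scaffold loading (`MAISU`,
7.59143 FM per ISU), reductive coupling (`MAISA`, 0.9416092 ISU and
1.787040 NADH per acceptor), cluster delivery (`MALYS`), heme synthesis
and release (`MAHEM`, `UHEM`, 7.054408 centers), cluster export
(`AATM`, 1.538601), cytosolic assembly and delivery (`MACIA`,
`MAPOL`), the iron sensor pair (`MAAFT`/`UAFT`, 0.3459033), protein
synthesis (`BAACIA`, 4667.9 AA + 14003.7 ATP), respiration (`ACTCA`,
`ACETC` with its 5% ROS yield), and the housekeeping biosyntheses
(`ACMEM`, `ACLYS`, `ACLEU`, `ACNUC`, `ACPOL`) — and closes the network
with flagged `invented` reactions (glycolysis-like NADH regeneration,
adenylate and NAD synthesis, transfers, one-step generic protein
biosyntheses at 300 residues and 3 ATP per residue). Reductions
relative to the full model, chosen to keep the fixture self-contained:
apo protein forms carry no permanent iron centers (holo profiles are
derived arithmetically from the transfer coefficients, which makes
every iron balance exact — e.g. the sensor's 0.85334 transient F2
content falls out of the chain rather than being asserted); the
vacuolar reduction step uses cytosolic NADH at the interface instead of
a vacuolar NAD pool; respiring multipliers are 1 throughout; the
cytosolic assembly factor is metallated in a single invented step. One
printed coefficient is adjusted: the reductive-coupling reaction prints
0.9416092 on the consumed scaffold but 0.9416091 on the returned apo
scaffold; the derivation fixes 0.9416092, and the one-digit asymmetry
would violate carbon balance at the enforced tolerance once multiplied
by group carbon content, so the derived value is used on both sides.

The wild-type state is defined by a frozen table of the 57 non-dilution
rates (`fixture_steady_rates()`), chosen so that (i) the two
iron-replete zero rates are the vacuolar exporter and the sensor's
reverse step, (ii) every component has strictly positive net
production, and (iii) the four ratio-law transports run down their
concentration gradients. Steady-state concentrations are then *derived*
from the dilution balance $[C_i] = d_i f_c/\alpha$ — the same move the
full model makes when it forms the wild-type concentration vector from
the steady dilution rates — which lands them in realistic ranges
(metabolites $10^1$–$10^3$ µM, protein groups around 1 µM, the generic
gene at 0.248 µM, vacuolar iron stores dominating cellular iron).
Carrier-like transports (adenylate, NAD, acetyl units) are modeled as
normalized mass action rather than ratio laws; ratio laws are kept for
the four gradient-driven transfers (O$_2$, amino acid, TCA metabolite,
nucleotide).

The regulation set was chosen by the same diagnostic procedure the full
model documents: integrate the unregulated system, find the mutually
autocatalytic loops that depart first, and damp their biosynthesis
steps. For this fixture that yields feedback on the iron-sensor
biosynthesis (sensing the cytosolic labile pool), the mitochondrial
iron importer (double regulation by the mitochondrial pool and free
heme), the respiratory chain, the glutaredoxin pool, and — because the
global growth mode (ribosome and DNA autocatalysis) is the dominant
weakly-unstable direction in a model this small — self-limitation of
ribosome biosynthesis and DNA replication. In this reduced network the
unregulated system is only weakly unstable (it holds its steady state
to $10^{-10}$ over 100 min and drifts slowly under perturbation), so
the tests assert short-horizon persistence for the unregulated model
and full recovery from ±50% labile-iron steps for the regulated one.

## The synthetic generator

`synthetic_network` emulates the *structural* conditions of the model
family — several compartments with the cytosol largest, carbon-balanced
irreversible conversions flowing from nutrient imports to destination
sinks, one dilution per component, $(S_0|-D)$ structure of full row
rank, and a strictly positive steady flux — with all randomness fixed
by one seed. Rates are built constructively (each component passes at
most 70% of its inflow downstream and dilutes the rest), so positivity
is guaranteed rather than sampled-and-checked, and concentrations again
follow from the dilution balance. It deliberately does **not** emulate
catalysis, regulation, reversibility, multi-substrate stoichiometry, or
iron chemistry; what passing ensemble tests show is that the null-space
machinery (rank structure, nonnegative basis, singleton solve, weight
recovery) is correct on the class of growth-dilution networks, not that
the biology of any real network is captured. Ensemble sizes in the
tests (100 seeded networks of 4–11 components; brute-force extreme-ray
enumeration only on systems of at most 8 reactions, where subset
enumeration is exact) were chosen so the whole suite stays
interactive-fast while still exercising every code path.

## Known limitations

* Irreversibility is a modeling commitment; reversible chemistry must
  be encoded as explicit opposing reaction pairs (as the sensor pair
  is), which enlarges the matrix and adds exchange-cycle basis columns.
* The nonnegative basis is a basis, not a minimal generating set of the
  cone; no elementary-flux-mode or minimality claims are made, and
  weight nonnegativity for an arbitrary feasible flux is only
  guaranteed for the anchored construction.
* Components decay only by dilution; real turnover (notably of
  kinetically labile iron–sulfur clusters) would shorten the long
  recovery timescales the simulations show.
* Population volume growth is not simulated; the model describes the
  expanding-steady-state average cell.
* Carbon bookkeeping is schematic by design; conclusions about carbon
  metabolism are outside the model's scope.
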