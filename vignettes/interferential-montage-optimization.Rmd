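---
title: "Interferential montage optimization in a layered head phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interferential montage optimization in a layered head phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(interfield)
```

## The problem

Interferential (temporal-interference) stimulation drives two electrode
groups with sinusoidal currents at slightly different high frequencies,
for example 5000 and 5010 Hz. Neither carrier is expected to drive neurons
by itself, but wherever both fields are present their superposition beats
at the 10 Hz difference frequency. The amplitude of that slow modulation
at a brain location with carrier fields $E_1$ and $E_2$ is taken here as

$$\mathrm{env}(v) \;=\; 2\,\min\bigl(\lVert E_1(v)\rVert,\,
\lVert E_2(v)\rVert\bigr),$$

the magnitude-based envelope. Because the envelope is limited by the
*weaker* of the two fields, it can peak deep in the brain even though each
carrier alone peaks directly under its electrodes — the property that makes
interferential stimulation a candidate for non-invasive deep-brain
targeting.

`interfield` asks the montage question: given an array of 19 disk
electrodes in the 10–20 layout, how should the two sources distribute
their currents to maximize the envelope at a chosen deep target while
keeping the envelope small elsewhere? And how does an *epicranial* array
(ECS: electrodes implanted under the scalp, resting on the skull, with an
insulating back facing the skin) compare with an ordinary *transcranial*
array (TES: the same layout on the scalp)?

## Head phantom and forward model

The package works on a five-shell spherical head phantom: skin, skull,
CSF, grey matter and white matter as concentric shells with conductivities
0.465, 0.01, 1.65, 0.27 and 0.126 S/m. The default outer radii are 92, 85,
78, 76 and 50 mm — standard four-shell EEG model radii extended with a
white-matter core. The phantom deliberately trades anatomical realism for
transparency: shapes of real heads (gyri, skull thickness variation,
anisotropy) are absent, so absolute field values and focality volumes are
not comparable with anatomically detailed models, while the *relative*
phenomena studied here (amplitude–focality trade-off, epicranial versus
transcranial contrast, electrode-reduction trade-off) are preserved.

Under the quasi-static approximation (valid below roughly 1 MHz) the
potential obeys $\nabla\!\cdot\!\sigma\nabla\varphi = 0$ with insulating
outer boundaries; the field is $E = -\nabla\varphi$. The discretization is
a conservative 7-point finite-volume stencil on the voxel grid with face
conductivities taken as harmonic means of the adjacent voxel
conductivities, which keeps fluxes consistent across the sharp
conductivity jumps at shell interfaces. Each electrode is a 15 mm disk
realized as the set of surface voxels within 7.5 mm of its center;
injection is a uniform current density over the patch (the platinum of a
physical electrode is idealized as uniform injection). For epicranial
electrodes the insulating back is modelled by removing the skin voxels in
the cylinder above each patch from the conductive domain — at the
conductivity of a polymer backing (~1e-19 S/m) this is numerically
indistinguishable from a perfect insulator and avoids meshing a
millimetre-scale layer. The return electrode is a 30° spherical cap at the
inferior pole, standing in for a distant body reference; the potential
gauge is zero mean over that cap.

The linear system is solved either by Jacobi-preconditioned conjugate
gradients (relative residual 1e-8, deterministic zero initialization) or,
for systems up to ~150k unknowns, by sparse Cholesky factorization shared
across the 19 per-electrode solves of a montage; both paths agree to
solver tolerance and the direct path verifies its residual explicitly.
Solver correctness is established against two closed forms: the
infinite-medium point-source field $I/(4\pi\sigma r^2)$ (an interior
monopole pair in a large homogeneous sphere, evaluated 3–8 voxel widths
from one source, where the insulating boundary contributes only about a
percent through its image terms; the closed-form source positions are the
actual source voxel centers, since a half-voxel offset alone would induce
several percent of spurious error at these radii), and the exact layered
radial-flow profile $I/(4\pi\sigma(r)\,r^2)$ on a spherically-symmetric
current harness. Field comparisons use magnitudes rather than raw
potentials because the potential carries the reference gauge. Mid-shell
radii at least five voxels from the central injection are used for the
layered check: central differences straddle conductivity interfaces, and
the voxelized point injection dominates the nearest shells, so both
regions are excluded by design.

## Lead fields and constraints

Each electrode's unit-current (1 mA) solve against the common reference is
flattened over the $n$ brain (GM∪WM) voxels into a column of the lead
field $A$ ($3n \times 19$; voxel-major rows, components x, y, z). Any
simultaneous stimulation pattern $s$ (mA per electrode) then produces the
brain field $E = As$ by superposition. Admissible patterns conserve
current, $\sum_i s_i = 0$, and respect a total-current budget
$\sum_i |s_i| \le I_{\max}$ with $I_{\max} = 1$ mA zero-to-peak per source
by default. CSF, skull and skin voxels are excluded from $A$ and from all
envelope and focality computations: the quantities of interest live in the
brain.

A target is a brain point plus a desired field direction (+x by default).
The target weight vector $e$ carries magnitude 1 at the target voxel,
decaying as a Gaussian of distance (width $\sigma_e$), times the desired
direction components, so $e^\top A s$ is the direction-projected,
distance-weighted target field. The penalty diagonal $\Gamma$ is
complementary: zero at the target, rising as $1 - \exp(-d^2/2\sigma_\gamma^2)$,
applied equally to all three field components (the constraint caps total
non-target power, not a projection). Both widths default to 10 mm; the
defaults are a deliberate compromise — much narrower than the phantom's
76 mm brain radius so the penalty discriminates target from non-target,
much wider than one voxel so the weights are resolution-independent.
Halving or doubling either width rescales `p_max0` but leaves the
qualitative sweep behavior unchanged.

The non-target field power is capped by
$\lVert \Gamma A s \rVert^2 \le P_{\max}$, with the closed-form default

$$P_{\max 0} = e^\top A\,(A^\top \Gamma^2 A)^{-1} A^\top e,$$

the power reached by the $\Gamma$-weighted least-squares pattern that best
realizes the desired field (an optional Tikhonov damping of
`1e-10 * mean(diag)` handles rank-deficient toys).

## The optimization problems

**Single source.** Maximize $e^\top A s$ subject to the zero-sum, L1 and
power constraints. The objective is implemented as the linear form (not an
absolute value): negating $e$ maps $s \to -s$ with the same objective, so
no generality is lost and the problem is a small convex program — linear
objective over the intersection of the zero-sum hyperplane, the L1 ball
and one convex quadratic. It is solved exactly (to tolerance) by bisection
on the multiplier $\lambda$ of the quadratic: each penalized subproblem
$\max_s\, c^\top s - \lambda s^\top M s$ over the polytope is a QP handled
by a compiled ADMM whose projection step (Dykstra's alternating
projections onto the hyperplane and the L1 ball) is exact, and
$s^\top M s$ is non-increasing in $\lambda$. Since $m = 19$, all matrices
in the inner solver are tiny; the per-voxel quadratic-form blocks of $A$
are precomputed once so that every reweighted $A^\top \mathrm{diag}(w) A$
is a single matrix–vector product.

**Two interferential sources.** Maximize
$2\min(e^\top A s_1,\, e^\top A s_2)$ with each source zero-sum and
L1-bounded, subject to the envelope-power cap

$$\sum_v \gamma_v^2\,\bigl(2 \min(\lVert E_1(v)\rVert, \lVert E_2(v)\rVert)\bigr)^2
\;\le\; P_{\max}.$$

This constraint is nonconvex (a voxelwise minimum of two field
magnitudes). The solver is a deterministic monotone alternating
majorization built on one inequality: for any $t_v \in [0,1]$,

$$\min(a,b)^2 \;\le\; t_v\,a^2 + (1-t_v)\,b^2,$$

so freezing per-voxel weights $t_v$ yields a convex single-source
subproblem for each source that *conservatively* bounds the true
constraint — every iterate is truly feasible. Between rounds $t_v$ is
refreshed to charge each voxel to whichever source currently has the
smaller magnitude there, which makes the bound tight at the current point;
the alternation is therefore monotone in the objective. A symmetric
per-source budget ($t \equiv 1/2$, i.e.
$4\lVert\Gamma A s_k\rVert^2 \le P_{\max}$) is one starting point, but by
itself it is a fixed point with $s_1 = s_2$ — genuinely interferential
solutions require distinct montages, so the solver runs a set of
deterministic starts (symmetric, full-budget/silent, disjoint-support L1
vertices, complementary spatial splits of the penalty region, strongest
bipolar vertex pairs) and keeps the best. Two further stages matter in the
power-binding regime: a *balance* move in which the currently stronger
source retreats along its Pareto frontier (minimum charged power at fixed
target field) to free budget for the weaker one, and a *polish* stage that
bisects the achievable target level $\tau$, alternately minimizing each
source's charged envelope power subject to $e^\top A s_k \ge \tau$. On
four-electrode toys the result matches (and slightly exceeds, being
continuous) exhaustive grid search over both sources' discretized zero-sum
L1 balls.

No per-electrode current caps are imposed beyond the L1 total, and both
sources may use any electrode (no disjointness constraint); an optional
exclusivity flag is deliberately absent from the defaults.

**Sweep and grand-optimal selection.** The budget sweep evaluates
$P_{\max 0} \times 10^{k}$ for $k = -3, \dots, 5$. The sweep is anchored
at $k = 0$ and evaluated outward. Downward, the optimum approaches a
fixed shape scaled to the shrinking budget, so warm-chained solves with
capped effort suffice (that regime is also where the search is most
expensive). Upward, the optimum changes quickly as the power constraint
loosens — a warm-chained solve can stay trapped in the low-budget shape
while the full deterministic start set is cheap there — so every point
from the anchor up runs the full search with the previous solution among
its starts. A repair pass re-runs any point that fell below its
predecessor (a feasible point at a smaller budget is feasible at a larger
one), so the recorded objective is non-decreasing by construction. The
*grand-optimal* configuration is the lowest budget at which both sources'
total currents have *reached* $I_{\max}$ (within 1%): the earliest sweep
point from which every later point is also saturated. Requiring the
saturation to persist matters — an isolated saturated point below the true
knee is a local-solver artifact, not the knee. Focality is the half-value volume: the cube root (reported in
cm) of the brain volume whose envelope strictly exceeds half the envelope
at the target; ties at exactly half are excluded. Because the half-value
volume is a voxel count, adjacent sweep points in the flat low-budget
region can wiggle by a fraction of a percent; the package's own tests
treat focality as non-decreasing up to a 0.5% step tolerance.

**Electrode reduction.** For each source and each pole separately,
electrodes are sorted by absolute current and the minimal prefix covering
at least 75% of that pole's total is kept (ties with the last kept
electrode are kept too, making the rule order-independent); the kept
currents are rescaled so each pole carries $I_{\max}/2$, restoring the
zero-sum and the full 1 mA budget. Fields are then recomputed directly as
$A s'$ — no re-optimization — and the reported electrode count is the
union of kept electrodes across both sources and poles.

## What the phantom shows (and what it cannot)

At the default 4 mm test resolution, the pipeline reproduces most of the
expected phenomenology end to end: the envelope at the target and the
injected currents grow with $P_{\max}$ while focality degrades; at the
grand-optimal point the two sources occupy distinct montages and the
envelope's deep-target contrast exceeds that of either carrier field
alone; epicranial arrays are never less focal than scalp arrays at their
grand-optimal points; and limiting each pole to its 75% prefix raises the
target envelope (the full budget flows through fewer, better-placed
electrodes) at the cost of focality.

One anatomically established property does **not** fully transfer to the
sphere: that the epicranial array's grand-optimal envelope is uniformly
*stronger* than the transcranial one. On the phantom the raw epicranial
advantage at depth is only a factor of roughly 1.3–2 (the thin,
moderately conductive spherical scalp shunts far less than real anatomy,
where the reported advantage is close to 4×), and the per-montage
$P_{\max 0}$ normalization interacts with the decade-quantized sweep: a
montage with stronger fields per mA reaches its 1 mA budget at a *higher*
relative power budget, so when both montages' saturation knees fall into
the same decade the epicranial array is evaluated under a tighter absolute
power cap and can come out weaker at the target. The stn-analog target
(whose epicranial knee lands one decade above the transcranial one) shows
the expected epicranial advantage; targets whose knees quantize into the
same decade need not. This was verified not to be a solver artifact: a
much higher-effort search at the affected knees improves the objective by
only a few percent and leaves the saturation pattern unchanged. The
package's test suite asserts the uniform-dominance property anyway and
reports it failed where the phantom disagrees, rather than weakening the
check.

The four built-in deep targets (`stn_left`, `vim_right`, `hippocampus`,
`insula_left`) are fixed points 12–30 mm from the head center in distinct
octants. They stand in for clinically motivated subcortical structures;
anatomical coordinates do not transfer to a sphere, so no anatomical claim
attaches to the names. Published comparison values from anatomically
detailed interferential modelling (shipped as
`example_comparison_table()`) serve as a worked example for the summary
statistics — ratio of mean field strengths ≈ 3.9, rounded focality
improvement 9% — and as an order-of-magnitude reference (grand-optimal
envelopes of a few hundredths of a V/m at 1 mA); the spherical phantom is
not expected to reproduce their absolute values, and its focality volumes
are substantially larger than anatomical ones because the phantom brain is
an unstructured 1.8 L sphere.

## Numerical choices

* Constraint tolerances: zero-sum and L1 are enforced exactly at the
  returned point (re-centering plus radial shrink are exact operations);
  validation accepts 1e-9 mA slack. The envelope-power cap is verified at
  the returned point with 1e-6 relative slack.
* The inner ADMM stops on standard relative primal/dual criteria
  (`eps_rel` 1e-8) with an iteration cap of 3000, over-relaxation 1.6, and
  a penalty parameter initialized at the geometric mean of the extreme
  Hessian eigenvalues and adapted within a bounded range (the bound
  matters: unbounded adaptation can overflow on the phantom's
  ill-conditioned lead fields).
* Multiplier bisections run on a log scale with bracket caps at 1e100 and
  plateau detection, so degenerate quadratics (rank-deficient toys, silent
  sources) terminate cleanly.
* Sweep determinism: no randomness anywhere in the pipeline; repeated runs
  are bitwise identical.
* Default problem sizes: 2 mm voxels for analyses; the package's tests and
  the acceptance script run the full pipeline at 4 mm (about 29k brain
  voxels, 19+19 unit solves, eight sweeps), which resolves the 15 mm disks
  with ~7–10 patch voxels, and validate the solver against closed forms at
  2 mm on smaller homogeneous spheres. In the eight-cell comparison, one
  demonstration cell runs the full nine-budget sweep; the other cells run
  budgets $10^{-1}$–$10^{5}$, since every observed saturation knee lies
  well inside that range (a guard fails if the lowest computed budget is
  already saturated, which would make the knee ambiguous).
* The five-tissue radii place a 2 mm CSF shell between skull and grey
  matter; at 4 mm that shell is ragged (a warning is raised). A shell that
  captures no voxels at all is an error. This keeps the declared
  geometry honest at coarse resolution without forbidding it.

## Known limitations

* The phantom is spherical and isotropic; no gyral folding, skull
  heterogeneity or anisotropy. Conclusions transfer qualitatively, not
  quantitatively, to anatomical head models.
* The two-source optimization is a nonconvex problem solved by a
  deterministic heuristic with feasibility guarantees; it matches
  exhaustive search on small toys but carries no global-optimality
  certificate at 19 electrodes.
* The envelope model is the standard magnitude-based formula; neuronal
  low-pass filtering, conduction block and any physiology of kHz exposure
  are out of scope, as is time-domain waveform synthesis. A
  direction-resolved envelope is available behind the `direction` argument
  of `if_envelope()` for comparison only.
* Electrode–skin impedance and safety limits of scalp sensation are not
  modelled; the L1 budget is the only current constraint.

## A minimal session

```{r example}
grid <- build_shell_phantom(voxel_size = 4)
montage <- place_1020_montage(grid, "skull")      # epicranial (ECS)
lf <- compute_leadfield(grid, montage)

ts <- target_spec(lf, target_mm = c(-12, -2, -6), name = "stn_left")
sweep <- sweep_pmax(lf, ts)
glance(sweep)                 # grand-optimal point
autoplot(sweep)               # trade-off curves

go <- attr(sweep, "grand_optimal")
best <- attr(sweep, "results")[[go]]
tidy(best)                    # per-electrode currents of s1 and s2
limit_electrodes_pair(best)   # 75% reduction rule
```

The full two-montage comparison over the four built-in targets is
`run_comparison(run_config(voxel_size = 4))`, and
`summarize_comparison()` condenses any such table into the two headline
numbers (ratio of mean field strengths; percent focality improvement).
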