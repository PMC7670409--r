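---
title: "Path-based similarity indices for link prediction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based similarity indices for link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlink)
```

## The problem and the model

A network observed from a real complex system — a protein interactome, a
neural wiring map, a metabolic graph — is almost always incomplete. Link
prediction ranks the node pairs that are *not* observed links by a
structural similarity score, on the premise that pairs resembling linked
pairs are the most plausible missing interactions. All scores in this
package are functions of the simple, undirected, unweighted graph alone:
no node attributes are used.

The local indices score a pair from its immediate neighbourhood. With
$\Gamma(u)$ the neighbour set and $d_u = |\Gamma(u)|$:

| index | set form | matrix form |
|---|---|---|
| CN | $|\Gamma(u)\cap\Gamma(v)|$ | $A^2$ |
| RA | $\sum_{w\in\Gamma(u)\cap\Gamma(v)} 1/d_w$ | $AD^{-1}A$ |
| AA | $\sum_{w} 1/\log d_w$ | $A(\log D)^{-1}A$ |
| SO | $2\,\mathrm{CN}/(d_u+d_v)$ | elementwise on $A^2$ |
| SA | $\mathrm{CN}/\sqrt{d_u d_v}$ | $D^{-1/2}A^2D^{-1/2}$ |
| LHN | $\mathrm{CN}/(d_u d_v)$ | $D^{-1}A^2D^{-1}$ |
| HP | $\mathrm{CN}/\min(d_u,d_v)$ | elementwise |
| HD | $\mathrm{CN}/\max(d_u,d_v)$ | elementwise |

plus the PA ($d_u d_v$) and Jaccard baselines. Every entry of $A^k$ counts
*walks* of length $k$; although the literature often says "paths", all the
matrix forms above (and every extension below) count walks, which may
revisit nodes. The package follows the matrix forms, which is what makes
the extensions well defined.

Each of the eight degree-aware indices is extended in two directions. The
**global extension** replaces the single length-2 walk count with the full
damped walk series in the index's *propagator* $W$ — $A$ for the CN family,
$D^{-1}A$ for RA, $(\log D)^{-1}A$ for AA:

$$\mathrm{CN}_G = \sum_{l\ge1}\beta^l A^l = (I-\beta A)^{-1}-I
  \quad(\text{the Katz index}),$$
$$\mathrm{RA}_G = \beta AD^{-1}A + \beta^2 AD^{-1}AD^{-1}A + \cdots
  = A(I-\beta D^{-1}A)^{-1}-A,$$

and analogously for AA. The five Sørensen-type indices keep their endpoint
normalisation but apply it to the Katz matrix $K$ instead of $A^2$, e.g.
$\mathrm{SO}_G(u,v) = 2K(u,v)/(d_u+d_v)$. The **quasi-local extension**
keeps only the first two series terms (walks of length 2 and 3), e.g.
$\mathrm{RA}_{QL} = AD^{-1}A + \beta AD^{-1}AD^{-1}A$ and the local-path
index $A^2+\beta A^3$ for CN. Quasi-local indices need only two sparse
matrix products instead of a resolvent, which is why they are the practical
choice for large networks.

One deliberate asymmetry is preserved from the defining forms: the global
series starts at $\beta^1$ while the quasi-local forms carry no leading
$\beta$ on their first term. We implement both exactly as defined rather
than rescaling them to match — AUC and every ranking-based quantity are
invariant under a positive per-index scale factor, so the discrepancy is
cosmetic, and fidelity to the published forms makes cross-checking easier.

## Parameters

**Damping weight $\beta \in (0,1)$** (default 0.001, dimensionless): walks
of length $l$ are weighted $\beta^l$, so $\beta$ sets how quickly long
walks stop mattering. The default follows the standard experimental
protocol for these indices; sweeps over
$\{0.001, 0.005, 0.01, 0.05, 0.1\}$ are supported and show accuracy
degrading at large $\beta$, where long walks — pure topology noise for
prediction — gain weight.

**Convergence.** The series converges iff $\beta\rho(W) < 1$, $\rho$ the
spectral radius. Notably $\rho(D^{-1}A) = 1$ on any graph without isolated
nodes (row-stochastic propagator), so RA$_G$ converges for *every*
$\beta < 1$ — one reason it is the most robust global index. For the CN
family $\rho(A)$ grows with density, and large $\beta$ can cross the
boundary; `extension_params(convergence_policy=)` then chooses between an
error naming $\rho(W)$ and a truncated-series fallback (default, at
truncation order 10, with a warning and a `truncated` flag on the result).
The fallback mirrors how a diverging series is handled in practice: the
first few terms still carry the ranking signal.

**Truncation order $L \ge 2$** (maximum walk length, default 10):
`truncated_global_scores()` exposes the partial sum directly. In the
convergent regime the geometric tail bound is
$(\beta\rho)^{L+1}/(1-\beta\rho)$; our equivalence tests compare closed
form against an $L=60$ truncation at $\beta\rho = 0.6$, where that bound
($\sim 3\cdot10^{-14}$) sits far below the $10^{-8}$ assertion tolerance.
Near the convergence boundary the tail itself dominates any such tolerance,
so no finite truncation "equals" the closed form there.

**Probe fraction** (default 0.1): the fraction of observed links hidden
for evaluation, rounded half away from zero with a minimum of one probe
edge and at least one training edge. Sweeps over 0.1–0.5 emulate
increasing structural noise.

## Numerical and design choices

- **0/0 convention.** Degree-normalised entries with zero walk count score
  0, matching the set forms, and all degree-inverse diagonals are guarded:
  $1/d \to 0$ for $d=0$, $1/\log d \to 0$ for $d \le 1$. Degree-1 common
  neighbours cannot occur in an intact simple graph, but the guards keep
  every matrix finite on training graphs after edge splitting, where
  isolated endpoints are retained so matrix dimensions stay stable across
  splits.
- **Natural logarithm in AA**, the standard convention.
- **Resolvents by linear solve** against identity columns, never an
  explicit inverse expression; dense at the package's intended scale
  (up to a few thousand nodes).
- **Score diagonals are forced to zero** and existing training links are
  excluded from candidate rankings: the task concerns non-observed pairs.
- **Candidate set.** Nonexistent links $E' = U \setminus E$ are always
  defined against the *full* edge set, so probe links never contaminate
  the negative class.
- **AUC mode.** Exhaustive comparison (equal to the normalised
  Mann–Whitney statistic) up to $10^7$ probe×candidate comparisons,
  seeded sampling with $10^5$ draws beyond. Ties receive the 0.5 credit of
  the defining formula; precision@L breaks ties by pair index order.
- **Seeding.** A single base seed expands additively into per-repetition
  split seeds, and all indices evaluated at the same base seed and probe
  fraction share identical splits, so method comparisons are paired. RNG
  is R's Mersenne-Twister throughout.
- **Small-$\beta$ reduction.** As $\beta \to 0$ each extension's ranking
  converges to its local index's ranking *as a refinement*: strictly
  ordered local pairs keep their order, while local ties (numerous — every
  pair without common neighbours scores 0 locally) are resolved by
  longer walks. Because of those tie groups a raw rank correlation between
  extension and local scores plateaus below 1 even in the limit; the
  package's tests therefore assert strict-pair concordance equal to 1
  (with a $10^{-9}$ gap floor absorbing floating-point noise between
  mathematically equal scores) rather than a correlation threshold.
- **Topology statistics.** Clustering is the mean local clustering over
  nodes of degree $\ge 2$ — the convention that reproduces the published
  value 0.588 for the karate club network (including degree-<2 nodes gives
  0.571). Mean path length averages unweighted shortest paths over
  unordered reachable pairs within the largest connected component (2.408
  for karate; conventions that average ordered pairs or include an extra
  factor of two circulate in the literature). Heterogeneity is reported in
  both circulating conventions: $\langle k^2\rangle/\langle k\rangle^2$
  (equal to 1 for any regular graph) and $\langle k^2\rangle/\langle
  k\rangle$.
- **LCC tie-break**: the component containing the smallest node index, for
  determinism.

## What the synthetic generators emulate

Tests and the acceptance script run on seeded Erdős–Rényi graphs (null
model without structure), two-block stochastic block models (planted
community structure, the regime where similarity-based prediction beats
chance — the bundled check uses blocks of 30 with $p_{in}=0.3$,
$p_{out}=0.02$, a strong but not extreme community contrast at a size
where exhaustive AUC is exact), and canonical graphs (path, cycle, star,
complete) whose index values are hand-derivable. The experiment scales
used by the test suite — graphs of 20–100 nodes, 20–100 repetitions — are
the package's chosen verification sizes; they keep exhaustive AUC exact
and every closed form checkable against brute force.

Real benchmark networks differ from these fixtures in ways that matter:
heavy-tailed degree distributions, degree assortativity, high clustering,
and scale. Passing tests demonstrate that the formulas, the evaluation
protocol and the convergence handling are correct, and that the extensions
behave qualitatively as expected on community-structured data; they do not
by themselves certify accuracy rankings between indices on any particular
real network. The worked karate-club example in the README shows the
qualitative effect carrying over to a small real social network.

## Known limitations

- Weighted, directed, temporal and bipartite networks are out of scope.
- Dense resolvent evaluation bounds the practical size of global indices
  to a few thousand nodes; quasi-local indices are the intended tool
  beyond that.
- The local-community (CAR-type) indices and global baselines such as the
  matrix-forest index are not implemented.
- Precision@L conventions vary across the literature; ours (pool
  $E^P \cup E'$, deterministic tie-break) is stated above and in
  `?precision_at_l`.
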