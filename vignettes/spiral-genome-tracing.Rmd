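---
title: "Spiral genome tracing: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiral genome tracing: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaspool)
```

## The problem

In many tailed double-stranded DNA phages the packaged genome winds as a
coaxial spool: concentric shells of duplex DNA, each shell wound as a
multi-start spiral about the capsid axis. Cryo-EM maps resolve this
winding as layered, striated density, but building coordinates into it is
laborious. `dnaspool` automates the coarse-to-fine route: generate a
parametric spiral of pseudoatoms (one per base pair), score it against the
map, scan the spiral parameters to locate the winding shells, and finally
replace each pseudoatom by a rigidly placed idealized base pair to obtain
an all-atom duplex.

## The spiral models

Both families are parameterized by radius $r$, pitch $p$ (distance between
consecutive turns measured along constant azimuth $\varphi$), angular
offset $\varphi_0$, a center and an axis. A spherical spiral satisfies

$$\theta = \frac{p}{2\pi r}\,(\varphi - \varphi_0),$$

with $\theta$ the polar angle from the axis, between bounds
$[\theta_{start}, \theta_{end}]$; its pitch is constant over the whole
shell, which is exactly what uniformly spaced wound DNA requires. A
cylindrical spiral satisfies $z = \frac{p}{2\pi}(\varphi-\varphi_0)$ from
$z=0$ to the cylinder height $h$.

A shell wound by $n_{pe}$ strands at once (the *points of entry*, like a
multi-start screw thread) is the union of $n_{pe}$ copies of the spiral at
offsets $\varphi_0 + 2\pi k/n_{pe}$. Faceted capsids depart slightly from
ideal spheres and cylinders; the winding radius can therefore be modulated
harmonically, $r(\varphi) = r + \sum_k a_k \cos(k\varphi+\psi_k)$, which
by Fourier's theorem can absorb any smooth azimuthal perturbation. Only
$r$ is modulated; this is where the departure is observed in practice.

### Pseudoatom placement

Nothing in the geometric model dictates where along the curve the
pseudoatoms sit. Since one pseudoatom represents one base pair, we place
them at equal *arc length* steps of `rise` (default 0.34 nm, the canonical
B-DNA rise). The curve speed $|d\mathbf{x}/d\varphi|$ is analytic for both
families (including harmonic modulation); cumulative arc length is
integrated by a composite trapezoid on a grid refined to $\ll$ one rise
and inverted by monotone interpolation. Emitted points are exact curve
evaluations, so they lie on the spiral surface to machine precision, and
a strand of arc length $L$ carries $\lfloor L/\mathrm{rise}\rfloor + 1$
points. Traces are emitted 5′-side first (from $\theta_{start}$, or from
$z = 0$), fixing chain direction downstream.

Angles are radians in the R API and degrees at the command line and in
all reports. The polar start $\theta_{start}=0$ is allowed: the equation
is singular in $\varphi$ at the pole but the position is not, and the
first point sits exactly on the axis.

## Density maps and the fitting energy

Maps are MRC/CCP4 2014 volumes (mode 2, float32). On read, the axis
permutation (`mapc/mapr/maps`) is normalized to X,Y,Z, the origin is taken
from the `origin` words or from `nstart`, and Angstroms become nm. The
fitting energy of a trace is

$$E = -\sum_i \rho(\mathbf{x}_i),$$

the negated sum of trilinearly interpolated map values at the pseudoatom
positions, so lower is better. The exact functional used by the reference
method is not published; this is the simplest convention that reproduces
its qualitative scan behavior (sharp minima at shell radii, azimuthal
minima at the packing register). Points outside the grid contribute zero
rather than a penalty — a penalty would make scans over the center
discontinuous — and the outside fraction is reported. The default scan
objective is energy *per atom*, because changing $r$ changes the number of
base pairs in a fixed-extent spiral; the total is available by flag.

## Parameter scans, coordinate descent, shell detection

The optimization primitive is the deterministic grid scan (`scan_parameter`),
matching the reference protocol; gradient methods are deliberately absent.
Exact ties break toward the lowest parameter value. $\varphi_0$ scans are
meaningful only modulo $360°/n_{pe}$, the period of the multi-start family.

`coordinate_descent` cycles through scan plans, updating the spec to each
argmin, and stops when a full round moves no parameter by more than its
own step (or at `max_rounds`, then flagged unconverged rather than
erroring). On noise-free planted cylindrical maps this settles in at most
two moving rounds: $r$ and $\varphi_0$ decouple because $\varphi_0$ only
sets the azimuthal register. For *spherical* spirals spanning many turns,
$r$ and $\varphi_0$ trade off along a diagonal valley (changing $r$
rephases the whole winding), and descent zig-zags over several rounds —
which is why tracing an icosahedral map calls for repeatedly optimizing
$\varphi_0$ at each local minimum of $r$. Our acceptance tests assert the
two-round property for cylindrical geometry only and exercise the
spherical case through single-parameter recovery.

`detect_shells` scans $r$, keeps discrete local minima of the energy curve
whose prominence exceeds `min_prominence` (default 0.05) times the curve
range, and refines each shell with a local $\varphi_0$ scan. The reference
analysis identified shells by eye on the energy trace; a prominence
threshold makes that reproducible, and the default is an exposed choice,
not a published constant.

## Synthetic maps: the stated world

`synth_map` splats an isotropic Gaussian (peak `amplitude`, width `sigma`,
truncated at $4\sigma$) at every pseudoatom, on a grid bounding the trace
plus padding, with optional seeded i.i.d. Gaussian voxel noise. Defaults:
$\sigma = 0.5$ nm (about half a duplex radius, so adjacent shells 2.0–2.5
nm apart remain separable, as in the real maps), voxel 0.4 nm (the 4–5 Å
regime of the source maps), amplitude 1, and "SNR 3" noise defined as
`noise_sd = amplitude/3`. These values are fixed as the validation world;
they are not tuned against test outcomes.

What the generator emulates: layered spiral density, overlap between
nearby shells, voxel noise, arbitrary axis orientation and origin. What it
does not: CTF and B-factor envelopes, rotational-averaging artifacts,
protein density, masking. A green recovery test therefore establishes that
the estimator recovers planted winding parameters under Gaussian blur and
noise — not that any particular real map is explained. Refits of real
EMDB maps are out of scope by design.

## All-atom building

Base pair $i$ is an idealized Watson–Crick pair rigidly transformed so
that its origin lands on trace point $i$, its z-axis lies along the local
curve tangent (central finite differences, one-sided at the ends), and its
in-plane orientation follows a rotation-minimizing frame (double
reflection) advanced by `twist_per_bp` (default 36°, 10 bp/turn) per step.
Frenet frames are avoided because they flip at inflection points and
inject spurious twist. The initial frame normal is taken from the curve's
own curvature direction so that models built on rigidly transformed traces
are related by the same transform; for straight traces, where no
curvature exists, a fixed world-axis convention supplies the (physically
unobservable) twist phase.

The packaged template (`inst/extdata/bdna_pair_template.txt`) holds the
heavy atoms of one WC pair per strand-A base, in a pair-local frame,
derived from idealized Arnott-type fiber-diffraction B-DNA (generated at
build time with a standard helix generator, untwisted to the local frame;
the file header records the provenance and the measured 0.338 nm /
36.000° step). It is an idealized synthetic construct, not experimental
coordinates, and any template file with the same columns may be
substituted.

Because placement is rigid, inter-residue O3′–P bonds are compressed on
the inside of a curved trace and extended on the outside.
`bond_strain_report` tabulates every such bond against a strain-free
reference. The default reference is the O3′–P length of a *straight*
duplex stacked at the model's own base-pair spacing and twist, computed
separately per strand (the fiber pair carries a ~2×10⁻⁴ nm dyad
asymmetry): with that convention the report isolates bending strain and a
straight build is strain-free by construction, independent of whether the
trace rise (0.34 nm) matches the template's native 0.338 nm step. A
force-field minimization to anneal these bonds is a post-processing step
outside this package's scope; the report is its diagnostic stand-in.

When no sequence is supplied, a repeating AT alternation is used and
flagged in the output headers. Entry strand $k$ becomes one duplex
segment with chains at positions $2k+1, 2k+2$ of `LETTERS, letters`.

## Capsid geometry rules

`capsid_rules` implements the analytic relations that quantize the capsid
inner diameter of elongated (C3-morphotype) phages in two integers: the
points of entry $n_{pe}$ and the number of shells $n_s$ whose end-cap
turnarounds nest against the portal funnel.

* DNA slope: $\theta_s = \arctan\!\big(p/(2\pi r)\big)$. We implement the
  $2\pi$ form (a helix unrolled onto a plane advances $p$ axially per
  $2\pi r$ tangentially); the bare $\arctan(p/r)$ variant that sometimes
  appears in print is not self-consistent with the interhelical spacings
  below and is therefore not used.
* Intrashell interhelical distance: $d_{ih} = (p/n_{pe})\cos\theta_s$.
* Intershell interhelical distance:
  $\sqrt{(d_{ih}/2)^2 + \Delta r^2}$ (hexagonal-like offset packing).
* Hexagonal packing offset between consecutive shells:
  $360°/(2 n_{pe})$.
* Dome turns (even $n_{pe}$ only — the rule assumes the leading end and
  the shell crossover share one dome): $n_{pe}/2$ distal,
  $(n_{pe}-2)/2$ at the tail.
* Minimum $n_{pe}$-conserving radius:
  $\mathrm{sep}\cdot n_{pe}/(2\pi)$.
* Portal major diameter: $D_p = 2 L_{cs}\sin\theta_f + D_{mp}$, with
  $L_{cs}$ either given directly or derived as
  $n_s \cdot s_{shell} + C_{cs}$. The two published parameterizations are
  mutually inconsistent (8.5 nm stated vs 7.2 nm derived); both are
  exposed and the direct $L_{cs}$ form is the default.
* Capsid inner diameter:
  $2 d_{arc}(n_{pe}/2-1)\cos\theta_f + 2L_{cs}\sin\theta_f + D_{mp}
  + w_{tr}$, affine in $n_s$ and in $n_{pe}/2-1$ — hence a discrete
  diameter spectrum, tabulated by `capsid_diameter_table`.

Constants $s_{shell} = 2.3$ nm and $d_{arc} = 2.48$ nm default to the
published SU10 values. Reported values are rounded to the published
precision in the acceptance report only; all functions return full
precision.

## Numerical choices

* Arc-length quadrature: trapezoid on $\max(2049, 32\lceil L/\mathrm{rise}
  \rceil+1)$ nodes; spacing uniformity is tested to 1% of one rise.
* Trilinear interpolation is exact on linear fields; points beyond the
  outermost voxel *centers* are "outside".
* Splats are truncated at $4\sigma$ (mass error $<10^{-3}$), and a
  warning is raised when $\sigma < \mathrm{voxel}/2$ (undersampled).
* Scan ties break to the smallest parameter value; scans are pure
  functions, and map noise is seeded, so every pipeline is reproducible
  byte-for-byte.
* Degenerate spiral extent yields a single-point trace with a warning;
  invalid parameters fail validation with the field named.

## Known limitations

* No force-field minimization, conformer restraints/assignment, or
  semiflexible fitting of the dome-to-cylinder connectors; connector
  modeling in the reference workflow is manual and is not reproduced.
* Base-pair steps are uniform: roll/tilt/twist variation along turns is
  neglected, which grows less accurate at small winding radii.
* Shell detection assumes minima separable at the scan step; shells
  closer than about two steps merge.
* The fitting energy has no normalization by map statistics; comparing
  energies across different maps requires care (within-map comparisons
  are the intended use).
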