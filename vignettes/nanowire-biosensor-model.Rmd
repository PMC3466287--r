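---
title: "The analytical nanowire biosensor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The analytical nanowire biosensor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanofet)
```

## The sensing problem

A nanowire field-effect biosensor (BioFET) is a thin semiconducting wire,
wrapped in an oxide shell and a molecular linker layer, immersed in an
electrolyte. When charged biomolecules bind near the surface, their
electric field penetrates the wire and shifts the carrier density, hence
the conductance. `nanofet` predicts the relative conductance change
$\Delta G/G_0$ of such a device from (i) an atomic structure of the
analyte, (ii) the pH and pKa values that set its charges, (iii) the
binding orientation, and (iv) a dozen device and buffer parameters.

The model is deliberately analytical. It trades electrostatic detail for
closed-form transparency: every predicted signal decomposes exactly into
per-charge contributions, which makes it a tool for reasoning about
orientation, screening, and pH trends rather than a quantitative device
simulator.

## The electrostatic model

Three concentric regions are treated in cylindrical coordinates:

* **Wire** ($r < R$): a degenerate carrier gas with one carrier type
  (holes for p-type), screened on the Thomas-Fermi length
  $\lambda_{TF}$, relative permittivity $\varepsilon_{NW}$. The carrier
  density is assumed uniform and unperturbed by surface charges
  (linear response).
* **Oxide shell** ($R < r < R + t_{ox}$): an unscreened dielectric
  $\varepsilon_{ox}$. Charges on or inside the oxide are *not* modelled;
  pH-dependent oxide surface charging is treated as background.
* **Electrolyte** ($r > R + t_{ox}$): Debye screening on the length
  $\lambda_D$ with permittivity $\varepsilon_{sol}$, assumed at
  equilibrium. $\lambda_D$ is an input ([debye_length()] converts a
  buffer composition) because the effective value near the
  functionalization layer can differ from the bulk-buffer one.

A discrete analyte charge $q_j$ sits at total distance $l_j$ from the
semiconductor surface (so $l_j$ *includes* the oxide and linker
thicknesses). Solving the linearized Poisson problem with a charge sheet
at radius $R + l_j$ gives, in terms of modified Bessel functions, the
per-charge attenuation implemented in `screening_factor()`,

$$\Gamma(l) \;=\; \frac{(R+l)\,K_0\!\big((R+l)/\lambda_D\big)}
                       {R\,K_0\!\big(R/\lambda_D\big)} \in [0,1],$$

normalized to 1 at the wire surface and decaying essentially as
$e^{-l/\lambda_D}$, together with two dimensionless factors
(`poisson_factors()`): a *wire response* factor that depends on both
$\lambda_{TF}$ and $\lambda_D$ (and the geometry and permittivities),
and an *electrolyte interface* factor
$K_0(a/\lambda_D)/K_1(a/\lambda_D)$ at the outer oxide radius
$a = R + t_{ox}$, which depends only on $\lambda_D$. The sensitivity is

$$\frac{\Delta G}{G_0} \;=\; \mp\,\frac{2}{e\,p\,R}\sum_j \sigma_j\,
  \Gamma(l_j)\,F_{wire}\,F_{electrolyte},
  \qquad \sigma_j = \frac{N_{mol}\,q_j\,e}{2\pi (R+t_{ox})\,L},$$

with the upper sign for p-type doping: a negative analyte accumulates
holes and increases the conductance, and an n-type wire flips the sign.
$\sigma_j$ spreads each charge of each of the $N_{mol}$ bound molecules
over the outer wire surface, which makes the sum linear in the charges
and consistent with total-charge normalization. Because the closed forms
are not printed in most of the literature this package derives them from
the boundary-value problem directly; the test suite contains an
independent finite-difference solver of the same radial problem and
requires agreement of the full per-charge response (and of the
distance dependence separately) to better than 2% — in practice they
agree to about 0.1%. In the no-oxide limit the expression reduces
exactly to the classic screening-model factor
$\Gamma_0 = \big[1 + \tfrac{\varepsilon_{sol}\lambda_{TF}}
{\varepsilon_{NW}\lambda_D}\tfrac{I_0 K_1}{I_1 K_0}\big]^{-1}$, which is
asserted in the tests as an independent anchor. The split of the
prefactor into the two named factors is a package convention; only the
product is observable.

Two further closed forms complete the device model. The Thomas-Fermi
length of the degenerate gas,
$\lambda_{TF} = \big(\varepsilon_0\varepsilon_{NW}\pi^2\hbar^2 /
(e^2 m^* (3\pi^2 p)^{1/3})\big)^{1/2} \propto p^{-1/6}$
(`tf_length()`, exact inverse `carrier_density()`), ties the screening
length to the carrier density; varying $p$ emulates a back gate. The
default effective mass $m^* = 0.37\,m_e$ (the silicon hole conductivity
mass) makes the default pair $p = 1.11\times10^{24}\,\mathrm{m^{-3}}$,
$\lambda_{TF} = 2.04$ nm mutually consistent to better than 1%; $m^*$ is
an explicit parameter. The base conductance is the Drude value
$G_0 = e\,p\,\mu\,\pi R^2/L$.

### Assumptions worth remembering

* Linear (accumulation/depletion) response only; no inversion or other
  non-linear operation. At full coverage by small analytes the linear
  extrapolation can exceed $|\Delta G/G_0| = 1$, which signals the model
  is outside its validity range, not a numerical problem.
* The wire surface is treated as locally flat for geometry (offsets,
  bounding boxes); curvature enters only through the cylindrical
  electrostatics.
* The linker carries no charge and binds every molecule identically.

## Protonation model

Each ionizable residue and each chain terminus carries a fractional
charge from the Henderson–Hasselbalch relation (`titration_charge()`):
acids (Asp, Glu, Tyr, Cys, C-terminus) $q = -1/(1+10^{pK_a-pH})$, bases
(Lys, Arg, His, N-terminus) $q = +1/(1+10^{pH-pK_a})$; $|q|$ is the
probability of the charged protonation state. His is classed as a base.
Charges are placed at the mean of the side-chain terminal atoms
(Asp OD1/OD2, Glu OE1/OE2, Lys NZ, Arg NH1/NH2, His ND1/NE2, Cys SG,
Tyr OH); the N-terminus sits on the backbone N of the first residue of
each chain and the C-terminus on OXT (falling back to the carbonyl C
with a warning). Missing side chains are never rebuilt; such a site
falls back to the residue centroid with a warning. For discontinuous
chains the package still adds one terminus pair per chain identifier —
the right treatment of chain breaks is genuinely ambiguous and this is
the simplest deterministic choice.

pKa values come from a null model of intrinsic values
(`default_pka_table()`: Asp 3.8, Glu 4.5, His 6.5, Cys 9.0, Tyr 10.0,
Lys 10.5, Arg 12.5, N-terminus 8.0, C-terminus 3.2) unless a per-site
table from an external structure-based predictor is supplied
(`read_pka_file()`, whitespace format `RESNAME RESNUM CHAIN PKA`).
Computing structure-perturbed pKas is out of scope, and binding to the
wire is assumed not to shift them. Site charges are monotone
non-increasing in pH, so the net charge of any titratable molecule is
strictly decreasing in pH — a property the tests verify.

## Geometry and coverage

`align_principal()` puts the mass-weighted center of mass at the origin
and maps the principal axes of the unit-weight atom cloud to x (largest
extent), y, z (smallest). Axis signs are fixed by requiring a positive
third moment along each axis (first-atom sign as fallback) and the third
axis is the cross product of the first two, so the rotation is proper and
reproducible. `orient()` then applies user rotations; the wire surface is
the plane the molecule is dropped onto, z pointing away from the wire.

`distance_profile()` removes the gap below the molecule (offset by the
most negative site z) and adds the linker and oxide thicknesses, so
free space below the analyte never affects the result and
$\min_j l_j = t_{linker} + t_{ox}$ exactly. `coverage()` estimates
$N_{mol} = \lfloor 2\pi(R+t_{ox})L / A_{face}\rfloor$ from the x–y face
of the all-atom bounding box — the *outer* (oxide) surface and the full
molecular envelope, floored for conservatism. Because it is debatable
whether the molecule count should follow the orientation, a manual
override is supported everywhere. `single_charge()` implements the
coarse mode that places the net charge at the bounding-box center.

## Parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `L_nm` | 2000 | nm | wire length |
| `R_nm` | 10 | nm | wire radius |
| `lambda_TF_nm` | 2.04 | nm | Thomas-Fermi screening length |
| `eps_NW` | 12.0 | – | wire permittivity |
| `mu_m2Vs` | 1e-2 | m²/Vs | carrier mobility |
| `p_m3` | 1.11e24 | m⁻³ | carrier density |
| `doping` | `"p"` | – | carrier type |
| `t_ox_nm` | 2.0 | nm | oxide thickness |
| `eps_ox` | 3.9 | – | oxide permittivity |
| `t_linker_nm` | 1.0 | nm | biolinker thickness |
| `lambda_D_nm` | 2.0 | nm | electrolyte Debye length |
| `eps_sol` | 78 | – | solvent permittivity |
| `N_mol` | 4000 | – | molecules on the wire (or computed) |
| `m_star` | 0.37 | $m_e$ | carrier effective mass |
| `T_K` | 298.15 | K | temperature |

The temperature default is standard laboratory conditions; it enters
only the Debye-length helper. `lambda_TF_nm` and `p_m3` are swept
independently (no hidden re-coupling), since either may be used to
emulate gating.

## The synthetic peptide generator

`build_peptide()` produces the test analyte used throughout: a
KK-(A)$_8$-DD dodecapeptide with two protonated lysines at the
N-terminal end, two deprotonated aspartates at the C-terminal end, and
the termini contributing a third charge at each end (net charge
$-0.202\,e$ at pH 7.4 with the null pKa model). The builder is a fixed
geometric template, not a molecular-mechanics build: an extended
backbone with a 3.3 Å per-residue rise (end-to-end $\approx 4.0$ nm),
side chains on alternating sides tilted slightly out of the backbone
plane so the chain has a finite thickness, and side-chain pseudo-atoms
at idealized fully-extended distances. It emulates what matters for this
model — charge stoichiometry, realistic charge spacing along the chain,
longer Lys than Asp side chains, and a finite bounding box — and nothing
else. It does not emulate real torsional ensembles, solvation, or
structure-dependent pKa shifts; consequently, passing tests demonstrate
the correctness and the qualitative behavior of the *model*, not
quantitative agreement with any laboratory peptide. With an external
structure-based pKa table the net charge moves from $-0.202$ towards the
$\approx -0.23$ expected for a real build of this sequence.

## Numerical choices

* Bessel-function ratios use the exponentially scaled `besselI`/`besselK`
  with the exponents restored analytically, so screening factors remain
  finite for arbitrarily large $l/\lambda_D$ or $R/\lambda_{TF}$.
* The average-height fit (`fit_average_height()`) models the relative
  sensitivity versus $\lambda_D$ series — normalized at the largest grid
  value, with a free global amplitude — as a single charge at height
  $\langle l\rangle$. The amplitude is solved in closed form per
  candidate height; the height is found by bounded 1-D minimization
  seeded from a 0.5 nm grid over 0.5–30 nm, making the fit deterministic
  and robust to local minima. Planted heights of 2–18 nm are recovered
  to $\le 2\%$ from noiseless series and with $\le 10\%$ median error
  under 5% multiplicative noise (50 replicates) in the tests.
* Degenerate inputs fail loudly: empty structures, zero ionic strength,
  flat fit series, zero bounding-box footprints and improper rotation
  matrices raise classed errors rather than producing numbers.
* Multi-model PDB files use the first model only; files without MODEL
  tags are accepted with a notice; alternate locations other than
  blank/"A" are dropped; ties in the principal-axis sign convention fall
  back to the first atom's coordinate.

## Known limitations

* The orientation study exposes a genuine property of the model: for an
  analyte whose far end carries a larger opposite charge than its near
  end (the Lys-down peptide: $+2.80\,e$ near, $-3.00\,e$ far),
  $|\Delta G/G_0|$ is *not* monotone in $\lambda_D$ — it peaks near
  $\lambda_D \approx 5$ nm and declines as the far end comes out of
  screening and cancels the near end. Only the orientation whose near
  charge dominates (Asp-down) grows monotonically over the 0.5–10 nm
  range. Any exponential-type screening kernel behaves this way.
* Signals scale linearly with $N_{mol}$; with complete coverage by a
  small peptide ($\sim 3 \times 10^4$–$6\times10^5$ molecules on the
  default wire, depending on orientation) the predicted $|\Delta G/G_0|$
  can far exceed unity. Interpret such values as "strong response", not
  as a literal conductance ratio.
* No oxide surface charging, no charged linkers, no pKa coupling between
  sites, no downloading or rebuilding of structures.

## Problem sizes

The test suite and the reproduction script run small, fixed problems: a
12-residue peptide (75 atoms, 6 charge sites), sweep grids of 5–20
points, pH grids of ~20–140 points, 10-point Debye series with 50 noise
replicates, and three finite-difference oracle solves on grids of
2–30 thousand radial cells. A full run takes well under a minute on one
core; these sizes were chosen because every statistical and numerical
claim stabilizes far below them.
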