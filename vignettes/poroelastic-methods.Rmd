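---
title: "Biphasic poroelasticity with vanishing porosity: model, discretization and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic poroelasticity with vanishing porosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`porozero` solves large-deformation biphasic poroelasticity built on mixture
theory: at every point of the current configuration a solid skeleton (volume
fraction $\phi_s$) and an interstitial fluid ($\phi_f$, the porosity) coexist
and saturate space, $\phi_s + \phi_f = 1$. Both constituents are
incompressible in their pure form, so the solid fraction follows the solid
deformation, $\phi_s = \phi_{Rs}/J_s$, where $\phi_{Rs}$ is the referential
solid fraction and $J_s = \det \mathbf F_s$.

The primary unknowns are the solid displacement $\mathbf u_s$, the fluid
velocity $\mathbf v_f$ and the pore pressure $p$. Three statements govern
them:

* **Mixture momentum.** $\rho_s(\mathbf a_s - \mathbf b_s) +
  \rho_f(\mathbf a_f - \mathbf b_f) + \nabla p - \nabla\!\cdot\!\mathbf T^e_s
  = \mathbf 0$, with partial densities $\rho_a = \phi_a \rho^*_a$ and the
  elastic Cauchy stress of a neo-Hookean skeleton,
  $\hat\Psi_s = \tfrac{\mu_s}{2}(\bar I_1 - 3)$, volume-weighted by
  $\phi_{Rs}$. The strain energy is purely isochoric; volumetric stiffness
  of the mixture comes entirely from the pore pressure acting as the
  incompressibility multiplier.
* **Rescaled fluid momentum.** The conventional per-phase fluid equation
  carries a Darcy drag $\phi_f^2 (\mu_f/\kappa_s)(\mathbf v_f - \mathbf v_s)$
  and becomes trivial as $\phi_f \to 0$. Dividing it by
  $\eta(\phi_f) = \mu_f\phi_f^2/\kappa_s(\phi_f)$ gives
  $$\frac{\phi_f\rho^*_f}{\eta}(\mathbf a_f - \mathbf b_f) +
    \frac{\phi_f}{\eta}\nabla p + (\mathbf v_f - \mathbf v_s) = \mathbf 0,$$
  which degenerates gracefully to $\mathbf v_f = \mathbf v_s$ at zero
  porosity — the no-slip picture of a fluid with no pore space left to move
  through. The two mobilities $\phi_f/\eta$ and $\phi_f\rho^*_f/\eta$ are
  evaluated in closed algebraic form (`mobilities()`), never as quotients,
  so $\phi_f = 0$ is an ordinary evaluation point.
* **Continuity.** $\nabla\!\cdot(\phi_s\mathbf v_s + \phi_f\mathbf v_f) = 0$,
  the volume balance of the saturated mixture.

The permeability closure is the C$^1$ cubic blend
$$\kappa_s(\phi_f) = \bar\kappa_s\,(4 - 3x)\,x^3,\quad x = \phi_f/\phi_{fc}
  \;(x<1);\qquad \kappa_s = \bar\kappa_s \;(x \ge 1),$$
which satisfies $\kappa_s = o(\phi_f)$, the property the rescaling needs.
The critical porosity $\phi_{fc}$ defaults to $0.1$ in all studies.

# Discretization

All equations are pulled back to the solid reference configuration (an ALE
scheme whose computational domain coincides with the initial configuration).
Meshes are structured triangulations of axisymmetric rectangles; the
axisymmetric measure $2\pi R\,\mathrm dR\,\mathrm dZ$ and a full
$3\times 3$ deformation gradient with the hoop stretch $1 + u_R/R$ are used
throughout.

The mixed element is MINI/P1/P1: piecewise-linear displacement enriched with
one interior cubic bubble per triangle, piecewise-linear fluid velocity and
pressure. Two asymmetries of the weak form are normative:

* the pressure gradient is **not** integrated by parts in either momentum
  equation, while the continuity equation **is** — this keeps gradients of
  volume fractions out of the formulation entirely;
* Neumann boundary terms therefore carry the *elastic* traction
  $\mathbf T^e_s\mathbf n$. Physical loads are prescribed as total
  tractions, so the discrete pressure trace appears in the boundary
  integral. Keeping that trace in the boundary term is a deliberate
  numerical choice: with a purely elastic datum the exactly incompressible
  limit exhibits a weakly controlled pressure/dilation boundary mode and
  the discrete solutions stop converging; with the total-traction form both
  verification cases converge at the expected rates.

The degrees of freedom include the bubbles explicitly (no static
condensation), plus an optional scalar multiplier that pins the mean
pressure whenever no pressure Dirichlet datum and no total-traction
boundary is present (the manufactured-solution study and the traveling-wave
problem).

**Nonlinear solve.** A monolithic damped Newton iteration; the Jacobian is
assembled from central finite differences of the vectorized element
residual with respect to element-local degrees of freedom (relative step
$6\times10^{-6}$ of a per-field typical magnitude), which is exact to about
$10^{-7}$ and verified against directional finite differences of the global
residual. The mixed-units system is column-scaled by the per-field typical
magnitudes and row-equilibrated before the sparse LU factorization; the
factorization is reused across iterations and time steps while the residual
contracts by at least a factor five per step. Backtracking line search is
the default; the traveling-wave solver follows the constant-damping-factor
policy with Jacobian reuse.

**Time integration.** Constant-step BDF2 with a BDF1 startup step. The
solid velocity and acceleration are the BDF derivatives of the displacement
history; the fluid acceleration is evaluated in ALE form, referential rate
plus convection by $\mathbf v_f - \mathbf v_s$. If a step fails to converge
(typically when a porosity depletion front crosses quadrature points), the
driver automatically redoes it as 2–8 first-order substeps and then resumes
the nominal grid with a first-order restart; this keeps the long squeezing
runs stable through the load-release rebounds.

**Degenerate-porosity handling.** Inside the assembly the porosity
$\phi_f = 1 - \phi_{Rs}/J_s$ is passed through a smooth positive part
($\varepsilon = 10^{-4}$ half-width), so Newton iterates that transiently
over-compact remain differentiable; the raw minimum porosity is recorded at
every solve. An optional over-compaction barrier (a smooth penalty pressure
added as a stress, active only where the raw porosity would be negative) is
available for the traveling-wave solver; it is off by default.

# Verification (manufactured solutions)

The verification harness prescribes analytic fields on the axisymmetric
rectangle $R \le 5\,$mm, $Z \le 10\,$mm ($L = 10\,$mm):
$$p = p_o \sin(\pi t/2t_o)(r/L)^3(z/L)^3,\quad
  u_{sR} = u_o[1-\cos(\pi t/2t_o)](R/L)^3,\quad
  u_{sZ} = u_o[1-\cos(\pi t/2t_o)](Z/L)^3,$$
with $p_o = 100\,$Pa, $u_o = 0.1\,$mm, $t_o = 1\,$s. Two cases hold the
porosity frozen at a constant: $\phi_f = 0.5$, where the manufactured fluid
velocity is $\mathbf v_f = \mathbf v_s + \phi_f \mathbf w$ with the smooth
perturbation $\mathbf w = (\bar\kappa_s p_o/\mu_f L)\sin(\pi t/2t_o)\,
((r/L)^2, (z/L)^2)$ — its amplitude is the Darcy velocity scale of the
problem — and $\phi_f = 0$, where $\mathbf v_f = \mathbf v_s$ identically.
The body forces $\mathbf b_s$, $\mathbf b_f$ and the continuity source $q$
that make these fields an exact solution are derived symbolically (base R
expression calculus; the separable map makes every operator closed-form)
and are verified in the test suite against independent finite-difference
evaluations of the strong equations. $q$ exists only for verification; all
physical runs use $q = 0$.

Boundary conditions follow the study design: displacement Dirichlet
everywhere except the top edge, which carries the manufactured total
traction; the manufactured normal filtration flux on the outer boundaries;
$u_R = 0$ on the axis. The pressure has no Dirichlet datum, so its level is
pinned by a mean constraint whose target is the manufactured mean.

The refinement ladder starts at $h_e = 2.5\,$mm and halves five times;
time stepping is BDF2 with $\Delta t = 5\times10^{-4}\,$s to
$T = 5\times10^{-2}\,$s. Errors are relative norms on the reference domain
(L$^2$ for all fields, H$^1$-seminorm for $p$ and $\mathbf u_s$,
H(div)-seminorm for $\mathbf v_f$), evaluated at the final time; rates are
least-squares slopes in log–log, reported both over all levels and over the
finest three (the two-radial-cell coarsest meshes are pre-asymptotic, so
the tail fit is the quoted rate). Observed tail rates: displacement and
fluid velocity L$^2$ about 1.9–2.4 and H$^1$ about 1.0 in both cases;
pressure 2.0 (L$^2$) and 1.0 (H$^1$) at $\phi_f = 0.5$. In the exactly
incompressible $\phi_f = 0$ case the pressure converges at about 1.5
(L$^2$) and 0.6 (H$^1$): this is the expected MINI behavior — the element's
pressure estimate is first order in the incompressible limit, partially
superconvergent on uniform meshes — not an implementation defect; the
displacement and fluid-velocity rates are unaffected, and the discrete
$\|\mathbf v_f - \mathbf v_s\|$ tracks the displacement error with a
constant well below 10.

# The squeezed-cylinder benchmark

A saturated cylinder (radius $0.5\,$mm, height $10\,$mm, uniform
$\phi_{Rf} = 0.5$ — the initial porosity is a configuration default, chosen
as the homogeneous mid-range value) is squeezed by a radial traction
confined to the band $2\,\mathrm{mm} < Z < 3\,\mathrm{mm}$ of the lateral
surface: $\mathbf p_g = -p_o\,\mathrm{rect}((Z-Z_0)/(Z_1-Z_0))
(1 - \cos 2\pi t/t_o)\,\mathbf e_r$ with $p_o = 100\,$Pa, $t_o = 0.4\,$s,
where $\mathrm{rect}$ is the C$^2$ quintic plateau window. The bottom is
fixed, $p = 0$ on top and bottom, the lateral surface is impermeable, and
the load is interpreted as a referential traction (the Nanson-scaled form).

Under full load the porosity at the monitor point $(0, 2.5\,\mathrm{mm})$
collapses to exactly zero within a quarter load cycle and the filtration
velocity vanishes in the depleted region, while the `"traditional"`
formulation selector (the unscaled fluid momentum equation, coefficients
evaluated verbatim) fails at that same stage — its drag coefficient blows
up as $\phi_f^{-1}$. At reduced load ($p_o = 10\,$Pa, porosity well above
$\phi_{fc}$) the two formulations agree at the $10^{-4}$–$10^{-3}$ level:
they share the continuous root set, but as discrete Petrov–Galerkin systems
they weight the pointwise residual by different positive factors
($1$ versus $\eta(\phi_f(x))$), so their discrete solutions differ by a
discretization-level amount wherever $\eta$ varies in space. Exact
agreement should not be expected at finite resolution.

Converged depleted states carry raw porosities down to about $-0.05$ at
quadrature points at the depletion front (mesh $0.1\,$mm, $\Delta t =
10^{-3}\,$s): the clamped constitutive evaluation cannot represent the
pressure spike that enforces $\phi_f \ge 0$ exactly, so a few percent of
over-compaction remains at practical resolution. The flag is recorded with
every solve; the package treats this as a known, resolution-dependent
limitation. The sealed variant (all boundaries impermeable) conserves the
current-configuration fluid volume to a few parts in $10^6$.

The desk-scale defaults used by the test suite run this benchmark to
$T = 0.4\,$s (one full load cycle, the same load phase as the printed final
time of $2\,$s) at the benchmark mesh and step; the longer horizon only
repeats the cycle with the depleted region persisting.

# Peristaltic perivascular flow

The annular perivascular space (inner radius $h = 10\,\mu$m, outer radius
$R_o = 11\,\mu$m, referential porosity $0.2$) is driven by a wall wave
$r_i = h + b\sin(2\pi(z - ct)/\lambda)$ with amplitude $b = 0.25\,\mu$m.
The frequency $f = 5\,$Hz is the invariant of wavelength sweeps, so
$c = \lambda f$. In the frame moving with the wave the problem is steady
and $\lambda$-periodic; the package solves it on the right hollow cylinder
$[h, R_o]\times[0,\lambda)$ (periodicity by shared degrees of freedom) with
the ALE map carried by the periodic displacement. The solid velocity
$\hat{\mathbf v}'_s$ is a primary P1 unknown tied to the map by
$\hat{\mathbf v}'_s + c\,\mathbf F_\lambda\mathbf e_{\hat z} = \mathbf 0$
(it carries the convective inertia); inside the drag and continuity terms
the exact substitution $-c\,\mathbf F_\lambda\mathbf e_{\hat z}$ is used,
which makes the wall-tangency of the solid velocity exact and removes all
lateral boundary terms from the continuity equation. The pressure splits as
$p' = \bar p' + (\Delta p/\lambda)z'$ with $\Delta p = 0$ by default (pure
peristaltic pumping; the axial pressure difference is exposed in the
configuration) and the periodic part is pinned by a zero-mean constraint.

Reported quantities: the volume flow rate
$\bar Q = \lambda^{-1}\int \phi_f(\mathbf v_f - \mathbf v_s)_z J\,
\mathrm d\Omega$ (frame-invariant filtration flux, in $\mu$m$^3$/s), the
peak pressure $\max|p'|$ in mmHg (1 mmHg = 133.322 Pa), and the average
axial gradient, operationalized as the peak-to-peak pressure along the
inner wall divided by $\lambda$ — the domain-max and inner-wall-max
conventions differ by well under a percent in the smooth regime because
the pressure is nearly uniform radially at lubrication aspect ratios.

The solve proceeds by amplitude continuation from the analytic
zero-amplitude state (a rigid drift at $-c\,\mathbf e_z$), with a linear
radial ramp of the wall displacement as the increment predictor and
bisection of the increment on failure. Because the solution family is
linear in $c$ at fixed relative geometry, wavelength sweeps rescale the
fields exactly; the solver nevertheless computes every row independently.

**Behavior at the study amplitude.** The Table-style amplitude
$b = 0.25\,\mu$m is one quarter of the gap, while the fluid available per
unit length is only $\phi_{Rf}\times$ gap $= 0.2\,\mu$m: complete local
depletion is geometrically forced before full amplitude. In this
discretization the steady traveling-wave branch terminates at about 83 % of
the study amplitude, exactly where the minimum porosity reaches zero; the
mesh-converged values just below termination (80 % amplitude, verified
stable to better than 2 % under both radial and axial refinement) are
$\bar Q \approx 8.9\times10^3\,\mu$m$^3$/s, peak $|p'| \approx 3.7$ mmHg and
average gradient $\approx 4.9\times10^4$ mmHg/m at $\lambda = 150\,\mu$m.
Beyond the termination the only states the solver can reach are
occlusion-dominated, with a regularization-dependent pressure spike across
the depleted plug; the transient path (an independent traveling-wall
initial-value computation that corroborates the moving-frame solver to
0.3 % in the smooth regime) fails at the same amplitude. The package
therefore returns the largest-amplitude converged state with an explicit
`depletion_limited` flag rather than a spike state. The qualitative
finding — a zero-porosity region appears under the literature parameters,
at any shear modulus — is robust; the quantitative summary numbers at full
nominal amplitude are not attainable as a smooth steady state here, and the
reported values carry the achieved amplitude alongside them.

For the heterogeneous-porosity studies the referential porosity follows the
radial cosine blend from $0.8$ at the wall to $0.2$ beyond
$\bar R = 12\,\mu$m, and the radial grid can be geometrically graded toward
the inner wall so the fluid-rich lumen stays resolved when the outer radius
grows to $200\,\mu$m.

# Problem sizes used by the packaged studies

The test suite and the acceptance script run at desk scale, chosen once as
the package's defaults: the verification ladder uses five levels (the
finest, $h_e = 0.15625\,$mm, has $32\times64$ cells) with the printed time
step; the squeeze benchmark runs its printed mesh ($0.1\,$mm) and step
($10^{-3}\,$s) over one load cycle; traveling-wave cases use 25–50 radial
cells and 16–96 axial cells per wavelength, with a grid-convergence check
(flow-rate drift under axial doubling at 80 % amplitude measured below 1 %,
well inside the 2 % gate required before reporting). Larger meshes and the
full printed horizons are reachable through the configuration objects; no
algorithmic parameter changes with problem size.

# Known limitations

* Pressure convergence in the exactly incompressible limit is first order
  (element property, see above).
* Depleted regions over-compact by a few percent in raw porosity at
  practical resolution; the incompressibility of a fully depleted solid is
  enforced only weakly.
* The steady traveling-wave branch terminates at the zero-porosity onset;
  post-occlusion steady states are not resolvable without regularization
  that dominates their pressure field.
* Quadrilateral cells are realized by consistent splitting into triangles
  (the MINI bubble is triangle-native); reported "rectangular" resolutions
  refer to the cell grid before splitting.
* No contact handling if the wall wave were to close the annulus, and no
  3D, non-axisymmetric modes.
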