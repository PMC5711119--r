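---
title: "Calibrating 2D detector arrays by beam-profile reconstruction with error-locking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating 2D detector arrays by beam-profile reconstruction with error-locking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamcal)
```

## The problem

A planar array of radiation detectors (a diode array used for
radiotherapy patient-specific QA, or an electronic portal imager) does
not respond uniformly: each detector has its own multiplicative
sensitivity to unit fluence.  Before the array can measure dose
distributions, these per-detector sensitivities must be calibrated.  A
wide open field can irradiate all detectors at once, but its fluence is
not flat — flattened linac beams are "bowl-shaped", rising a few percent
toward the field edges — so the raw reading of detector $d$ at position
$(x, y)$ confounds beam and detector:

$$ MC(X,Y) = R(X,Y)\, S(X,Y), $$

where $R$ is the relative beam profile, $S$ the sensitivity, and $(X,Y)$
integer grid coordinates centred on the beam axis (CAX).  Calibration
requires separating $R$ from $S$ without knowing either.

## Iterative reconstruction from shifted measurements

If the array is re-irradiated after shifting it one grid step to the
left, detector $X$ now sits under beam position $X-1$:

$$ M_{LAT-1}(X,Y) = R(X-1,Y)\, S(X,Y). $$

In the ratio $M_{LAT-1}/MC$ the sensitivity cancels, leaving the ratio
of neighbouring beam-profile values.  Chaining these ratios outward from
the centre reconstructs the whole normalized lateral profile of each row
without any knowledge of the sensitivities:

$$
R_{XNOR}(X,Y) = \prod_{i=1}^{-X} \frac{M_{LAT-1}(X+i,Y)}{MC(X+i,Y)}
\quad (X<0), \qquad
R_{XNOR}(X,Y) = \prod_{i=1}^{X} \frac{MC(i,Y)}{M_{LAT-1}(i,Y)}
\quad (X>0).
$$

A third irradiation, shifted one step longitudinally, gives the central
longitudinal profile $R_{YNOR}(0,Y)$ the same way, and the 2D profile is
composed by reweighing each lateral row:

$$ R_{NOR}(X,Y) = R_{XNOR}(X,Y) \times R_{YNOR}(0,Y). $$

Dividing the normalized unshifted measurement by the (interpolated)
profile yields the sensitivities,
$s(x,y) = mc_{nor}(x,y) / r_{nor}(x,y)$.  Three wide-field irradiations
therefore suffice — no array rotation is needed, which makes the scheme
applicable to inline imagers that cannot rotate.

Numerically, the products are computed as exponentials of cumulative
sums of log ratios, extending outward from index 0.  This treats the two
directions symmetrically and is robust over the up-to-16-factor chains
of the default layout.  A masked (absent) detector truncates its chain
beyond the gap: every intermediate reading is required, so gaps are
never jumped.  A zero or negative reading inside a chain is an error
naming the offending index, because the ratio chain is undefined there.

## Propagation errors and the two-component model

Chained ratios amplify small systematic differences between the shifted
and unshifted irradiations.  Two physical causes are modelled as
constant per-step multiplicative factors:

* **E1, output variation** — the machine delivered slightly more or
  less during the shifted measurement.  This tilts the reconstruction:
  one side rises, the other falls.
* **E2, positioning error** — the array was not shifted by exactly one
  step.  On a bowl-shaped beam this lowers (or raises) both sides
  alike, flattening or sharpening the reconstruction.

The distorted profile follows

$$ R'_{XNOR}(X) = R_{XNOR}(X)\,(1+E_1-E_2)^{-X} \ (X<0), \qquad
   R'_{XNOR}(X) = R_{XNOR}(X)\,/\,(1+E_1+E_2)^{X} \ (X>0). $$

The sign structure is fixed by the directional behaviour of the two
components — a positive $E_1$ must raise the $X<0$ side and lower the
$X>0$ side, a positive $E_2$ must lower both — which makes the form
above the unique consistent choice; `apply_propagation_error()`
implements it.  The error compounds geometrically: a per-step error $e$
accumulates to $(1+e)^n$ after $n$ steps (`propagation_factor()`); e.g.
a 1 mm positioning offset on a bowl that reads 1.08 at 15 cm off-axis
causes a local error of $0.08/150$ per step and
$(1+0.08/150)^{16} = 1.0086$ — a 0.86% edge error — after 16 steps.

## Error-locking with narrow-field triads

The errors are estimated from three extra irradiations per axis with a
narrow strip field (e.g. $4\times37$ cm$^2$).  The field stays on the
CAX while the array is shifted so that, in turn, the detectors at grid
positions $A < 0$, $B = 0$ and $C > 0$ sit on the field centre.  Each of
those detectors then receives *identical* fluence, so single reading
ratios give the relative sensitivities $S(A,Y)/S(0,Y)$ and
$S(C,Y)/S(0,Y)$ exactly (`triad_relative_sensitivities()`).  Correcting
the wide-field readings by them yields propagation-error-free "anchor"
values of the true profile at $A$ and $C$ (`anchor_points()`), and the
two-sided model is solved in closed form (`solve_errors()`):

$$ u = \left(\frac{R'_{XNOR}(A)}{R_{XNOR}(A)}\right)^{1/(-A)} - 1 = E_1 - E_2,
\qquad
v = \left(\frac{R_{XNOR}(C)}{R'_{XNOR}(C)}\right)^{1/C} - 1 = E_1 + E_2, $$

so $E_1 = (u+v)/2$ and $E_2 = (v-u)/2$.  The lateral solve is done per
grid row and the estimates averaged with equal weight over all rows
whose chains reach both anchors; the longitudinal solve is done per grid
column the same way (the pipeline itself only consumes the corrected
central longitudinal profile).  Per-row values are retained in the
estimate diagnostics, since their spread is a useful health indicator.
`correct_profile()` / `correct_reconstruction()` invert the model
exactly.  With the triads, a locked calibration needs 9 irradiations.

A known bias mode, surfaced in the tests rather than hidden: output
drift *between triad exposures* scales the corresponding relative
sensitivity by the same factor.  The triads should therefore be
delivered in quick succession.

## The noniterative reference

For validation the package also implements a scan-based method: one wide
field plus a narrow field scanned across the array (25 lateral + 33
longitudinal positions at 1 cm, 59 irradiations in all).  Each scan
position's sensitivity follows from its own pair of readings, so local
errors stay local — nothing propagates.  On noiseless simulated sessions
the iterative and scan reconstructions agree to better than $10^{-10}$;
under injected errors the scan method is the accuracy floor the
iterative methods are judged against.

## The simulator: what it emulates and what it does not

Every stage above is testable against ground truth because the package
simulates complete sessions:

* **Beam**: radially symmetric even-polynomial bowl
  $R = 1 + a_2 r^2$ with $a_2 = 0.08/225$ cm$^{-2}$, i.e. exactly 1.08
  at 15 cm — the minimal shape consistent with a flattened 6 MV beam;
  quartic and linear-tilt terms and an FFF-like central peak are
  available.  Field edges fall off through an error-function penumbra of
  0.5 cm 80–20 width; wide calibration fields are larger than the array
  precisely so this region is never sampled, and the simulator warns if
  it is.
* **Detectors**: i.i.d. sensitivities $\sim N(1, 0.02)$ truncated at
  $\pm5\sigma$; masked positions are carried as `NA` throughout (never
  zero, which would corrupt ratio products).
* **Perturbations**: per-measurement multiplicative output scale,
  continuous positioning offsets in cm (so a 5 mm error on a 1 cm grid
  is representable), and multiplicative Gaussian reading noise
  (relative SD, truncated at $\pm5\sigma$) — diode repeatability is
  relative, which is why everything is expressed in percent.
* **Reproducibility**: all randomness derives from one session seed via
  named substreams, so any single measurement can be regenerated alone.
* **Monitor units** (default 200) are a pure scale and cancel in every
  ratio.

Deliberately *not* emulated: energy-spectrum-dependent detector
response, backscatter from imager support arms, beam-symmetry drift
within a session, and gradient-dependent (non-constant) positioning
error.  Passing tests therefore demonstrate the algebra and the error
model, not detector physics.

The staggered default layout mirrors a MapCHECK2-class device: 1 cm
lateral spacing, 0.5 cm row interval and stagger, 26 cm × 32 cm active
area with empty 7×7 cm corner triangles — 1527 detectors, about half of
which lie on the 1 cm reconstruction grid (x ∈ −13…13, y ∈ −16…16); the
rest are obtained by bilinear interpolation.  Bilinear (not bicubic) is
the default because it is monotone and cannot overshoot on bowl
profiles; detectors outside the grid hull or adjacent to undefined
corner nodes are excluded and reported, never extrapolated.

## Choices made where the design was open

* **Axis orientation**: +x lateral, +y toward the gantry, CAX-centred
  cm at 100 cm source-to-detector distance.  "Shifted left by one step"
  makes detector $X$ sample beam position $X-1$.
* **Array orientation**: the longitudinal extent is taken as 32 cm and
  the lateral as 26 cm, because the default longitudinal scan range
  (±16 cm), longitudinal anchors (±14 cm) and 16-step longitudinal
  chains only fit that way.
* **Anchors** default to ±11 steps laterally and ±14 longitudinally,
  configurable per session.
* **Normalization detector** is the geometry origin; if it is masked,
  calibration aborts rather than silently renormalizing elsewhere.
* **Greer irradiation counting** is inclusive of both scan endpoints
  and the centre (1 + 25 + 33 = 59 at 1 cm step).
* **Estimates are stored as fractions** and reported additionally in
  percent, to keep unit bugs out of the arithmetic.

## Known limitations

The single-factor E2 model is an average over a gradient-dependent
truth.  For any smooth bowl the chain distortion from a real positioning
offset $\delta$ is approximately $\exp(-\delta \cdot \ln R_{NOR}(Y))$ —
quadratic in $|Y|$ for the default bowl — while the lock can only remove
a geometric, linear-in-$|Y|$ component anchored at $\pm14$.  The
correction is therefore exact at the anchors and at the centre but
leaves a curvature residual in between and beyond, visible in the
robustness study (`run_robustness_study()`): with a 5 mm longitudinal
positioning error and 0.1% noise the lock reduces the mean deviation
from truth by roughly 2–3× and the worst-case edge deviation by more
than 5×, and its E2 estimate clearly flags the mispositioning while E1
stays near zero.  A lock that removed the error entirely would need
either gradient-weighted per-position factors or anchors at more than
two positions — both outside the present model, whose simplicity is the
point.  Relatedly, a full-span ratio product (the statistic a
rotation-based scheme relies on) is blind to pure positioning error,
which is the motivation for the triad lock.

Problem sizes used throughout the test suite and the study: the full
staggered layout (1527 detectors) for end-to-end and robustness checks,
and 9×9 regular grids for unit-level algebra, which keeps the complete
suite under a minute on one CPU.
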