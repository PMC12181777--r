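---
title: "Simulated dual-function liquid handling and bead imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated dual-function liquid handling and bead imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadscreen)
```

## What the package models

An open liquid-handling robot can be turned into an in-situ imaging
platform by exploiting its own tip mechanics: a 3D-printed adapter holds a
truncated pipette tip and a downward-facing USB camera, so the pipetting
gantry can friction-fit the whole assembly exactly as it picks up a tip,
and release it with the ordinary tip ejector. One pipette keeps doing
liquid handling while the other carries the camera, which lets the same
machine prepare ionically crosslinked hydrogel beads (alginate + CaCl~2~)
in microplate wells and photograph them in place as they gel or fall
apart.

`beadscreen` is a complete software simulation of that platform, built so
the full loop — protocol, capture service, image formation, image analysis
— is testable on a desk with no hardware. It has five parts:

1. **Virtual deck** (`deckLayout`, `loadLabwareDefinition`,
   `wellPosition`, `conditionCapacity`): an 11-slot deck with labware
   geometry read from Opentrons-style JSON definitions.
2. **Protocol engine** (`planHydrogelScreen`, `simulateProtocol`,
   `scheduleImaging`, `volumeLedger`): plans and executes the two-pipette
   screening protocol against pipette state machines.
3. **Camera link** (`captureMessage`, `cameraServe`): a
   capture-on-message service speaking newline-delimited JSON.
4. **Synthetic imaging** (`opacityFromConcentrations`,
   `opacityTimeCourse`, `renderFrame`, `simulateScreen`,
   `simulateTimelapse`): the forward model producing ground-truth frames.
5. **Bead analysis** (`segmentBead`, `measureIntensity`,
   `summarizeScreen`, `analyzeTimelapse`, `fitDisintegration`): the
   inverse analysis recovering bead intensity and kinetics from frames.

## The gelation opacity model

Against a black well background a bead reads out as a bright disk whose
8-bit pixel intensity encodes opacity. Opacity depends on the balance of
crosslinker and polymer, summarized by the ratio

$$R = \frac{[\mathrm{CaCl_2}]}{[\mathrm{alginate}]} \quad (\%\,w/v\ \text{over}\ \%\,w/v).$$

Too little calcium leaves the network too sparse to scatter light; past a
critical ratio the gel becomes weaker and more transparent again. We model
this as an asymmetric log-normal bump,

$$\omega(R) = \omega_{\max} \exp\!\left(-\frac{\log^2(R/R_c)}{2 s^2}\right),
\qquad s = \begin{cases} s_\mathrm{rise} & R < R_c \\ s_\mathrm{fall} & R \ge R_c,\end{cases}$$

which is continuous, strictly increasing below $R_c$ and strictly
decreasing above it, with its maximum exactly at $R_c$. Defaults:
$R_c = 1$ (so at 1.5 % alginate the peak sits at 1.5 % CaCl~2~, matching
the observed turnover between 1.5 % and 5 %), $s_\mathrm{rise} = 0.8$,
$s_\mathrm{fall} = 1.0$, $\omega_{\max} = 0.9$, and a *visibility floor*
of 0.15 below which a bead is considered hard to see without contrast
enhancement. The functional form is a package choice — the underlying
observations are qualitative orderings, and any continuous unimodal bump
satisfying them would do; this one is convenient because the peak location
and the two tail widths are independent knobs.

One consequence worth knowing: because the model depends on concentrations
only through $R$, a single critical ratio cannot make *every* alginate row
of the 4 × 6 screen turn over between the same two CaCl~2~ columns — rows
differ in where their $R$ values fall. Each row still has a strictly
interior intensity maximum, which is the property the analysis pipeline is
tested against.

## The disintegration time course

For the time-lapse experiment (1.5 % alginate, 1.0 % calcium, EDTA added
at $t_E$), opacity follows

$$\omega(t) = \begin{cases}
  b + (P - b)\,(1 - e^{-k_\mathrm{rise} t}) & t < t_E \\
  b + (\omega(t_E) - b)\, e^{-k_\mathrm{decay}(t - t_E)} & t \ge t_E,
\end{cases}$$

a saturating maturation from baseline $b$ toward plateau $P$, then — once
EDTA chelates the calcium out of the network — an exponential relaxation
back toward baseline, continuous at $t_E$. Defaults: $b = 0.1$,
$P = 0.85$, $k_\mathrm{rise} = k_\mathrm{decay} = 0.01\,\mathrm{s}^{-1}$,
i.e. maturation and decay on the few-minute scale that makes rapid
in-situ imaging necessary in the first place. The closed-form half-life
identity $\omega(t_E + \ln 2 / k_\mathrm{decay}) = b + (\omega(t_E)-b)/2$
is used as an oracle in the tests.

## Image formation

`renderFrame` draws the bead as a disk of radius $r$ (pixel-centre
convention) at continuous level
$\mathrm{bg} + \omega\,(255 - \mathrm{bg})$ on background $\mathrm{bg}$
(default 6), then applies, in order: a normalized disk-kernel blur
(radius 1 px by default, softening the bead edge), additive zero-mean
Gaussian luminance noise (one field shared by all three channels), and a
single clip-and-quantize to 8 bits. Quantizing once at the end means a
noise-free render has disk level exactly
$\mathrm{round}(\mathrm{bg} + \omega(255-\mathrm{bg}))$ while noisy disk
means stay centred on the continuous level — both properties are asserted
in the tests. Rendering restores the caller's RNG state and is
bit-identical for equal seeds; grid and time-lapse generators derive
per-frame seeds deterministically from one run seed.

What the generator deliberately does **not** emulate: multiple beads per
well, well walls and meniscus shading, non-uniform illumination, bead size
or position changes during disintegration, and any real optics beyond
disk + blur + noise. Passing tests therefore demonstrate that the
analysis pipeline is correct *given* this image model, not that it is
robust to every artefact of real well images.

## The inverse analysis

Segmentation (`segmentBead`) follows the classic enhancement +
thresholding recipe:

1. grayscale by Rec. 601 luma (0.299 R + 0.587 G + 0.114 B, rounded);
2. histogram equalization, by the cumulative-histogram map
   $v \mapsto \mathrm{round}\!\big(255\,\tfrac{F(v)-F_{\min}}{1-F_{\min}}\big)$
   (constant images pass through unchanged). In `auto` mode equalization
   triggers only when the dynamic range $p_{99} - p_{1}$ falls below 40
   levels — transparent beads need it, opaque beads do not;
3. Otsu threshold on the working image (a fixed threshold is available
   for oracle tests);
4. morphological open then close with a radius-2 disk brush;
5. 4-connected component labelling, dropping components under 500 px;
6. a **detection-significance guard**: a component counts as a bead only
   if its mean on the working image exceeds the background mean by at
   least 30 levels. This is what makes the equalization genuinely
   necessary for faint beads — a plain Otsu split will happily bisect even
   a near-invisible two-mode histogram, so without the guard nothing
   would ever be "difficult to visualize";
7. selection of the surviving component nearest the image centre (one
   bead per well by design).

Intensity statistics (`measureIntensity`) are always computed on the
**raw, non-equalized** grayscale restricted to the mask: only
pre-equalization values carry the opacity interpretation on the 0–255
scale. The reported spread (sd plus the 5/25/50/75/95 % quantiles) is the
operationalization of "error bars represent the pixel distribution".

Kinetics fitting (`fitDisintegration`) detects the disintegration onset
by an exhaustive two-segment scan — the series are short, so trying every
observed time point as the change point is cheap and deterministic. Each
candidate splits the series into a saturating-rise fit (falling back to a
line when the nonlinear fit will not converge) and an exponential-decay
fit $b + A e^{-k(t - t_0)}$ via Levenberg–Marquardt least squares. The
best split is accepted only if (a) its total residual sum of squares is
below half that of the best single-segment fit and (b) the fitted drop
amplitude $A$ exceeds 10 intensity levels; otherwise the series is
reported as having no onset. The amplitude condition matters for
rise-only series, where both models fit nearly perfectly and the RSS
ratio alone is numerically unstable.

## The protocol engine

The planner reproduces the demo protocol structure: right (1000 µL)
pipette takes a tip and distributes CaCl~2~ from the vial rack into the
target wells; tip is dropped; the left pipette takes a 300 µL tip; the
right pipette friction-fits the camera tool; the left pipette aspirates
one alginate droplet per well with air gaps in between; each droplet is
delivered by two-sub-step coalescence dispensing (partial dispense to just
before droplet detachment, then a touch-and-coalesce transfer) followed
immediately by an image capture over that well; finally tool and tip are
returned. Modelling choices:

* *Every* dispense is the two-sub-step pair, CaCl~2~ included — the step
  vocabulary has one dispensing idiom and the degenerate case costs
  nothing. Coalescence physics is reduced to a bookkeeping transfer of
  the pending droplet volume.
* Droplets are aspirated in reverse well order, because the tip is a LIFO
  stack: the last-aspirated segment is the first dispensed.
* The left pipette is the 300 µL class by default, matching the 300 µL
  tip rack on slot 9 (the protocol description also mentions a 20 µL
  pipette once; the volume class is a config parameter, so either is
  available).
* Collision safety is one rule: every occupied labware except the target
  plate and the tool holder must sit below the camera's working height
  (100 mm default), else planning fails.
* Nominal durations: 5 s per capture (the one measured figure), 2 s for
  moves/aspirates/dispenses, 10 s for tool changes; all configurable. A
  full-plate nine-interval scan involves overheads this model does not
  claim to reproduce.

`simulateProtocol` executes the plan against per-mount state machines
(tip/tool exclusivity, capacity limits, segment stack), halting at the
first violation with an `error` event. `volumeLedger` checks per-solution
conservation: aspirated = dispensed + residual. `scheduleImaging`
serializes the single camera: requests collide at each interval and later
wells shift by multiples of the per-well time; realized times are never
earlier than requested, and intervals spaced closer than
`wells × perWellTime` are reported as infeasible (the shifted schedule is
still returned). Imaging intervals are anchored per well (relative to
that well's dispense); this is a convention choice, and the scheduler is
agnostic to the anchor since it only sees requested times.

## The camera service

The capture service is a function of a message stream, not of a network:
`cameraServe` consumes newline-delimited JSON lines (from a character
vector, file, or connection), and for each well-formed message captures
one frame from its source, writes a lossless PNG named
`<run_id>_<slot>_<well>_<sequence>.png`, appends a CSV index row, and
replies with an acknowledgement carrying the filename. Malformed messages
and per-run sequence regressions get error replies and produce no files.
A thin TCP wrapper (`cameraServeSocket`) exists for shell use; the
live-feed display window of the physical setup is replaced by an optional
`latest.png`, since a GUI cannot be tested headlessly.

## Problem sizes and numerical choices

* Simulation studies (segmentation quality over 100 noisy beads,
  kinetics recovery over 50 time-lapse replicates, the analyzed 4 × 6
  screen) run at 320 × 240 px with radius-40 beads — the bead fills about
  a third of the frame width, as in the well images the model emulates,
  and the studies stay fast. The capture path keeps the full 640 × 480
  default.
* The kinetics study uses 20 frames at 50 s spacing with EDTA at 300 s,
  noise σ = 3; recovery there is typically exact in onset and ~2 %
  median relative error in $k_\mathrm{decay}$.
* Quantile type is R's default (type 7); Otsu runs on 256 levels;
  `round` is R's round-half-to-even throughout.
* The vial rack's 54 positions are arranged 6 × 9 — its capacity is
  known, the arrangement is an assumption recorded here.
* Degenerate inputs are results, not errors, wherever absence is
  informative: a blank frame segments to `found = FALSE`; an EDTA-free
  series fits to `onsetFound = FALSE`.

## Worked example

```{r example, eval = FALSE}
# plan and simulate the demo screen
plan <- planHydrogelScreen()
log <- simulateProtocol(plan)
volumeLedger(log)

# forward model + inverse analysis of a disintegration run
d <- disintegrationParams(tEdta = 300, kDecay = 0.01)
tl <- simulateTimelapse(d, seq(0, 950, by = 50),
                        cameraModel(320, 240, seed = 11),
                        wellScene(radius = 40))
analyzeTimelapse(tl)$fit
```

## Known limitations

The simulation's fidelity boundary is explicit: no physico-chemical
crosslinking model (the opacity bump is phenomenological), no gelation
front or diffusion, no real camera driver, no continuous-space motion
planning, and no multi-bead tracking. The package is a test bed for the
orchestration logic and the analysis pipeline, and a generator of
ground-truthed benchmark images for bead segmentation — it is not a
predictive model of alginate chemistry.
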