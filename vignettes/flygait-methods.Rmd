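---
title: "flygait: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flygait: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flygait)
```

## The signal model

In an fTIR walking arena, light is injected into the edges of an
optical glass plate and trapped by total internal reflection — for a
borosilicate/air interface the critical angle is
`critical_angle(1.471, 1.000)` ≈ 43°.  Wherever a tarsus contacts the
glass the reflection is frustrated and light scatters toward a
high-speed camera below the plate.  The image of a walking fly
therefore contains:

* one bright, compact spot per leg in stance phase, **stationary in
  the world frame** for the duration of the stance;
* a dim glow over the body (stray light), much weaker than the spots;
* static artifacts (dust, scratches) present before the fly enters;
* sensor noise.

Every stage of flygait is built around these four components, and the
synthetic renderer (`render_ftir_frames()`) generates exactly them:
Gaussian spots of amplitude 0.5 (full scale = 1), a uniform body
ellipse of amplitude 0.12 with semi-axes 0.5 × 0.15 body lengths, a
background offset of 0.05, configurable dust spots, and Gaussian noise
with SD 0.025 (5% of the spot amplitude).  The amplitude ordering
`spot > body glow > noise` is enforced as a config invariant because
the tracker relies on it.

## The synthetic world

The generator's defaults describe a typical wild-type fly under the
standard recording conditions: body length 2.5 mm, 250 frames/s
(4 ms temporal resolution), 25 µm/pixel (a ~1.2 cm field of view on a
512-pixel sensor), walking at 20 mm/s with a 100 ms step period and
duty factor 0.5.  Leg touchdown positions (AEPs, in body lengths,
+x anterior / +y left) are fore (0.62, ±0.32), mid (0.25, ±0.52),
hind (−0.18, ±0.36), with neutral PEP longitudinal coordinates 0.17,
−0.20 and −0.63: anterior-lateral forelegs, wide midlegs, posterior
hindlegs, and each leg's AEP anterior to its PEP.  These values were
chosen once as a realistic hexapod geometry in which consecutive
fore→mid→hind touchdowns land within 0.3 body lengths of each other
(follow-the-leader), and are not tuned against any test.

Gait timing is generated in continuous time and only quantized at
render time, so analysis-level tests can consume exact onsets without
quantization bias:

* **tripod** — triplets {LF, LH, RM} and {RF, RH, LM} in exact
  antiphase; contralateral same-segment phase is exactly 0.5 and the
  hind→fore metachronal lag equals the period.
* **tetrapod** — three swing pairs at period/3 offsets; right-handed
  cycle (RH,LM) → (RM,LF) → (RF,LH), mirrored for left-handed.  The
  precise canonical pair sequence is shown only graphically in the
  literature; this 6-code convention is fixed and documented in
  `TETRAPOD_CODES`.  Duty factors below 2/3 are rejected (they would
  force more than two legs to swing at once).
* **wave** — one leg swings at a time, back to front on each side;
  default duty 5/6.
* an optional **metachronal-lag override** builds a per-side wave with
  the requested hind→fore swing-onset lag (midleg at half the lag),
  used by the regression-recovery tests.

Body kinematics: the body advances along +x at constant average speed;
an optional within-cycle speed modulation (cosine, period *P*/2,
peaks at tripod mid-stance) emulates the speed maxima real flies show
halfway through stance.  Each footprint is placed at the body position
at touchdown plus the AEP and then held fixed, so the body-frame trace
sweeps backward to the PEP; combinations of speed, duty and period
whose stance sweep exceeds 1.5× the plan's AEP–PEP workspace are
rejected as kinematically impossible.

Per-step jitter supports the clustering analyses: AEP jitter is 2-D
Gaussian positional jitter at touchdown.  PEP "jitter" is realized as
*liftoff-time* jitter — a stationary footprint cannot be displaced at
liftoff, only released earlier or later — which spreads the PEP along
the travel axis by the requested SD in body lengths.  By construction
this makes PEP clustering exceed AEP clustering whenever the PEP sigma
dominates, which is the direction observed in real flies.

## Tracking

1. **Background**: the pixelwise maximum (default; median available)
   of the pre-entry frames is subtracted (clipped at 0) from every
   frame.  Dust and scratches are static, so the maximum is safe and
   conservative.
2. **Thresholds** are multiples of the raw median absolute deviation
   of the pre-entry noise — 8× for footprint spots, 2× for the body
   glow — rather than absolute intensities, making them robust to
   exposure changes.  The original software's exact "preset
   thresholds" are unpublished; this MAD convention is the documented
   substitute.
3. **Body**: the largest connected component above the body threshold;
   intensity-weighted centroid, moment-based major-axis length
   (4·√λ₁, with a 1/12 finite-pixel correction), displacement axis
   from centroid displacement over a centered 5-frame window after
   light temporal smoothing of the centroid series (per-frame centroid
   noise otherwise dominates the direction estimate).  Nearly
   stationary frames fall back to the ellipse orientation with the
   sign carried over.  If more than half the frames lack a body the
   run aborts ("fly not found").
4. **Footprints**: 8-connected components of the thresholded
   background-subtracted frame, area-filtered (3–400 px), with
   intensity-weighted centroids; components on or next to the body
   mask are excluded so the glow is never called a footprint.
5. **Leg identities**: detections are linked into tracks
   (nearest-neighbor within 5 px, bridging 1-frame dropouts); a
   persisting track keeps its label.  New tracks are labeled by the
   sign of their body-frame lateral coordinate (left = positive) and,
   within the side, by an order-consistency rule against tracks
   detected in the *same frame* (fore anterior to mid anterior to
   hind), breaking ties by proximity to typical touchdown zones
   (x ≈ 0.60 / 0.25 / −0.18 body lengths).  Only same-frame tracks
   claim labels: a leg that just lifted off must not block its
   neighbour's touchdown, whose AEP may be anterior to the
   just-vacated PEP.  Unresolvable conflicts are flagged for the edit
   log rather than guessed.
6. **Edits**: a declarative JSON log (add / remove / relabel records,
   applied in order) replaces interactive editing; an empty log is the
   identity.
7. **Stance events**: per leg, contact runs become half-open intervals
   `[touchdown, liftoff)` — the touchdown frame owns the AEP — with
   dropouts of up to 2 frames bridged and runs shorter than 2 frames
   dropped.  Stances touching the first/last contact of the video are
   flagged as edge-truncated, and every duration-based parameter skips
   them.

### Coordinate conventions

Image coordinates are 0-based, origin top-left, x right, y down.  The
body frame has +x anterior along the displacement axis and +y to the
fly's **left**; because the fTIR camera views the glass from below, a
fly walking toward +x in the image has its left side at +y image, so
the left normal is (−u_y, u_x).  Positions are normalized by the
median tracked body length.

## Parameter definitions and numerical choices

* Period = consecutive touchdown-to-touchdown time; stance = liftoff −
  touchdown; swing = next touchdown − liftoff.  The three satisfy
  period = stance + swing exactly, by construction.
* Step length is the Euclidean world-frame distance between successive
  footprints of the same leg (no projection onto the travel
  direction); swing speed = step length / swing duration, the natural
  estimator since the tarsus travels between consecutive footprints
  during the swing.
* Metachronal lag: for each hindleg swing onset, the first ipsilateral
  foreleg swing onset *strictly* after it; simultaneous onsets are
  skipped, so an ideal tripod yields lag = period.
* Phase = (first onset of the compared leg at/after the reference
  onset − reference onset) / reference period, reduced mod 1.  Phases
  are averaged circularly, never arithmetically; the Rayleigh p uses
  the standard series approximation
  p = exp(−Z)·[1 + (2Z − Z²)/4n − (24Z − 132Z² + 76Z³ − 9Z⁴)/288n²],
  Z = n·r², clipped to (0, 1].
* Average speed is total path length / duration (the alternative — net
  displacement / duration — is indistinguishable for the straight
  walks this pipeline targets); instantaneous speed uses a centered
  window (default 25 ms) with truncated, flagged edges.
* Stance traces run from the touchdown timestamp through the
  **liftoff timestamp**.  Under the half-open convention the last
  contact frame precedes the liftoff instant by one frame; sampling
  the PEP there would displace every PEP posteriorly by a full frame
  of body travel (0.032 body lengths at 250 fps and 20 mm/s — larger
  than the 0.02 BL recovery tolerance the package holds itself to), so
  the PEP is evaluated at the liftoff instant instead.
* Stance linearity: the smoothed trace keeps every 5th sample (first
  and last always included) and is linearly re-interpolated to
  per-frame resolution; the index is the mean distance between
  original and smoothed traces, averaged over all traces of ≥ 6
  frames.  "Every five frames" is interpreted as
  decimate-then-interpolate, not a moving average; the interpretation
  is isolated in `stance_linearity()` so the alternative is a
  one-line change.  Values are reported both in body lengths (primary)
  and µm, as the units in the original figure are unspecified.
* Footprint clustering uses sample (n−1) standard deviations.
* Footprint alignment triplets are matched follow-the-leader style in
  *space*: each fore touchdown to the nearest subsequent ipsilateral
  mid touchdown within 0.3 body lengths, then mid to hind; whether the
  original software matched temporally or spatially is not described,
  and spatial matching is the convention here.  Projections are taken
  on the mean displacement axis; per-triplet value = sample SD of the
  three projections.
* Gait index: per-frame scores (+1 tripod, −1 tetrapod, 0
  noncanonical) averaged over a *trailing* 8-frame window (the
  window alignment is not stated in the original figures; trailing
  keeps the index causal).  The average gait index is the mean of raw
  per-frame scores.  Pentapod frames (exactly one leg swinging, e.g.
  wave gait) score 0 as noncanonical but are tallied separately in the
  summary.  Frames before the first and after the last tracked contact
  are excluded from all indexes.

## What the synthetic tests do and do not establish

The generator produces the idealized signal the tracker is designed
for: exactly periodic gaits, straight constant-heading paths, constant
illumination, stationary Gaussian footprints well separated from the
body glow.  A green test suite therefore establishes that the
implementation is *internally correct* — parameters are recovered at
the stated tolerances from videos that obey the signal model — not
that tracking will survive grooming stops, curved paths, leg-overlap
ambiguities, reflections or illumination drift in real recordings.
Those conditions were excluded from the original study's inclusion
criteria too; the manual edit log is the designed escape hatch.

Because the video quantizes stance membership to frames, the ground
truth carries both the continuous onsets and the as-rendered
(frame-quantized) onsets; recovery tests compare against the latter,
since sub-frame timing is not representable in the data.  Onset
recovery is asserted to ≤ 1 frame, AEP/PEP recovery to ≤ 0.02 body
lengths, speed to 5%, leg labels to 100%.

## Known limitations

Single fly per arena; straight paths only (no curved-walking
v1 support); no joint-level kinematics (not resolvable with fTIR);
no AVI/MP4 decoding (numbered TIFF/PNG frames or multi-page TIFF);
the TIFF codec is a deliberate minimal subset (uncompressed grayscale
strips) and rejects anything else explicitly.
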