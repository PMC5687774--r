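---
title: "Colour quantification for holographic sensors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour quantification for holographic sensors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holoquant)
```

## The measurement problem

A holographic chemical sensor is a hydrogel-embedded diffraction grating
whose replay colour shifts as the gel swells or shrinks with the analyte —
here pH over the operating range 3.00–6.50, running from blue at the acid
end through green to red. Reading that colour with a smartphone camera and
turning it into a number requires solving several coupled problems: the
photograph must travel to the processing side securely and compactly; the
sensor must be found automatically in a cluttered scene; the camera's
device-dependent RGB response must be mapped to device-independent
colorimetry; the sensor pixels must be isolated from highlights, shadows
and background; and the resulting colour descriptor must be calibrated
against known analyte levels. `holoquant` implements this chain end to
end, with a scene/camera simulator that generates fully ground-truthed
synthetic imagery for testing every stage.

## The simulator and what it stands for

The original study rests on a database of 66 photographs (six sensor
batches at eleven pH levels) taken with one characterised handset under a
D65 light booth. Those photographs are not machine-readable, so the
package ships a forward model in their place. `camera_sim_config()`
renders a linear-reflectance scene through

```
out = clip( vignette(x, y) * (Mix %*% reflectance)^(1/gamma) + noise )
```

with per-channel gamma exponents (defaulting to the characterised values
1.987, 1.899, 1.791), a mildly off-diagonal 3×3 sensor mixing matrix,
radial vignetting and i.i.d. Gaussian noise clipped to [0, 1]. Scenes
(`render_scene()`) contain a QR-style fiducial with a central circular
hologram whose hue encodes pH through a piecewise-linear monotone map
(240° at pH 3.00, 100° at pH 5.00, 0° at pH 6.50 — steeper below pH 5 as a
nod to the sigmoidal swelling response), pasted at a random similarity
transform over a background with a shadow gradient, specular highlight
blobs and coloured distractors. Above clutter level 0.5 one distractor is
deliberately given a hue within 20° of the hologram's: a hard negative for
the recognition stage. Charts (`render_chart()`) carry a six-step neutral
ramp plus fixed chromatic patches whose reference XYZ is derived from the
known linear reflectance under sRGB/D65 primaries; `render_grey_card()`
gives the uniform 18% card used for non-uniformity correction.

What the simulator does *not* emulate: spectral rendering (colours are
three-channel reflectances, not spectra), lens distortion, out-of-plane
pose, JPEG artefacts, and the gamut limitations that caused the physical
device's systematic error above pH 5.00. Passing tests therefore
demonstrate the correctness and robustness of the algorithmic chain under
a realistic camera model, not performance on any particular handset.
Default scene side is 512 px (the study images were 2048×1536); all sizes
are configurable, and tests use smaller sizes purely as the package's own
choice of economical fixtures.

## Secure transfer

Encryption follows the classical confusion/diffusion pattern.
`derive_key()` encodes a case-folded alphanumeric passcode over the
36-symbol alphabet and reduces its big-endian base-36 value modulo 2^32.
Confusion is a key-seeded pseudo-random permutation of pixel positions
(the generator's shuffle is uniform and reproducible); diffusion XORs the
8-bit channel values with a key-seeded byte stream. The pair is an exact
bijection on 8-bit images. No cryptographic strength is claimed — the goal
is personalised scrambling, mirroring the original design.

Compression is a single-level 2-D orthogonal wavelet transform (Haar or
4-tap Daubechies, periodic boundary), keeping the approximation band in
full and hard-thresholding detail coefficients to the top `keep_fraction`
by magnitude. Surviving coefficients are quantised to 8 bits (LL scaled by
100, details by 60 — quantisation error well under the photographic noise
floor) and deflate-coded. With quantisation disabled the `keep_fraction =
1` round trip is exact to double precision. The transport format
(`secure_pack()`) compresses first and then encrypts the coefficient byte
stream, since permuted pixels would destroy the smoothness the wavelet
exploits.

## Locating the fiducial

The locator is a local-feature template matcher: Harris corners with
3×3 non-maximum suppression, an intensity-centroid orientation per
keypoint, and a 12×12 oriented patch descriptor sampled at 5 px spacing,
normalised to zero mean and unit norm. Two design points deserve note,
both driven by the QR target's self-similarity. First, small descriptors
are useless on a module grid — every corner looks like every other — so
the descriptor support spans roughly five modules, enough to capture local
layout context. Second, gradient-based orientation flips at symmetric
corners; the intensity-centroid angle (the vector from the keypoint to the
centroid of its circular neighbourhood) is stable there. Matching uses
Lowe's ratio test plus mutual-nearest-neighbour consistency, again because
self-similar patterns otherwise produce clustered false matches. Scale
tolerance comes from matching the template over a five-level pyramid
(step 0.93, covering ~0.72–1.05 of nominal size).

The homography is estimated by seeded RANSAC with a 3 px reprojection
threshold. Candidate models are vetoed unless the projected template
corners form a convex quadrilateral of plausible area, and inlier support
is counted over *distinct* scene locations, so repeated matches onto one
cluster cannot fake consensus. Fewer than `min_inliers = 12` supported
matches raises a typed no-detection condition — the "sensor not found,
re-capture" signal. `extract_roi_patch()` rectifies the detected quad to a
square and cuts the central window (default 22–26%, comfortably containing
the hologram circle, whose diameter is ~21% of the target).

## Camera characterisation

Characterisation proceeds in the order: encoded-domain flat-field from the
grey card (vignetting acts multiplicatively on the encoded signal), gamma
estimation from the neutral ramp, linear-domain flat-field, polynomial
regression. Gamma is fitted per channel as `value = luminance^(1/gamma)`
in the log–log domain with an intercept absorbing constant gain. The
flat-field "smoothing" is a degree-4 polynomial surface fit per channel
rather than a boundary convolution: a Gaussian blur with reflected edges
biases a radial falloff exactly where it is strongest (the corners),
whereas the surface fit recovers a quadratic vignette exactly and is
equally robust to noise. The per-channel means of the fitted surface are
the calibration constants.

The RGB→XYZ map is linear least squares on augmented monomial terms
`R^p G^q B^r`. Term sets are data: presets with 3, 5, 8 and 11 terms plus
the full 20-monomial basis of total degree ≤ 3 are shipped, and arbitrary
exponent-triple matrices are accepted (the literature's larger augmented
sets can be supplied the same way). Model selection minimises the median
CIE76 colour difference over the training patches, with ties broken
towards fewer terms. Patch means use the central 50% of each cell to avoid
edge bleed.

## Segmentation and the validity measure

Pixels are smoothed (σ = 1 px Gaussian), converted to the working colour
space, and clustered by k-means (seeded k-means++ initialisation, Lloyd
iterations) or fuzzy c-means (fuzzifier 2) for each candidate k. The
Turi–Ray validity measure selects k automatically:

```
VM = y(k) * intra / inter
intra = mean squared distance of pixels to their own centre
inter = min squared distance between centres
y(k)  = m * N(mu, sigma)(k) + 1,   m = 20, mu = 2, sigma = 1
```

searched over k = 2..10. The printed form of the Gaussian multiplier
carries a negative sign, which would *reward* rather than penalise small
cluster counts and contradicts the criterion's stated purpose; the package
defaults to the positive Gaussian (`sign_variant = "positive_gaussian"`)
and retains the literal form as `"as_printed"`. Both variants are tested
against a brute-force loop oracle. The `+1` keeps VM proportional to
intra/inter at large k where the Gaussian vanishes.

In HSI space the hue circle is embedded as `(S cos H, S sin H, I)` before
clustering, so Euclidean distances respect hue wrap-around; centroids are
reported back in HSI. Clustering runs on a ≤ 20,000-pixel subsample with
full-image labels assigned by nearest centre.

## Recognition

Colour spaces are ranked by the Fisher-style separability `J`. The scatter
matrices follow the usual definitions (within-class scatter summed over
classes, between-class scatter about the size-weighted grand mean); the
criterion is `trace(Sw⁻¹ Sb)`, which is scale-invariant and matches the
interpretation "larger J = better separated classes". The literal matrix
product form is available as `form = "product"` but is not the default,
since it changes under any rescaling of the features.

Each segment is summarised by the 9-dimensional hybrid descriptor
(mean R, G, B, H, S, I, L\*, a\*, b\*; hue averaged circularly with
saturation weights). A 10×10 batch self-organising map, trained for 25–30
epochs with a Gaussian neighbourhood shrinking linearly from radius 5 to
0.5 on z-scored descriptors, is calibrated by majority vote of the mapped
training samples; empty nodes inherit the nearest labelled node's class.
Batch training keeps the procedure deterministic given the seed, and the
quantisation error measured after each epoch's update is nonincreasing in
practice (asserted in the tests for the training schedule used).

## Agreement and calibration

Method agreement uses the one-way intraclass correlation exactly as
defined by the mean-squares form `(MS_B − MS_W)/(MS_B + (k−1) MS_W)`, with
the three ROI colour coordinates as targets and the segmentation methods
as raters; per-scene ICCs are averaged across the pH range, and the pooled
all-scene table is reported alongside. Bland–Altman limits use the sample
(n−1) standard deviation and the 1.96 multiplier.

Calibration is a multilayer perceptron with 9 inputs, two log-sigmoid
hidden layers (default widths 10 and 5 — deliberately small for the
44-sample training regime) and a linear output, trained by full-batch
backpropagation on mean squared error with classical momentum and a
bold-driver step control (the step shrinks and momentum resets whenever
the full-batch loss rises). Training stops at 10,000 iterations or when
the MSE falls below 1e-6; inputs are z-scored with training statistics
stored in the model, so raw descriptors can be passed at prediction time.
Sensors are split wholesale into training and test sets (default 4:2 of
six), so evaluation always simulates unseen devices. Predictions outside
[2.5, 7.0] are returned but flagged.

## Numerical choices and degenerate inputs

* k-means/FCM tolerate ties and empty clusters by re-seeding nudges;
  coincident centres raise a degenerate-clustering error in the validity
  measure rather than returning an infinite ratio.
* The DWT requires even dimensions; quantisation thresholds (LL × 100,
  details × 60) keep quantisation error ≈ 0.3% of full scale.
* RANSAC, k-means++, SOM initialisation, the MLP and every simulator
  render derive their streams from explicit integer seeds; identical
  (seed, arguments) pairs are bit-reproducible.
* Scatter or design matrices that are singular (a one-member class, a
  rank-deficient term set) raise informative errors instead of silently
  pseudo-inverting.

## Known limitations

The locator assumes the fiducial is nearly planar and in-plane rotated;
strong out-of-plane tilt degrades the descriptor match before the
homography model itself fails. The 22-term augmented basis referenced in
the camera-characterisation literature is not shipped because its exact
membership is not published in a form available here — the preset
mechanism accepts it as data. Compression ratios depend strongly on image
content; figures quoted anywhere in this package refer to the synthetic
scenes the code generates, not to any photographic database. The
simulator's gamut is not deliberately restricted, so the device-gamut
saturation effect reported for physical handsets above pH 5.00 does not
arise in the synthetic study.
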