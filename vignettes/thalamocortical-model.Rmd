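---
title: "A thalamocortical neural mass model of centromedian-nucleus stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thalamocortical neural mass model of centromedian-nucleus stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thalamostim)
```

## The problem this package addresses

Electrical stimulation of the centromedian nucleus (CMN) of the thalamus can
transiently suppress interictal epileptiform discharges in focal cortical
dysplasia, and it does so in a frequency-dependent way: low-frequency trains
(50 Hz) leave the neocortical rhythm intact, mid-frequency trains (70 and
150 Hz) suppress it briefly, and 100 Hz trains produce the longest
post-stimulation silence. `thalamostim` implements a two-compartment neural
mass model whose mechanisms — short-term synaptic plasticity, extrasynaptic
GABA accumulation with tonic inhibition of the relay cells, and presynaptic
GABA-B self-inhibition at high frequency — jointly reproduce this pattern,
together with the analysis battery used to quantify it and a
codimension-one bifurcation toolbox for the neocortical subsystem.

## Model structure

Every neuronal subpopulation is a neural mass: a static wave-to-pulse
sigmoid $S(v) = 2e_0 / (1 + e^{r(v_0 - v)})$ converts the summed
postsynaptic potential into a mean firing rate, and a critically damped
second-order pulse-to-wave filter
$\ddot y = W w\, \mathit{fr} - 2 w \dot y - w^2 y$ converts a presynaptic
rate into an average PSP with gain $W$ (mV) and lumped rate constant $w$
(1/s). Connections are signed, scaled by coupling constants, and the two
compartments exchange activity through 12 ms transmission delays.

The **neocortical compartment** contains two mutually coupled pyramidal
masses (recurrent excitation), parvalbumin-positive (PV, fast somatic
inhibition), two somatostatin-positive masses with apical and basal
pyramidal targets (slow dendritic inhibition), VIP-positive and
neurogliaform (NGFC) interneurons with the standard disinhibitory wiring
(VIP–SST mutual inhibition, SST→PV, NGFC→VIP). The PV–PV coupling is wired
but fixed to zero; there is no PV→SST edge. The field potential proxy is a
two-monopole construction on the pyramidal population,
`apical_weight * apical - basal_weight * basal`, built from the
intracortical synaptic currents (the extrinsic thalamocortical EPSP is
excluded so that the proxy reflects local sink/source structure).

The **thalamic compartment** couples a thalamocortical relay mass (TC, with
a self-connection standing for adjacent nuclei) to a fast-kinetics (RtN1,
$w = 350\,/s$) and a slow-kinetics (RtN2, $w = 30\,/s$) reticular
inhibitory mass. Thalamocortical feedforward inhibition targets PV, SST and
NGFC; corticothalamic feedback reaches TC and both reticular masses.

Three connections are plastic (Tsodyks–Markram):

$$\dot u = \frac{u_e - u}{\tau_f} + (1-u)\,u_e\,\mathit{fr}\,\mathit{stim},
\qquad
\dot k = \frac{1-k}{\tau_d} - u\,k\,\mathit{fr}\,\mathit{stim},
\qquad x(t) = \frac{u}{u_e}\,k\,x_0,$$

with depression on TC→PYR (gain family `ACd`) and RtN1→TC (`GTh`), and
facilitation on RtN2→TC (`BTh`). The `stim` gate restricts the
rate-dependent terms to the stimulation period, after which $u$ and $k$
relax to baseline.

Extrasynaptic GABA accumulation follows

$$\dot y_{26} = -\frac{y_{26}}{\tau_{IE}} + \phi_{RtN}\,\mathit{stim},
\qquad \phi_{RtN} = c_1\,g_{GTh}(t)\,\mathit{fr}_{RtN1}
                  + c_2\,g_{BTh}(t)\,\mathit{fr}_{RtN2},$$

where the weights track the plastic gain ratios, and drives a tonic IPSP on
TC through a critically damped second-order stage
($\dot y_{24} = E_T e_T y_{26} - 2 e_T y_{24} - e_T^2 y_{11}$). At 150 Hz a
presynaptic GABA-B gate latches when $y_{26}$ exceeds a threshold taken
from a reference 100 Hz run: the reticular release baselines $u_e$ are
multiplied by 50 (clipped at 1, as $u$ is a release fraction) and
$\tau_{IE}$ is divided by 3.5, modelling reduced release probability and
faster reuptake.

The stimulation waveform is a charge-balanced biphasic pulse (0.5 ms per
phase, 1 ms inter-phase interval) distorted by the RC behaviour of the
electrode–tissue interface (rise 1 ms, decay 4.8 ms), normalised to a peak
of 3.2 arbitrary units, and applied pre-sigmoid to the three thalamic
masses through the lambda-E coupling coefficients. The anodic phase is
placed second so that the slow RC tail is depolarising; with the opposite
order the tail clamps the population rates for most of each cycle and even
50 Hz trains silence the relay, which contradicts the target phenomenology.

## Numerical scheme

The full stochastic system is integrated with a fixed-step Euler–Maruyama
scheme at `dt = 1e-4` s, which resolves both the 0.5 ms pulse phases and
the fastest synaptic kinetics ($w = 550\,/s$). White noise enters as a
firing-rate input to the excitatory masses with diffusion scaling
($\sigma\,\xi/\sqrt{dt}$ per step), so trajectories converge as `dt` is
refined; a convergence test in the suite verifies the first-order error
decay on a noise-free run. Delays are fixed-lag ring buffers at integration
resolution. Ten seconds of warm-up are discarded, and output is recorded at
500 Hz — the closest output rate commensurate with the `dt` grid to the
~512 Hz class of clinical SEEG recorders. Runs are bit-reproducible from
`(parameters, protocol, seed)`, and the frequency battery reuses one
pre-generated noise matrix so that runs differ only in the protocol.

The per-step update order is fixed: waveform value, total inputs and firing
rates of both compartments (delayed couplings read from the buffers), PSP
update, short-term plasticity, GABA accumulation and tonic IPSP, gate
check, buffer push. `u` is clipped to $[u_e^{(0)}, 1]$ (the pre-engagement
baseline, so the gate's release-probability collapse is not clipped away)
and `k` to $[0, 1]$.

## Parameter choices and calibration

The neocortex uses the classical neural-mass constants as its skeleton
(excitatory $W/w \approx 3.25/100$, slow inhibition $22/50$, fast
inhibition $10/500$, coupling scaled from $C = 135$), with four deliberate
departures, each selected during calibration of the regime structure:

- **Pyramidal gain 3.6 mV and 10% faster cortical kinetics** (an exact time
  rescaling of $W$ and $w$ together): places the interictal spike-wave
  rhythm at 3–4 Hz at the operating drive.
- **Detuned SST kinetics** (apical $w = 55$, basal $w = 40$ with matched
  DC gains): splitting the slow-inhibition resonance damps the competing
  ~10 Hz oscillatory mode so that the closed thalamocortical loop settles
  into spike-wave discharges rather than alpha-band activity.
- **Strong PV output (coupling 70)**: restabilises the equilibrium branch
  inside the spike-wave cycle, producing a wide drive window
  ($y_6 \approx 0.21$–$0.30$ mV) in which a stable equilibrium coexists
  with the stable ~3 Hz orbit — the bistable region that makes suppression
  and noise-driven re-ignition possible.
- **Per-subpopulation sigmoids in the thalamus**: the relay mass has a
  steeper activation curve ($r = 2.5$) with its half-activation placed just
  below the operating input (relay-mode gating), and the reticular masses
  have a raised threshold ($v_0 = 8$ mV; recruited only by strong
  synchronous drive). The first makes the relay's suppressed state reach
  below the cortical ignition boundary while keeping a unique fixed point
  for every tonic level (the self-loop slope stays below one, so the relay
  cannot latch); the second removes the frequency-independent floor of
  GABA accumulation so the 50 vs 70 Hz contrast survives the noise.

Thalamic constants were then calibrated so that the unstimulated loop sits
at a relay PSP of $\approx 0.27$ mV — inside the bistable window, where the
spike-wave attractor dominates — and so that the tonic inhibition produced
by the accumulation levels at 10 s (about 0.32, 0.46 and 0.76 A.U. at 50,
70 and 100 Hz) straddles the dropout threshold between the 50 and 70 Hz
levels. The reuptake constant $\tau_{IE} = 12$ s sets the post-stimulation
suppression times (roughly 5 s at 70 Hz and 11–13 s at 100 Hz); the
GABA-B gate at 150 Hz cuts the tail to 2–4 s, and disabling it lengthens
the 150 Hz window several-fold. This frequency-response pattern is
reproduced across every noise seed we tested (12/12).

Tunable parameters of practical interest, with defaults:

| parameter | default | units | role |
|---|---|---|---|
| `stp$ACd` $u_e, \tau_f, \tau_d$ | 0.5, 0.1, 0.1 | –, s, s | depression of the thalamocortical drive |
| `stp$BTh` $u_e, \tau_f, \tau_d$ | 0.2, 4, 0.4 | –, s, s | facilitation of slow reticular inhibition |
| `tonic$ET`, `eT` | 0.125, 3 | mV, 1/s | tonic IPSP gain and rate |
| `tonic$tau_IE` | 12 | s | GABA reuptake (suppression tail) |
| `tonic$c1`, `c2` | 0.02, 0.22 | – | reticular weights in accumulation |
| `gate$ue_multiplier`, `tau_reduction` | 50, 3.5 | – | presynaptic GABA-B engagement |
| `stim_coupling` | 4, 4, 4 | A.U. | lambda-E coefficients (TC first) |
| `integration$dt` | 1e-4 | s | integration step |

## Analysis conventions

The spike detector band-passes at 1–40 Hz, estimates a robust baseline
(median/MAD) on the first 2 s, and thresholds at 4 robust SDs with a
150 ms refractory period; it is invariant to amplitude scaling and offset.
A suppression window is the longest inter-event gap exceeding 2 s (six to
eight missed interictal periods) that overlaps the train; a gap is
attributed to the train if it begins no later than 0.5 s after train end,
so a single straggler discharge at the train boundary does not sever the
window. Spike counts use half-open 5 s bins over 60 s. DTW similarity uses
the classic symmetric dynamic program in a Sakoe–Chiba band on z-scored
series, normalised by the cost of aligning each series against its
sign-flipped self; identical series score 1.

The mechanism-ablation experiment varies one mechanism at a time — the
tonic gain $E_T$ from 0 to 0.125, or a plastic connection's $u_e$ from 0%
to 100% of its default — with the rest of the model intact, over a list of
noise seeds shared across levels so comparisons are paired. In this
calibration, suppression begins at the end of the train (the depolarising
stimulation tail keeps the relay active while the train is on), so the
during-train bin is nearly insensitive to the facilitation baseline; the
facilitation direction (larger $u_e$, weaker facilitation, more spikes)
expresses in the recovery bins after the train instead. The tonic-gain
direction (larger $E_T$, fewer spikes in the 10–15 s bin) and the null
effect of RtN1 depression match the expected pattern directly.

## Bifurcation toolbox

The noise-free neocortical subsystem (14 states, with the relay PSP frozen
as a parameter, justified by the timescale separation between the slow
thalamic quantities and the cortical dynamics) is analysed by multistart
Newton on the reduced 7-dimensional fixed-point map, with the analytic
Jacobian for iteration and the full linearisation for stability.
Natural-parameter continuation with warm starts tracks branches; Hopf
points are flagged where the leading complex pair's real part changes sign
and refined by bisection to 1e-5, and folds where a branch terminates (or
appears), refined by bisection on root existence. Periodic orbits are
characterised by direct simulation past a transient with peak detection,
probing bistability from several initial conditions. Unstable orbit
continuation, homoclinic and period-doubling structure are out of scope;
exact bifurcation values differ from any particular published parameter
set since the defaults here were calibrated as described above.

## What the synthetic fixture emulates

`generate_fixture_seeg()` builds a periodic spike-wave template train (a
sharp positive spike followed by a slower opposite wave) with additive
Gaussian noise, and a thalamic channel of negative peaks time-locked to
the neocortical events — the morphology and timing relationship seen in
interictal depth recordings from dysplastic premotor cortex and the CMN.
It deliberately omits amplitude variability, sporadic low-amplitude
spiking, drift and line noise; passing detector tests on the fixture shows
correct behaviour under idealised morphology, not clinical-grade detection
performance.

## Problem sizes used in tests

Unit tests use 2–8 s simulations; the regime and battery checks use the
full 60 s protocol horizon with a 10 s warm-up; the ablation checks use
10 shared seeds per level, a size at which the paired level effects are
already unambiguous. The acceptance script reruns the battery (4 × 60 s),
a 31-point stability scan, two normal-form sweeps and three 10-seed
ablation experiments.

## Known limitations

- The model reproduces a single patient-like regime; no parameter fitting
  to recordings is provided.
- Low-threshold relay bursting, postsynaptic GABA-B currents, astrocytic
  glutamate release and long-term plasticity are not modelled.
- At low drive a second (high-activity) cortical equilibrium exists with a
  small basin; it is not visited in any of the shipped protocols.
- Suppression onset in this calibration occurs late in the train, whereas
  recordings can show suppression from mid-train; see the ablation note
  above.
- DTW scores against real recordings depend on an undocumented
  normalisation in the source material and are not comparable in absolute
  value.
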