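# thalamostim

A thalamocortical neural mass simulation workbench for studying how
electrical stimulation of the centromedian thalamic nucleus (CMS) suppresses
neocortical interictal epileptiform discharges — and why the effect depends
on the stimulation frequency.

## The science

In focal cortical dysplasia, depth recordings show continuous ~3–4 Hz
interictal spike-wave discharges in the dysplastic cortex, driven by the
thalamocortical relay input. Five-second CMS trains modulate this activity
in a frequency-dependent way: 50 Hz leaves it intact, 70 and 150 Hz suppress
it briefly, and 100 Hz produces the longest post-stimulation silence.

`thalamostim` implements a two-compartment neural mass model of this system.
Each population couples a wave-to-pulse sigmoid
`S(v) = 2e0 / (1 + exp(r (v0 − v)))` with a critically damped second-order
pulse-to-wave filter `ÿ = W w S(v) − 2 w ẏ − w² y`. A layered neocortex
(two pyramidal masses, PV, SST, VIP and neurogliaform interneurons) is
reciprocally coupled, with 12 ms delays, to a thalamic compartment
(relay cells TC plus fast- and slow-kinetics reticular masses RtN1/RtN2).
Three mechanisms shape the response to the RC-distorted biphasic pulse
train:

- **Tsodyks–Markram short-term plasticity** on TC→PYR (depression),
  RtN1→TC (depression) and RtN2→TC (facilitation):
  `u̇ = (ue − u)/τf + (1 − u) ue · fr · stim`,
  `k̇ = (1 − k)/τd − u k · fr · stim`, gain `x = (u/ue) k x0`.
- **Extrasynaptic GABA accumulation and tonic inhibition**:
  `ẏ26 = −y26/τIE + φRtN` during the train (reuptake only otherwise), with
  `φRtN` a plasticity-weighted sum of the reticular firing rates; `y26`
  drives a slow tonic IPSP on the relay cells through a second-order stage.
  Accumulation grows with stimulation frequency, so high-frequency trains
  push the relay drive below the cortical ignition boundary and the
  discharges stop until reuptake clears the accumulated GABA.
- **A presynaptic GABA-B gate** at 150 Hz: when accumulation crosses a
  threshold taken from a reference 100 Hz run, the reticular release
  baselines are multiplied by 50 and reuptake accelerates — release
  collapses, accumulation stops growing, and the suppression tail is cut
  short. This is why 100 Hz, not 150 Hz, gives the longest suppression.

The package also ships the analysis battery (interictal spike detection,
suppression windows, binned counts, DTW similarity, mechanism-ablation
experiments) and a codimension-one bifurcation toolbox (multistart Newton,
natural-parameter continuation, Hopf/saddle-node localisation, periodic
orbit characterisation) for the neocortical subsystem as a function of the
thalamic drive `y6` and the depression factor `κ`.

## Worked example

```r
library(thalamostim)

p <- default_params()

# unstimulated run: continuous interictal spike-wave activity
sim <- run_protocol(p, stim_protocol(0), seed = 1)
dominant_frequency(sim$traces[, "lfp"], sim$fs, c(0.8, 30))
#> [1] 3.466667
ev <- detect_interictal_spikes(sim$traces[, "lfp"], sim$fs)
length(ev$times) / max(sim$time)   # discharges per second
#> [1] 3.466782

# the four-frequency battery with one shared noise path
bat <- run_frequency_battery(p, seed = 1)
for (f in names(bat)) {
  e <- detect_interictal_spikes(bat[[f]]$traces[, "lfp"], bat[[f]]$fs)
  w <- suppression_window(e, bat[[f]]$proto)
  cat(f, "Hz:", if (is.null(w)) "no suppression"
      else sprintf("suppressed %.1f-%.1f s (%.1f s after train end)",
                   w$start, w$end, w$post), "\n")
}
#> 50 Hz: no suppression
#> 70 Hz: suppressed 9.9-14.3 s (4.3 s after train end)
#> 100 Hz: suppressed 9.8-20.1 s (10.1 s after train end)
#> 150 Hz: suppressed 9.9-13.1 s (3.1 s after train end)
```

The 5 s train runs from 5 to 10 s. At 50 Hz the discharges persist through
every 5 s bin; at 100 Hz suppression begins during the train and outlasts it
by more than ten seconds; at 150 Hz the presynaptic GABA-B gate engages at
about 7.6 s and the suppression tail collapses to a few seconds. GABA
accumulation at the end of the train is monotone in frequency
(`y26` ≈ 0.32, 0.46, 0.76 A.U. at 50, 70, 100 Hz).

The noise-free neocortical subsystem can be probed directly:

```r
pq <- p; pq$noise$PYR2$sd <- 0; pq$noise$TC$sd <- 0
ncx_equilibria(pq, y6 = 0.24)      # stable equilibrium inside the window
orbit_branch(pq, "y6", values = 0.28, inits = list(rep(0, 14)))
#> a stable spike-wave orbit at ~3.6 Hz
```

Low drive (`y6 ≲ 0.20`) gives background activity only; a bistable window
(`y6 ≈ 0.21–0.30`) holds a stable equilibrium and the spike-wave orbit
simultaneously; higher drive leaves only the oscillation. Suppression works
by pulling the relay drive leftwards across this structure.

A thin command-line front end is installed at `inst/cli/thalamostim.R`
(subcommands `simulate`, `battery`, `analyze`, `ablate`, `bifurcate`,
`fixtures`).

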