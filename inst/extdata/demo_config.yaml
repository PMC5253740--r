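# Demo run: LDH-like synthetic toy tetramer at three temperatures.
# Produces rigid/effective/internal/composed diffusion spectra, per-residue
# fluctuation profiles, conformational/kinetic networks, and loop CV traces.
seed: 1
outdir: runs/demo
stages: [synth, hydro, rigid_spectrum, isf, decompose, modes, cluster, cv]
synth:
  n_residues_per_subunit: 20
  n_loop_residues: 4
  loop_distances: [45, 60, 75]   # A; D2-symmetric rectangle
  n_frames: 4000
  dt: 0.05                       # ns per frame
  temperatures: [283, 298, 313]  # K
  mode_sigmas: [0.5, 1.0, 1.8]   # A; thermal activation ladder of loop modes
  mode_tau: 2.0                  # ns
hydro:
  bead_radius: 2.9               # A, per-residue bead
q_grid: {min: 0.04, max: 0.25, points: 10}   # 1/A
fit_window: [0.0, 2.0]           # ns
n_orientations: 32
cluster:
  cutoff: 1.5                    # A RMSD
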