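# Demo run configuration for the synaxon pipeline.
# Paths atlas/morphologies are filled in after `make-fixtures`.
paths:
  atlas: demo/atlas
  morphologies: demo/morphologies
  output: demo
level: 2
clustering:
  imposed_C: 5
  covariance: spherical
  n_init: 10
tufts:
  radial_max: 300    # um
  path_max: 300      # um
synthesis:
  lattice_step: 1    # voxels; the toy atlas is small, finer routing lattice
  alpha: 0.5         # fiber-tract edge discount
  trunk_step: 50     # um
  noise_weight: 0.1
  history_weight: 0.2
  tuft_step: 20      # um
  tuft_noise: 0.3
  radius: 0.5        # um
  retry_bound: 10
  n_axons: 59
connectivity:
  touch_distance: 50 # um (toy-scale proximity)
  interval: 5        # um
  density: 0.1       # synapses per um of dendrite
seed: 1
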