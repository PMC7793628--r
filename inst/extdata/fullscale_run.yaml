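# Production-scale run configuration: the chain settings, priors and model
# switches of the published gnathostome analysis. The matrix, homology-block
# declarations, fossil-site table, monophyly constraints and group map must
# point at the user's copy of the study's supplementary data files, which are
# not redistributed here. Running this configuration is a cluster-scale job
# (800 million generations, four independent chains).

matrix: supplementary/gnathostome_matrix.nex   # user-supplied; 489 fixed +
                                               # 2 x 18 homology columns
blocks:
  - label: upper_jaw_bones
    states:
      - "490-507"    # homology alignment 0: supragnathals as
                     # vomer-dermopalatine series
      - "508-525"    # homology alignment 1: supragnathals as
                     # premaxilla-maxilla series

# Fossil-site table and monophyly constraints: fill the member-taxon lists
# from the supplementary BEAST2 xml.
sites: ~
constraints: ~
focal_clade: ~       # taxa of the apomorphy-defined gnathostome clade
groups: ~            # taxon -> group map for nearest-taxon binning

parsimony:
  k: 10              # implied-weights concavity constant
  n_starts: 10
  seed: 1

priors:
  birth_real_mean: 0.14    # lognormal, mean in real space
  birth_sdlog: 0.9
  death_mean: 0.1          # exponential
  sampling_mean: 0.1       # exponential
  clock_meanlog: -5.5      # lognormal, log space
  clock_sdlog: 2
  clock_sd_mean: 1         # exponential
  rate_mean: 1             # normal prior on each partition rate
  rate_sd: 2

model:
  mkv: false
  rho: 0
  partition_by_homoplasy: true

mcmc:
  generations: 800000000
  sample_every: 400000
  burnin_frac: 0.1         # 2001 samples per run, 1801 retained
  seed: 1
  n_runs: 4

phenetics:
  subsample_every: 20      # 5% of the retained posterior sample
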