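# Default poolsweep pipeline configuration (the package defaults, spelled
# out). Any omitted field falls back to the same value.
sim:
  "N": 1000000          # chemostat population size (desk-scale; quoted: bare N is a YAML 1.1 boolean)
  genome_length: 100000 # bp
  mu: 1.0e-9            # per-base per-generation mutation rate
  mutator_fold: 100     # mutation-rate multiplier in mutator carriers
  dilution_rate: 0.1    # h^-1
  duration_days: 60
  sample_days: [5, 7, 14, 20, 28, 35, 40, 45, 50, 56, 60]
  freq_dep: [0.15, 1.0] # (s_h, c): carrier fitness 1 + s_h - c * x_h
  seed: 1
seq:
  mean_depth: 800
  depth_law: poisson
  strand_prob: 0.5
  base_error_rate: 0.001
  read_len: 101
call:
  min_alt_reads: 3
  require_both_strand_coverage: true
  min_report_freq: 0.01
trim:
  p_max: 0.05
  min_len: 25
cohort:
  eps: 0.05
  min_peak: 0.05
sweep:
  hard_hi: 0.90
  soft_min: 0.10
  origin_max: 0.01
# uncomment to also generate and preprocess a paired-FASTQ fixture:
# fastq_fixture:
#   n_fragments: 200
#   dup_fraction: 0.1
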