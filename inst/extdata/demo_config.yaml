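# All-synthetic demo configuration: simulates a two-condition Hi-C
# experiment with planted loops (4 Mb chromosome, 10 kb bins), a deeper
# 50 kb-resolution experiment for compartment analysis, and an ATAC-like
# fragment experiment with planted differential peaks, then runs the whole
# analysis chain. Omitted keys take package defaults.
seed: 1
outdir: pipeline_out
hic_sim:
  chrom_lengths:
    chrS: 4000000
  bin_size: 10000
compartment_sim:
  chrom_lengths:
    chrC: 20000000
  bin_size: 50000
frag_sim:
  genome_len: 10000000
loops:
  p: 1
  w: 5
  score_min: 2
diffloops:
  mode: all_combinations
  alpha: 0.05
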