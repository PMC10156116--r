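# hybridscan demonstration configuration: simulates a reduced-scale panel
# under the default fur seal history and runs the analysis stages.
seed = 1
n_sites = 20000
n_windows = 200
block_size = 200
stages = simulate,fstats,twisst,ploidy
out_dir = hybridscan_demo
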