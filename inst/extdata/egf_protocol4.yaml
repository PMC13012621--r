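# Growth-factor stimulus protocol 4: at time 0 the AP-2 number doubles
# (100 -> 200), the gated clathrin-clathrin rate increases 50-fold and the
# clathrin diffusion coefficient drops to 1/50; all three revert to
# baseline after 30 simulated minutes. Cluster-scale at full duration.
box_edge: "1000 nm"
dt: "3 us"
n_clathrin: 300
n_ap2: 100
duration: "60 min"
frame_interval: "0.1 s"
seed: 1
rates:
  k_cc_gated: "50x0.913 uM-1s-1"
  k_cc_free: "0 uM-1s-1"
  k_ap2_clat: "0.0012 uM-1s-1"
  koff_cc: "1 s-1"
  koff_ap2_clat: "0.1 s-1"
schedule:
  - time: "0 s"
    n_ap2: 200
    k_cc_gated_mult: 50
    d_clat_mult: 0.02
  - time: "30 min"
    n_ap2: 100
    k_cc_gated_mult: 1
    d_clat_mult: 1
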