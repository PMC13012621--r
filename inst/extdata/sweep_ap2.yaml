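# AP-2 number sweep at the reference condition (cluster-scale when run at
# full duration). The sweep block lists the AP-2 grid.
box_edge: "1000 nm"
dt: "3 us"
n_clathrin: 300
n_ap2: 100
duration: "30 min"
frame_interval: "0.1 s"
seed: 1
rates:
  k_cc_gated: "50x0.913 uM-1s-1"
  k_cc_free: "0 uM-1s-1"
  k_ap2_clat: "0.0012 uM-1s-1"
  koff_cc: "1 s-1"
  koff_ap2_clat: "0.1 s-1"
sweep:
  n_ap2: [10, 50, 100, 150, 200, 300, 400]
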