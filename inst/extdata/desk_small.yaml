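# Desk-scale study conditions: quarter membrane area (500 nm box edge),
# 60 clathrins, 3 simulated seconds. Because clathrin-clathrin capture is
# encounter-limited, time compression is achieved by enlarging the
# association reaction radius (2.5 nm), scaling the AP-2 capture rate
# 2000-fold and the dissociation rates so that nucleation, exchange and
# anchor turnover all play out within the run. AP-2 numbers for sweep
# analogs are scaled by membrane area (one quarter of full-scale values).
box_edge: "500 nm"
dt: "3 us"
n_clathrin: 60
n_ap2: 25
duration: "3 s"
frame_interval: "0.05 s"
seed: 1
reaction_radius: "2.5 nm"
rates:
  k_cc_gated: "50x0.913 uM-1s-1"
  k_cc_free: "0 uM-1s-1"
  k_ap2_clat: "2000x0.0012 uM-1s-1"
  koff_cc: "10 s-1"
  koff_ap2_clat: "20 s-1"
d_clat: 13
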