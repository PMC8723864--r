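# Canonical parameter set of the modified Toporikova-Butera PBC model.
# tau_n_bar / tau_h_bar follow the canonical Butera assignment (fast n,
# slow h); can_scale = 1 is the plain Hill CAN activation.
C_m: 21.0
g_Na: 28.0
g_K: 11.2
g_L: 2.3
g_NaP: 2.0
g_CAN: 0.7
V_Na: 50.0
V_K: -85.0
V_L: -58.0
V_m: -34.0
V_n: -29.0
V_p: -40.0
V_h: -48.0
s_m: -5.0
s_n: -4.0
s_h: 5.0
s_mp: -6.0
tau_n_bar: 10.0
tau_h_bar: 10000.0
n_CAN: 0.97
K_CAN: 0.74
eps: 0.09
d: 0.5
Ca_c: 0.1
l_c: 0.9
can_scale: 1.0
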