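schema_version: 1
c_soma: 150.0
c_dend: 1000.0
gl_soma: 15.0
gl_dend: 2.0
el_soma: -72.0
el_dend: -72.0
g_na: 5000.0
g_kd: 1500.0
g_ca: 900.0
g_ks: 6000.0
g_h: 8.0
g_c: 100.0
e_na: 55.0
e_k: -90.0
e_h: -35.0
g_syn: 2.2
ca_scale: 1.0
e_ca: 120.0
mca_mid: -42.0
mca_slope: 4.5
tau_mca: 3.0
q_mid: -25.0
q_slope: 4.0
tau_q: 6.0
tau_q_off: 250.0
g_adapt: 95.0
z_mid: -35.0
tau_z_on: 0.5
tau_z_off: 150.0
c_bas: 80.0
gl_bas: 10.0
el_bas: -72.0
g_cb: 35.0
g_m: 80.0
tau_m: 80.0
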