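# Fitted kinetic constants of the CHO PFL/NOPFL circuit (nM, min^-1).
# s_obs is an instrument gain (fluorescence a.u. per nM folded reporter),
# not a kinetic constant; 10 is the package's reference value.
theta: 4.81
alpha0: 1.13e-05
v1: 7.54e-02
kp: 2.71e-02
d1: 1.01e-02
d2: 1.00e-02
d3: 3.24e-03
"n": 3.16
k_dox: 1.00
h: 6.03e-02
Kf: 1.24e-03
rho_tTA: 13.69
s_obs: 10
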