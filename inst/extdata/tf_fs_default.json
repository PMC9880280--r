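{"population":"FS","K_e":400,"K_i":100,"P":[-51.2590908738283,3.56812117647769,-8.6438138743477,3.56939709560604,-0.244596370492083,2.13775082555235,0.432439802222021,-0.0486086821440784,-13.6248198786604,-19.0837089227178],"params":{"c_m":200,"g_L":10,"E_L_e":-63,"E_L_i":-65,"Delta_e":2,"Delta_i":0.5,"v_thr":-50,"v_peak_e":-40,"v_peak_i":-47.5,"v_reset":-65,"T_refr":5,"a":0,"b":0,"u_w":500,"Q_e":1.5,"Q_i":5,"E_e":0,"E_i":-80,"u_e":5,"u_i":5},"fit":{"n_points":169,"rms_hz":0.199222665090816,"seed":202,"sim_time":10000,"n_rep":20}}
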