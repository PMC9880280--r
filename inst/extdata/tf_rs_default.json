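{"population":"RS","K_e":400,"K_i":100,"P":[-49.2365618106866,1.71042234049273,0.745341678879404,-2.90018663021361,0.754702923682242,-0.726115484749879,1.40616511188181,11.6565173230388,3.79053308173318,-1.88353778850322],"params":{"c_m":200,"g_L":10,"E_L_e":-63,"E_L_i":-65,"Delta_e":2,"Delta_i":0.5,"v_thr":-50,"v_peak_e":-40,"v_peak_i":-47.5,"v_reset":-65,"T_refr":5,"a":0,"b":0,"u_w":500,"Q_e":1.5,"Q_i":5,"E_e":0,"E_i":-80,"u_e":5,"u_i":5},"fit":{"n_points":507,"rms_hz":0.33785121048537,"seed":201,"sim_time":10000,"n_rep":20}}
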