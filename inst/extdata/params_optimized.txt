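# Optimized parameter set of the minimal pig intestinal-lumen PBPK model.
# Units: Qcar L/(h*kg); Vc_* fraction of BW; Qc_* fraction of Qcar;
# k_* 1/h; Cl_renal L/(h*kg); F, Pb, PCV fractions; BW kg.
Qcar: 4.944
PCV: 0.333
Qc_l: 0.3
Qc_ot: 0.7
Vc_int: 0.0136733
Vc_l: 0.0294
Vc_b: 0.06
Vc_ot: 0.8969267
k_st: 0.8544925
k_a: 0.8555538
F: 0.7925891
P_l: 2.936615
P_ot: 11.33514
k_e: 0.007358172
k_bi: 0.05834594
Pb: 0.319
Cl_renal: 0.2805897
BW: 27
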