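scene,D_um,P_mW_cm2,U_deg,level
S-1,70.23,1.537,1.62,II
S-2,54.15,1.537,1.52,II
S-3,45.67,1.537,1.39,III
S-4,23.63,1.537,0.88,III
S-5,11.04,1.537,0.53,III
S-6,9.69,1.537,0.47,II
S-7,18.69,1.537,0.76,II
S-8,54.35,0.249,2.81,III
S-9,all_covered,0.063,3.54,I
S-10,18.69,1.537,0.76,I
S-11,18.98,1.537,0.77,I
S-12,19.23,1.537,0.79,II
S-13,18.82,1.537,0.77,II
S-14,19.54,1.537,0.8,III
S-15,19.97,1.537,0.85,III
S-16,70.23,1.537,1.94,II
S-17,54.15,1.537,1.79,II
S-18,45.67,1.537,1.42,III
S-19,23.63,1.537,1.33,III
S-20,11.04,1.537,0.69,III
S-21,9.69,1.537,0.51,II
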