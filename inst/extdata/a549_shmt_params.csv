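quality,plating,oxygen,d0_Gy,sd_d0,n,sd_n,pe,sd_pe
xray,immediate,normoxia,2.98,0.20,1.07,0.05,0.35,0.03
xray,immediate,hypoxia,1.68,0.08,1.20,0.07,0.25,0.02
xray,late,normoxia,2.29,0.13,0.94,0.05,0.35,0.03
xray,late,hypoxia,2.50,0.16,1.19,0.06,0.25,0.02
carbon,immediate,normoxia,1.11,0.07,0.64,0.08,0.35,0.03
carbon,immediate,hypoxia,1.10,0.11,0.34,0.06,0.25,0.02
carbon,late,normoxia,0.90,0.03,0.76,0.07,0.35,0.03
carbon,late,hypoxia,1.08,0.10,0.49,0.09,0.25,0.02
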