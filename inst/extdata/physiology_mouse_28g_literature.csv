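# Mouse physiology, 28 g animal, with generic literature-style cellular
# volume fractions (alternative to the Kp-calibrated set shipped in
# physiology_mouse_28g.csv). Synthetic stand-in table; volumes mL, flows mL/h.
tissue,V_total_mL,f_vascular,f_endothelial,f_interstitial,f_cellular,Q_blood_mL_h
blood,1.72,1,0,0,0,678.1
lung,0.204,0.2601,0.005,0.2349,0.5000,678.1
liver,1.93,0.2100,0.005,0.1350,0.6500,18.7
heart,0.152,0.1000,0.005,0.1150,0.7800,66.4
kidney,0.525,0.1600,0.005,0.0850,0.7500,124.5
brain,0.485,0.0300,0.005,0.1850,0.7800,21.5
muscle,11.30,0.0400,0.005,0.1250,0.8300,156.5
bone,2.82,0.0400,0.005,0.2050,0.7500,27.6
thymus,0.009,0.0400,0.005,0.2950,0.6600,2.2
skin,5.02,0.0400,0.005,0.3550,0.6000,50.5
adipose,1.98,0.0200,0.005,0.1550,0.8200,24.4
small_intestine,0.728,0.0700,0.005,0.2250,0.7000,105.6
large_intestine,0.314,0.0700,0.005,0.2250,0.7000,31.5
spleen,0.127,0.2200,0.005,0.1750,0.6000,14.9
pancreas,0.097,0.0600,0.005,0.2150,0.7200,11.3
other,0.60,0.0400,0.005,0.2050,0.7500,22.5
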