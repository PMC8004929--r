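# Mouse physiology for a 28 g tumor-bearing animal (synthetic stand-in table,
# assembled from standard rodent PBPK physiology; volumes mL, flows mL/h).
# f_cellular is the Kp-calibrated set: the ratio of apparent to
# cellular-space-adjusted partition coefficients fixes the cellular volume
# fraction of each observed tissue; unobserved tissues carry generic values.
# The lung row carries the cardiac-output (total) blood flow; it equals the
# sum of all regional flows by construction. The blood row is the central
# venous pool (vascular only) and carries the cardiac output for reference.
tissue,V_total_mL,f_vascular,f_endothelial,f_interstitial,f_cellular,Q_blood_mL_h
blood,1.72,1,0,0,0,678.1
lung,0.204,0.2601,0.005,0.1910,0.5439,678.1
liver,1.93,0.2100,0.005,0.1482,0.6368,18.7
heart,0.152,0.1000,0.005,0.1099,0.7851,66.4
kidney,0.525,0.1600,0.005,0.0897,0.7453,124.5
brain,0.485,0.0300,0.005,0.1895,0.7755,21.5
muscle,11.30,0.0400,0.005,0.1272,0.8278,156.5
bone,2.82,0.0400,0.005,0.1878,0.7672,27.6
thymus,0.009,0.0400,0.005,0.2950,0.6600,2.2
skin,5.02,0.0400,0.005,0.3592,0.5958,50.5
adipose,1.98,0.0200,0.005,0.1677,0.8073,24.4
small_intestine,0.728,0.0700,0.005,0.2250,0.7000,105.6
large_intestine,0.314,0.0700,0.005,0.2250,0.7000,31.5
spleen,0.127,0.2200,0.005,0.2009,0.5741,14.9
pancreas,0.097,0.0600,0.005,0.2149,0.7201,11.3
other,0.60,0.0400,0.005,0.2050,0.7500,22.5
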