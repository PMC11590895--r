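class,accuracy,tpr,tnr,ppv,f1
natural_suckling,99.10,96.75,99.50,97.01,96.88
rumination,97.36,93.74,98.71,96.43,95.07
feeding,95.76,91.68,97.20,92.10,91.89
others,93.79,91.80,94.74,89.26,90.51
Overall,96.50,93.49,97.54,93.70,93.59
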