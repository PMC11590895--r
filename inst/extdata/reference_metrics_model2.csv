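class,accuracy,tpr,tnr,ppv,f1
lying,97.98,98.82,96.43,98.08,98.45
standing,97.98,96.43,98.82,97.80,97.11
Overall,97.98,97.63,97.63,97.94,97.78
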